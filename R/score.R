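#' Area under the ROC curve for opening energy
#'
#' AUC of opening energy as a predictor of expression success, with the
#' lower-is-positive orientation (low opening energy predicts success) and
#' midrank handling of ties, i.e. the normalized Mann-Whitney statistic.
#'
#' @param data Labeled dataset tibble with `opening_energy` and binary
#'   `outcome` columns.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(data) {
  validate_labeled(data, require_energy = TRUE)
  y <- data$outcome
  if (length(unique(y)) < 2) {
    abort("Both outcome classes must be present for ROC analysis.",
      class = "tir_validation_error"
    )
  }
  score <- -data$opening_energy # lower energy = more positive
  r <- rank(score, ties.method = "average")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Positive likelihood ratio from cumulative counts
#'
#' `sensitivity / (1 - specificity) = (tp/(tp+fn)) / (fp/(fp+tn))`. With
#' `fp = 0` and `tp > 0` the ratio is `Inf` (flagged by the caller).
#'
#' @param tp,fn,fp,tn Non-negative cumulative counts.
#' @return The positive likelihood ratio.
#' @export
plr <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) {
    abort("Counts must be non-negative.", class = "tir_validation_error")
  }
  if (tp + fn <= 0 || fp + tn <= 0) {
    abort("Need at least one record in each outcome class.",
      class = "tir_validation_error"
    )
  }
  sens <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  if (fpr == 0) {
    return(if (sens > 0) Inf else NaN)
  }
  sens / fpr
}

#' Threshold-wise positive likelihood-ratio curve
#'
#' At each opening-energy threshold `t`, records with energy `<= t` are
#' called positive ("less than type"): successes below the threshold are
#' true positives, failures below are false positives, and the complements
#' above the threshold are false negatives and true negatives.
#'
#' @param data Labeled dataset with `opening_energy` and `outcome`.
#' @param thresholds Energy thresholds; defaults to every distinct observed
#'   energy.
#' @return A tibble of class `plr_curve`: `threshold`, `tp`, `fp`, `tn`,
#'   `fn`, `plr`.
#' @export
plr_curve <- function(data, thresholds = NULL) {
  validate_labeled(data, require_energy = TRUE)
  if (is.null(thresholds)) thresholds <- sort(unique(data$opening_energy))
  if (length(thresholds) == 0) {
    abort("`thresholds` must be non-empty.", class = "tir_validation_error")
  }
  thresholds <- sort(thresholds)
  ord <- order(data$opening_energy)
  x <- data$opening_energy[ord]
  y <- data$outcome[ord]
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  cum_pos <- cumsum(y == 1)
  cum_neg <- cumsum(y == 0)
  idx <- findInterval(thresholds, x)
  tp <- ifelse(idx == 0, 0L, cum_pos[pmax(idx, 1)])
  fp <- ifelse(idx == 0, 0L, cum_neg[pmax(idx, 1)])
  out <- tibble(
    threshold = thresholds, tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(n0 - fp), fn = as.integer(n1 - tp)
  )
  out$plr <- purrr::pmap_dbl(
    out[, c("tp", "fn", "fp", "tn")],
    function(tp, fn, fp, tn) plr(tp, fn, fp, tn)
  )
  class(out) <- c("plr_curve", class(out))
  out
}

#' Bootstrap confidence interval for a threshold's PLR
#'
#' Percentile interval over `B` resamples of the records with replacement.
#' Resamples missing an outcome class are redrawn up to 10 times and then
#' dropped with a warning.
#'
#' @param data Labeled dataset.
#' @param threshold Opening-energy threshold.
#' @param B Number of bootstrap replicates (>= 100; 10,000 by default).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Tibble `threshold`, `estimate`, `ci_low`, `ci_high`, `B_used`.
#' @export
bootstrap_plr_ci <- function(data, threshold, B = 10000, seed = NULL,
                             conf = 0.95) {
  validate_labeled(data, require_energy = TRUE)
  if (B < 100) abort("`B` must be >= 100.", class = "tir_validation_error")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  x <- data$opening_energy
  y <- data$outcome
  n <- length(x)
  plr_at <- function(xx, yy) {
    tp <- sum(yy == 1 & xx <= threshold)
    fp <- sum(yy == 0 & xx <= threshold)
    plr(tp, sum(yy == 1) - tp, fp, sum(yy == 0) - fp)
  }
  stats <- rep(NA_real_, B)
  dropped <- 0L
  for (b in seq_len(B)) {
    val <- NA_real_
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2) next
      val <- plr_at(x[idx], y[idx])
      break
    }
    if (is.na(val)) dropped <- dropped + 1L
    stats[b] <- val
  }
  if (dropped > 0) {
    warn(sprintf("%d degenerate bootstrap replicates dropped.", dropped))
  }
  stats <- stats[!is.na(stats)]
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(stats, c(alpha, 1 - alpha), names = FALSE))
  tibble(
    threshold = threshold, estimate = plr_at(x, y),
    ci_low = ci[1], ci_high = ci[2], B_used = length(stats)
  )
}

#' Fit a four-parameter logistic to likelihood ratios
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x/c)^b)` over
#' opening-energy thresholds `x` and positive likelihood ratios `y`, with
#' multi-start Levenberg-Marquardt initialization. Non-finite `y` values
#' (infinite PLRs at extreme thresholds) are excluded with a note in the
#' result.
#'
#' @param x Opening-energy thresholds (kcal/mol).
#' @param y Positive likelihood ratios.
#' @param weights Optional fit weights.
#' @return An object of class `four_pl` with elements `a`, `b`, `c`, `d`,
#'   `rss`, `converged`, `degenerate`, `n`, `n_dropped`.
#' @export
fit_4pl <- function(x, y, weights = NULL) {
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  x <- x[keep]
  y <- y[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(x) < 4) {
    abort("Need at least 4 finite points to fit a 4PL.",
      class = "tir_validation_error"
    )
  }
  if (sd(y) < 1e-12) {
    const <- mean(y)
    fit <- structure(
      list(
        a = const, b = 1, c = stats::median(x), d = const,
        rss = sum((y - const)^2), converged = TRUE, degenerate = TRUE,
        n = length(x), n_dropped = n_dropped
      ),
      class = "four_pl"
    )
    return(fit)
  }
  df <- data.frame(x = x, y = y)
  starts <- tidyr::expand_grid(
    a = max(y), d = min(y),
    c = unname(quantile(x, c(0.25, 0.5, 0.75))),
    b = c(0.5, 1, 2, 4, 8)
  )
  best <- NULL
  last_err <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- as.list(starts[i, ])
    call_args <- list(
      y ~ d + (a - d) / (1 + (x / c)^b),
      data = df, start = st,
      lower = c(a = -Inf, d = -Inf, c = 1e-9, b = -50),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (!is.null(weights)) call_args$weights <- weights
    fit <- tryCatch(
      do.call(minpack.lm::nlsLM, call_args),
      error = function(e) {
        last_err <<- e
        NULL
      }
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort(
      sprintf(
        "4PL fit failed from every start (last error: %s)",
        conditionMessage(last_err)
      ),
      class = "tir_numerical_error"
    )
  }
  cf <- coef(best$fit)
  structure(
    list(
      a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
      d = unname(cf["d"]), rss = best$rss, converged = TRUE,
      degenerate = FALSE, n = length(x), n_dropped = n_dropped
    ),
    class = "four_pl"
  )
}

#' @export
predict.four_pl <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  object$d + (object$a - object$d) / (1 + (x / object$c)^object$b)
}

#' @export
print.four_pl <- function(x, ...) {
  cat(sprintf(
    "<four_pl a=%.4g b=%.4g c=%.4g d=%.4g rss=%.4g%s>\n",
    x$a, x$b, x$c, x$d, x$rss, if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' @export
tidy.four_pl <- function(x, ...) {
  tibble(
    term = c("a", "b", "c", "d"),
    estimate = c(x$a, x$b, x$c, x$d)
  )
}

#' @export
glance.four_pl <- function(x, ...) {
  tibble(
    rss = x$rss, n = x$n, n_dropped = x$n_dropped,
    converged = x$converged, degenerate = x$degenerate
  )
}

#' Expression score model
#'
#' Couples a fitted 4PL likelihood-ratio curve with a prior probability of
#' expression success (default 0.49, the Expressed/Cloned proportion of the
#' PSI:Biology campaign: 21,046 / 42,774).
#'
#' @param fourpl A [fit_4pl()] object.
#' @param prior Prior success probability in (0, 1).
#' @param provenance Free-text description of the data the model was fit
#'   on.
#' @return An object of class `score_model`.
#' @export
score_model <- function(fourpl, prior = 0.49, provenance = "unspecified") {
  stopifnot(inherits(fourpl, "four_pl"))
  if (prior <= 0 || prior >= 1) {
    abort("`prior` must be in (0, 1).", class = "tir_validation_error")
  }
  structure(
    list(fourpl = fourpl, prior = prior, provenance = provenance),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model prior=%.3f, %s>\n", x$prior, x$provenance))
  print(x$fourpl)
  invisible(x)
}

#' Expression Score of an opening energy
#'
#' Bayesian posterior probability of expression success, as a percentage:
#' prior odds times the fitted positive likelihood ratio at the opening
#' energy gives posterior odds, mapped to a probability and scaled by 100.
#' A fitted ratio at or below zero is clamped to a small positive floor and
#' flagged via the `"clamped"` attribute.
#'
#' @param energy Opening energies (kcal/mol); vectorized.
#' @param model A [score_model()].
#' @return Scores in `[0, 100]` (raw, not rounded) with attribute
#'   `"rounded"` giving the nearest-integer presentation values.
#' @export
expression_score <- function(energy, model) {
  stopifnot(inherits(model, "score_model"))
  lr <- predict(model$fourpl, energy)
  clamped <- lr <= 0
  lr[clamped] <- 1e-9
  prior_odds <- model$prior / (1 - model$prior)
  odds <- prior_odds * lr
  score <- 100 * odds / (1 + odds)
  attr(score, "rounded") <- round(score)
  attr(score, "clamped") <- clamped
  score
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' Sup-norm distance between the empirical cumulative distribution
#' functions.
#'
#' @param sample_a,sample_b Numeric samples.
#' @return D in `[0, 1]`.
#' @export
ks_distance <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  grid <- sort(unique(c(sample_a, sample_b)))
  fa <- vapply(grid, function(g) mean(sample_a <= g), numeric(1))
  fb <- vapply(grid, function(g) mean(sample_b <= g), numeric(1))
  max(abs(fa - fb))
}

#' Fit a complete Expression Score model from a labeled dataset
#'
#' Convenience pipeline: PLR curve over thresholds, optional bootstrap CIs,
#' 4PL fit (excluding infinite ratios), and a [score_model()].
#'
#' @param data Labeled dataset with `opening_energy` and `outcome`.
#' @param thresholds Optional energy thresholds (default: observed values).
#' @param B Bootstrap replicates per threshold for CIs; `0` (default)
#'   skips the bootstrap.
#' @param seed Optional seed for the bootstrap.
#' @param prior Prior success probability.
#' @return A `score_model` with the `plr_curve` attached as attribute
#'   `"curve"`.
#' @export
fit_score_model <- function(data, thresholds = NULL, B = 0, seed = NULL,
                            prior = 0.49) {
  curve <- plr_curve(data, thresholds)
  if (B > 0) {
    cis <- purrr::map_dfr(
      seq_len(nrow(curve)),
      function(i) {
        bootstrap_plr_ci(data, curve$threshold[i], B = B, seed = seed)
      }
    )
    curve$ci_low <- cis$ci_low
    curve$ci_high <- cis$ci_high
  }
  fit <- fit_4pl(curve$threshold, curve$plr)
  model <- score_model(
    fit, prior,
    provenance = sprintf("fit on %d records", nrow(data))
  )
  attr(model, "curve") <- curve
  model
}

#' Serialize / restore a score model
#'
#' @param model A [score_model()].
#' @param path JSON file path.
#' @return `write_score_model()` returns `path` invisibly;
#'   `read_score_model()` returns the restored `score_model`.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  f <- model$fourpl
  jsonlite::write_json(
    list(
      a = f$a, b = f$b, c = f$c, d = f$d, rss = f$rss,
      converged = f$converged, degenerate = f$degenerate, n = f$n,
      n_dropped = f$n_dropped, prior = model$prior,
      provenance = model$provenance
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- structure(
    list(
      a = j$a, b = j$b, c = j$c, d = j$d, rss = j$rss,
      converged = j$converged, degenerate = j$degenerate, n = j$n,
      n_dropped = j$n_dropped
    ),
    class = "four_pl"
  )
  score_model(fit, prior = j$prior, provenance = j$provenance)
}

#' Plot a PLR curve and its 4PL fit
#'
#' @param object A `plr_curve` tibble.
#' @param fit Optional `four_pl` to overlay.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.plr_curve <- function(object, fit = NULL, ...) {
  df <- object[is.finite(object$plr), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$plr)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "opening energy threshold (kcal/mol)",
      y = "positive likelihood ratio"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$ci_low)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0, alpha = 0.3
    )
  }
  if (!is.null(fit)) {
    grid <- seq(min(df$threshold), max(df$threshold), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = data.frame(threshold = grid, plr = predict(fit, grid)),
      colour = "firebrick"
    )
  }
  p
}
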