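test_that("AUC equals brute-force pair counting with midrank ties", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    d <- tibble::tibble(
      opening_energy = sample(seq(2, 30, 0.5), n, replace = TRUE),
      outcome = sample(c(0, 1), n, replace = TRUE)
    )
    if (length(unique(d$outcome)) < 2) next
    pos <- d$opening_energy[d$outcome == 1]
    neg <- d$opening_energy[d$outcome == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b)))
    expect_equal(roc_auc(d), brute, tolerance = 1e-12)
  }
})

test_that("AUC boundary cases: perfect separation, pure ties, label flip", {
  sep <- tibble::tibble(
    opening_energy = c(1, 2, 3, 20, 21, 22), outcome = c(1, 1, 1, 0, 0, 0)
  )
  expect_equal(roc_auc(sep), 1)
  ties <- tibble::tibble(opening_energy = rep(7, 10), outcome = rep(c(0, 1), 5))
  expect_equal(roc_auc(ties), 0.5)
  d <- labeled_fixture(100, seed = 4)
  flipped <- dplyr::mutate(d, outcome = 1 - outcome)
  expect_equal(roc_auc(d) + roc_auc(flipped), 1)
  expect_error(
    roc_auc(tibble::tibble(opening_energy = 1:5, outcome = rep(1, 5))),
    class = "tir_validation_error"
  )
})

test_that("positive likelihood ratio arithmetic and boundaries", {
  expect_equal(plr(8, 2, 3, 7), 0.8 / 0.3)
  # sensitivity = 1 - specificity: uninformative threshold
  expect_equal(plr(5, 5, 5, 5), 1)
  expect_identical(plr(3, 1, 0, 9), Inf)
  expect_error(plr(-1, 2, 3, 4), class = "tir_validation_error")
  expect_error(plr(0, 0, 3, 4), class = "tir_validation_error")
})

test_that("PLR curve tabulates cumulative counts correctly", {
  d <- tibble::tibble(
    opening_energy = c(5, 10, 15, 20),
    outcome = c(1, 1, 0, 0)
  )
  cv <- plr_curve(d)
  expect_identical(cv$threshold, c(5, 10, 15, 20))
  expect_identical(cv$tp, c(1L, 2L, 2L, 2L))
  expect_identical(cv$fp, c(0L, 0L, 1L, 2L))
  expect_identical(cv$fn, c(1L, 0L, 0L, 0L))
  expect_identical(cv$tn, c(2L, 2L, 1L, 0L))
  expect_equal(cv$plr[3], (2 / 2) / (1 / 2))
  # count sums invariant across thresholds; FN = 0 at the maximum
  expect_true(all(cv$tp + cv$fn == 2))
  expect_true(all(cv$fp + cv$tn == 2))
  expect_identical(cv$fn[nrow(cv)], 0L)
  expect_error(plr_curve(d, numeric(0)), class = "tir_validation_error")
})

test_that("bootstrap CI brackets the estimate, is seeded, and shrinks as 1/sqrt(n)", {
  d <- labeled_fixture(200, seed = 21)
  ci <- bootstrap_plr_ci(d, 12, B = 400, seed = 1)
  expect_lte(ci$ci_low, ci$estimate)
  expect_gte(ci$ci_high, ci$estimate)
  expect_identical(ci, bootstrap_plr_ci(d, 12, B = 400, seed = 1))
  d4 <- labeled_fixture(3200, seed = 21)
  ci4 <- bootstrap_plr_ci(d4, 12, B = 400, seed = 1)
  ratio <- (ci$ci_high - ci$ci_low) / (ci4$ci_high - ci4$ci_low)
  expect_gt(ratio, 4^0.5 * 0.55) # ~ sqrt(16x records) with slack
  expect_lt(ratio, 4^0.5 * 3)
  expect_error(bootstrap_plr_ci(d, 12, B = 50), class = "tir_validation_error")
})

test_that("bootstrap CIs achieve near-nominal coverage on synthetic data", {
  # truth from the generating model by numeric integration
  gen <- attr(labeled_fixture(20, seed = 1), "generator")
  p_s <- function(x) 1 / (1 + exp(gen$slope * (x - gen$midpoint)))
  lo <- gen$energy_range[1]
  hi <- gen$energy_range[2]
  t0 <- 12
  num <- stats::integrate(p_s, lo, t0)$value /
    stats::integrate(p_s, lo, hi)$value
  den <- stats::integrate(function(x) 1 - p_s(x), lo, t0)$value /
    stats::integrate(function(x) 1 - p_s(x), lo, hi)$value
  true_plr <- num / den
  covered <- vapply(1:120, function(s) {
    d <- labeled_fixture(250, seed = 4000 + s)
    ci <- suppressWarnings(bootstrap_plr_ci(d, t0, B = 300, seed = s))
    ci$ci_low <= true_plr && true_plr <= ci$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 1.0)
})

test_that("4PL fit recovers noiseless parameters to 1e-4 relative", {
  x <- seq(1, 30, length.out = 40)
  truth <- c(a = 3.0, b = 4.0, c = 12.0, d = 0.5)
  y <- truth["d"] + (truth["a"] - truth["d"]) / (1 + (x / truth["c"])^truth["b"])
  f <- fit_4pl(x, y)
  est <- c(a = f$a, b = f$b, c = f$c, d = f$d)
  expect_lt(max(abs(est - truth) / abs(truth)), 1e-4)
  expect_false(f$degenerate)
  expect_true(f$converged)
})

test_that("4PL fit flags constant input as degenerate and drops infinities", {
  f <- fit_4pl(1:10, rep(2.5, 10))
  expect_true(f$degenerate)
  expect_equal(f$a, 2.5)
  expect_equal(f$d, 2.5)
  x <- seq(1, 30, length.out = 20)
  y <- 0.5 + 2.5 / (1 + (x / 12)^4)
  y[1] <- Inf
  f2 <- fit_4pl(x, y)
  expect_identical(f2$n_dropped, 1L)
  expect_identical(f2$n, 19L)
  expect_error(fit_4pl(1:3, c(1, 2, 3)), class = "tir_validation_error")
})

test_that("4PL fit stays within 5% under moderate noise (median over seeds)", {
  x <- seq(2, 30, length.out = 30)
  truth <- c(a = 3.0, b = 4.0, c = 12.0, d = 0.5)
  y0 <- truth["d"] + (truth["a"] - truth["d"]) / (1 + (x / truth["c"])^truth["b"])
  rel_err <- vapply(1:40, function(s) {
    set.seed(s)
    f <- fit_4pl(x, y0 + rnorm(30, 0, 0.05))
    est <- c(a = f$a, b = f$b, c = f$c, d = f$d)
    max(abs(est - truth) / abs(truth))
  }, numeric(1))
  expect_lte(median(rel_err), 0.05)
})

test_that("Expression Score follows Bayes with the 0.49 prior", {
  flat <- structure(
    list(a = 1, b = 1, c = 1, d = 1, rss = 0, converged = TRUE,
      degenerate = TRUE, n = 4, n_dropped = 0),
    class = "four_pl"
  )
  m <- score_model(flat, prior = 0.49)
  expect_equal(as.numeric(expression_score(10, m)), 49, tolerance = 1e-9)
  two <- structure(
    list(a = 2, b = 1e-9, c = 1, d = 2, rss = 0, converged = TRUE,
      degenerate = TRUE, n = 4, n_dropped = 0),
    class = "four_pl"
  )
  m2 <- score_model(two, prior = 0.49)
  # odds 0.9608 * 2 = 1.9216 -> 65.77
  expect_equal(as.numeric(expression_score(10, m2)), 65.77, tolerance = 0.01)
  neg <- structure(
    list(a = -1, b = 1e-9, c = 1, d = -1, rss = 0, converged = TRUE,
      degenerate = TRUE, n = 4, n_dropped = 0),
    class = "four_pl"
  )
  s <- expression_score(10, score_model(neg))
  expect_true(attr(s, "clamped"))
  expect_gte(as.numeric(s), 0)
  expect_error(score_model(flat, prior = 1.2), class = "tir_validation_error")
})

test_that("Expression Score is monotone when the fitted curve decreases", {
  d <- labeled_fixture(2000, seed = 31)
  m <- fit_score_model(d, prior = mean(d$outcome))
  # sign condition: decreasing 4PL on the data range
  expect_gt((m$fourpl$a - m$fourpl$d) * m$fourpl$b, 0)
  grid <- seq(3, 29, 0.5)
  s <- as.numeric(expression_score(grid, m))
  expect_true(all(diff(s) <= 1e-9))
})

test_that("KS distance matches hand CDFs and the stats oracle", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_distance(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(ks_distance(c(1, 2), c(1, 3)), 0.5)
  set.seed(41)
  a <- rnorm(40)
  b <- rnorm(35, 0.5)
  expect_equal(
    ks_distance(a, b),
    unname(suppressWarnings(ks.test(a, b)$statistic)),
    tolerance = 1e-12
  )
})

test_that("score model serialization round-trips", {
  withr::with_tempfile("js", {
    d <- labeled_fixture(500, seed = 8)
    m <- fit_score_model(d)
    write_score_model(m, js)
    back <- read_score_model(js)
    expect_equal(back$fourpl$a, m$fourpl$a)
    expect_equal(back$fourpl$c, m$fourpl$c)
    expect_equal(back$prior, m$prior)
    expect_equal(
      as.numeric(expression_score(c(5, 15, 25), back)),
      as.numeric(expression_score(c(5, 15, 25), m))
    )
  })
})

test_that("fitted pipeline recovers the generator-implied success probability", {
  # the Expression Score estimates P(success | OE <= t); compare against
  # the same quantity computed from the known generating model
  errs <- vapply(1:8, function(s) {
    d <- labeled_fixture(5000, seed = 600 + s)
    m <- fit_score_model(d, prior = mean(d$outcome))
    gen <- attr(d, "generator")
    p_s <- function(x) 1 / (1 + exp(gen$slope * (x - gen$midpoint)))
    cum_true <- function(t) {
      stats::integrate(p_s, gen$energy_range[1], t)$value /
        (t - gen$energy_range[1])
    }
    grid <- seq(4, 29, 1)
    median(abs(
      as.numeric(expression_score(grid, m)) -
        100 * vapply(grid, cum_true, numeric(1))
    ))
  }, numeric(1))
  expect_lte(median(errs), 5)
})
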