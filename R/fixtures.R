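#' Synthetic labeled expression dataset
#'
#' Fixture generator mirroring the structure of success/failure expression
#' panels: opening energies are drawn uniformly on `energy_range` and the
#' binary outcome is Bernoulli with success probability a decreasing
#' logistic in opening energy,
#' `p(x) = 1 / (1 + exp(slope * (x - midpoint)))`.
#' `slope = 0` makes labels independent of energy with
#' `p = 0.5` at every record.
#'
#' @param n Number of records (>= 20).
#' @param seed Optional integer seed (fixed seed gives a byte-identical
#'   dataset).
#' @param slope Logistic steepness per kcal/mol (>= 0).
#' @param midpoint Energy at which success probability is 0.5 (kcal/mol).
#' @param energy_range Range of the uniform opening-energy spread
#'   (kcal/mol).
#' @return A tibble `id`, `opening_energy`, `outcome` with the generator
#'   parameters attached as the `"generator"` attribute.
#' @export
labeled_fixture <- function(n, seed = NULL, slope = 0.25, midpoint = 12,
                            energy_range = c(2, 30)) {
  if (n < 20) {
    abort("`n` must be at least 20.", class = "tir_validation_error")
  }
  if (slope < 0) {
    abort("`slope` must be >= 0.", class = "tir_validation_error")
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  energy <- runif(n, energy_range[1], energy_range[2])
  p <- fixture_success_prob(energy, slope, midpoint)
  out <- tibble(
    id = sprintf("rec%05d", seq_len(n)),
    opening_energy = energy,
    outcome = as.integer(runif(n) < p)
  )
  attr(out, "generator") <- list(
    n = n, seed = seed, slope = slope, midpoint = midpoint,
    energy_range = energy_range
  )
  out
}

# Generating success probability of the labeled fixture.
fixture_success_prob <- function(energy, slope, midpoint) {
  1 / (1 + exp(slope * (energy - midpoint)))
}

#' Generate several random constructs at once
#'
#' @inheritParams random_construct
#' @param n Number of constructs.
#' @param seed Optional integer seed.
#' @return A construct tibble with `n` rows.
#' @export
random_constructs <- function(n, n_codons, utr5_len = 24, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    random_construct(n_codons, utr5_len, id = sprintf("rand%03d", i))
  }))
}
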