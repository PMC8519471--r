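#' Configuration of the stochastic production simulation
#'
#' Models a panel of reporter constructs spanning opening energies binned
#' on `[bin_low, bin_high)` in steps of `bin_step` kcal/mol (defaults
#' 2-32 step 2, i.e. bin centres 3, 5, ..., 31), each simulated in
#' `n_replicates` seeded replicate runs whose realized opening energy is
#' the bin centre plus Gaussian jitter (`jitter_sd`, truncated positive).
#' Each iteration and cell: plasmid copies are drawn uniformly on
#' `plasmid_range` and transcribed with `transcription_prob`; every mRNA
#' initiates translation with a logistic probability centred at
#' `optimum_energy` with softness `softness`; an mRNA translated more than
#' `decay_limit` times decays with `decay_prob`; a cell whose protein tally
#' exceeds `toxicity_threshold` dies with `death_prob`, otherwise it
#' reproduces with `reproduction_prob`; `baseline_death_prob` applies to
#' every cell. Demographic rates are per iteration and deliberately small
#' so that 100 starting cells grow steadily over the 10,000-iteration
#' horizon instead of overflowing; `death_prob < reproduction_prob` is
#' enforced (viability beats death).
#'
#' @param bin_low,bin_high,bin_step Opening-energy binning (kcal/mol).
#' @param jitter_sd Technical-replicate jitter sd (kcal/mol).
#' @param plasmid_range Integer range of plasmid copies per cell.
#' @param optimum_energy Opening energy at which initiation probability is
#'   0.5 (kcal/mol); energies at or below it are favourable.
#' @param softness Logistic softness of the initiation probability
#'   (kcal/mol).
#' @param decay_limit Translations after which an mRNA becomes
#'   decay-eligible.
#' @param decay_prob Per-iteration decay probability beyond the limit.
#' @param transcription_prob Per-plasmid transcription probability per
#'   round.
#' @param toxicity_threshold Protein copies per cell above which the cell
#'   is burdened.
#' @param reproduction_prob Per-iteration reproduction probability of an
#'   unburdened cell.
#' @param death_prob Additional per-iteration death probability of a
#'   burdened cell (must stay below `reproduction_prob`).
#' @param baseline_death_prob Small always-on death probability.
#' @param initial_cells Starting population.
#' @param max_iterations Iteration cap (simulation also stops at
#'   extinction).
#' @param n_replicates Seeded replicate runs per construct.
#' @param tracked_cap Individually tracked cells; beyond it the population
#'   is subsampled and carried as `tracked x scale` aggregate dynamics.
#' @param record_every Trajectory thinning interval (iterations).
#' @return A `sim_config` list.
#' @export
sim_config <- function(bin_low = 2, bin_high = 32, bin_step = 2,
                       jitter_sd = 1, plasmid_range = c(30L, 60L),
                       optimum_energy = 12, softness = 2,
                       decay_limit = 10, decay_prob = 0.5,
                       transcription_prob = 0.5,
                       toxicity_threshold = 1e6,
                       reproduction_prob = 2.5e-4, death_prob = 2e-4,
                       baseline_death_prob = 1e-4,
                       initial_cells = 100, max_iterations = 10000,
                       n_replicates = 3, tracked_cap = 100,
                       record_every = 50) {
  if (bin_step <= 0) abort("`bin_step` must be > 0.", class = "tir_validation_error")
  if (death_prob >= reproduction_prob) {
    abort("`death_prob` must stay below `reproduction_prob`.",
      class = "tir_validation_error"
    )
  }
  if (tracked_cap < initial_cells) {
    abort("`tracked_cap` must be at least `initial_cells`.",
      class = "tir_validation_error"
    )
  }
  structure(
    list(
      bin_low = bin_low, bin_high = bin_high, bin_step = bin_step,
      jitter_sd = jitter_sd,
      plasmid_range = as.integer(plasmid_range),
      optimum_energy = optimum_energy, softness = softness,
      decay_limit = as.integer(decay_limit), decay_prob = decay_prob,
      transcription_prob = transcription_prob,
      toxicity_threshold = toxicity_threshold,
      reproduction_prob = reproduction_prob, death_prob = death_prob,
      baseline_death_prob = baseline_death_prob,
      initial_cells = as.integer(initial_cells),
      max_iterations = as.integer(max_iterations),
      n_replicates = as.integer(n_replicates),
      tracked_cap = as.integer(tracked_cap),
      record_every = as.integer(record_every)
    ),
    class = "sim_config"
  )
}

# Parameter list handed to the C++ core.
sim_pars <- function(config) {
  list(
    plasmid_lo = config$plasmid_range[1],
    plasmid_hi = config$plasmid_range[2],
    transcription_prob = config$transcription_prob,
    decay_limit = config$decay_limit,
    decay_prob = config$decay_prob,
    toxicity_threshold = config$toxicity_threshold,
    reproduction_prob = config$reproduction_prob,
    death_prob = config$death_prob,
    baseline_death_prob = config$baseline_death_prob,
    initial_cells = config$initial_cells,
    tracked_cap = config$tracked_cap
  )
}

#' Nominal opening energies of the simulated construct panel
#'
#' @param config A [sim_config()].
#' @return Bin centres in kcal/mol (3, 5, ..., 31 by default).
#' @export
sim_bin_centers <- function(config = sim_config()) {
  edges <- seq(config$bin_low, config$bin_high, by = config$bin_step)
  (edges[-length(edges)] + edges[-1]) / 2
}

#' Translation-initiation probability at an opening energy
#'
#' Logistic gate `1 / (1 + exp((energy - optimum) / softness))`: 0.5 at the
#' optimum cutoff, above 0.5 for favourable (lower) energies, and strictly
#' decreasing.
#'
#' @param energy Opening energies (kcal/mol); vectorized.
#' @param config A [sim_config()].
#' @return Probabilities in `[0, 1]`.
#' @export
initiation_probability <- function(energy, config = sim_config()) {
  1 / (1 + exp((energy - config$optimum_energy) / config$softness))
}

#' Construct panel with technical-replicate energies
#'
#' One construct per opening-energy bin; each replicate's realized energy
#' is the bin centre plus Gaussian jitter, truncated to stay positive.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble `construct`, `nominal_energy`, `replicate`,
#'   `realized_energy`.
#' @export
make_construct_panel <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  centers <- sim_bin_centers(config)
  grid <- tidyr::expand_grid(
    construct = seq_along(centers),
    replicate = seq_len(config$n_replicates)
  )
  grid$nominal_energy <- centers[grid$construct]
  jitter <- rnorm(nrow(grid), 0, config$jitter_sd)
  grid$realized_energy <- pmax(1e-3, grid$nominal_energy + jitter)
  grid[, c("construct", "nominal_energy", "replicate", "realized_energy")]
}

#' Advance a simulation state
#'
#' Runs `iterations` rounds of transcription, translation, decay and
#' demography for one construct at a fixed realized opening energy.
#' `state = NULL` starts a fresh population of empty cells.
#'
#' @param realized_energy Realized opening energy (kcal/mol).
#' @param config A [sim_config()].
#' @param state A state list from a previous call (or `NULL`).
#' @param iterations Number of iterations to advance (default 1).
#' @return A list with `proteins`, `cells`, `mrna`, `proteins_per_cell`,
#'   `extinct`, `iteration`, `state` and a `trajectory` tibble.
#' @export
sim_step <- function(realized_energy, config = sim_config(), state = NULL,
                     iterations = 1) {
  p_init <- initiation_probability(realized_energy, config)
  res <- sim_run_cpp(
    p_init, as.integer(iterations), sim_pars(config),
    state_in = state, record_every = config$record_every
  )
  res$trajectory <- as_tibble(res$trajectory)
  res
}

#' Run the full production simulation
#'
#' Simulates every construct of the panel in every replicate run with
#' independent seeded streams and extracts endpoint protein and cell
#' counts.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; per-replicate streams are derived from it.
#' @return An object of class `sim_result`: list with `endpoints` (tibble:
#'   construct, replicate, nominal_energy, realized_energy, proteins,
#'   cells, proteins_per_cell, extinct), `trajectories` (thinned tibble)
#'   and `config`.
#' @export
run_simulation <- function(config = sim_config(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  panel <- make_construct_panel(config)
  row_seeds <- sample.int(.Machine$integer.max - 1L, nrow(panel))
  runs <- purrr::map(seq_len(nrow(panel)), function(i) {
    set.seed(row_seeds[i])
    res <- sim_step(
      panel$realized_energy[i], config,
      state = NULL, iterations = config$max_iterations
    )
    traj <- dplyr::mutate(
      res$trajectory,
      construct = panel$construct[i], replicate = panel$replicate[i]
    )
    list(
      endpoint = tibble(
        construct = panel$construct[i],
        replicate = panel$replicate[i],
        nominal_energy = panel$nominal_energy[i],
        realized_energy = panel$realized_energy[i],
        proteins = res$proteins,
        cells = res$cells,
        proteins_per_cell = res$proteins_per_cell,
        extinct = res$extinct
      ),
      trajectory = traj
    )
  })
  out <- list(
    endpoints = dplyr::bind_rows(purrr::map(runs, "endpoint")),
    trajectories = dplyr::bind_rows(purrr::map(runs, "trajectory")),
    config = config,
    seed = seed
  )
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result: %d constructs x %d replicates, %d iterations max>\n",
    dplyr::n_distinct(x$endpoints$construct),
    x$config$n_replicates, x$config$max_iterations
  ))
  print(summarize_simulation(x))
  invisible(x)
}

#' @export
tidy.sim_result <- function(x, ...) x$endpoints

#' Summary statistics of a simulation
#'
#' Spearman correlations of opening energy against per-cell protein yield
#' (the in-silico analogue of relative cellular fluorescence) over
#' replicate-level points and over replicate averages, and of protein
#' yield against endpoint cell count (the protein-cost signature).
#' Degenerate (constant) inputs yield `NA` correlations.
#'
#' @param result A [run_simulation()] result.
#' @return A one-row tibble of correlations.
#' @export
summarize_simulation <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  ep <- result$endpoints
  avg <- ep |>
    dplyr::group_by(.data$construct, .data$nominal_energy) |>
    dplyr::summarise(
      proteins_per_cell = mean(.data$proteins_per_cell, na.rm = TRUE),
      cells = mean(.data$cells),
      .groups = "drop"
    )
  safe_spearman <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(a[ok], b[ok], method = "spearman")
  }
  tibble(
    spearman_energy_yield_replicates = safe_spearman(
      ep$nominal_energy, ep$proteins_per_cell
    ),
    spearman_energy_yield_averaged = safe_spearman(
      avg$nominal_energy, avg$proteins_per_cell
    ),
    spearman_yield_cells_averaged = safe_spearman(
      avg$proteins_per_cell, avg$cells
    ),
    n_extinct = sum(ep$extinct)
  )
}

#' Plot simulated yields and growth
#'
#' @param object A `sim_result`.
#' @param ... Ignored.
#' @return A ggplot of per-cell protein yield against opening energy
#'   (replicates as open circles, replicate means filled).
#' @export
autoplot.sim_result <- function(object, ...) {
  ep <- object$endpoints
  avg <- ep |>
    dplyr::group_by(.data$nominal_energy) |>
    dplyr::summarise(
      proteins_per_cell = mean(.data$proteins_per_cell, na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(ep, ggplot2::aes(
    x = .data$nominal_energy, y = .data$proteins_per_cell
  )) +
    ggplot2::geom_point(shape = 1, alpha = 0.7) +
    ggplot2::geom_point(data = avg, colour = "purple", size = 3) +
    ggplot2::labs(
      x = "opening energy (kcal/mol)",
      y = "proteins per cell at endpoint"
    ) +
    ggplot2::theme_minimal()
}

#' Export simulation endpoints
#'
#' Writes the endpoint table as delimited text (construct, replicate,
#' opening_energy, proteins, cells, proteins_per_cell).
#'
#' @param result A `sim_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_endpoints <- function(result, path) {
  stopifnot(inherits(result, "sim_result"))
  ep <- result$endpoints[, c(
    "construct", "replicate", "nominal_energy", "realized_energy",
    "proteins", "cells", "proteins_per_cell"
  )]
  utils::write.table(ep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
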