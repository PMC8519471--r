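#' Annealing configuration
#'
#' Schedule, constraints and objective for synonymous-codon optimization.
#' Substitutions are restricted to the first `n_codons` codons after the
#' start codon (default 9, the PCR-amenable window); `n_codons = "full"`
#' frees every codon between start and stop. Cooling is exponential,
#' `T(k) = t0 * cooling^k`, and each move substitutes
#' `max(1, round(T/T0 * n_replaceable))` codons, so the first move is
#' drastic (all replaceable codons) and late moves are single-codon.
#' Candidate sequences containing a forbidden motif (on either strand) are
#' rejected at proposal time; the defaults are the AarI, BsaI and BsmBI
#' recognition sites.
#'
#' @param n_codons Number of substitutable codons after the start codon, or
#'   `"full"`.
#' @param chains Number of independent annealing chains.
#' @param max_iterations Iteration cap per chain.
#' @param t0 Initial temperature (in units of kcal/mol energy differences).
#' @param cooling Exponential cooling constant in (0, 1).
#' @param patience Stop a chain after this many iterations without
#'   improvement of the best energy.
#' @param seed Optional integer seed (fixed seed gives a byte-identical
#'   result).
#' @param objective `"minimize"` (maximize accessibility, the default),
#'   `"maximize"`, or a numeric target opening energy to approach.
#' @param forbidden_motifs Named character vector of motifs to avoid.
#' @param region Scoring region for the default energy function.
#' @param fold A [fold_config()] for the default energy function.
#' @return An `anneal_config` list.
#' @export
anneal_config <- function(n_codons = 9, chains = 10, max_iterations = 1000,
                          t0 = 1, cooling = 0.99, patience = 200,
                          seed = NULL, objective = "minimize",
                          forbidden_motifs = c(
                            AarI = "CACCTGC", BsaI = "GGTCTC", BsmBI = "CGTCTC"
                          ),
                          region = host_region("E. coli"),
                          fold = fold_config()) {
  if (chains < 1) abort("`chains` must be >= 1.", class = "tir_validation_error")
  if (t0 <= 0) abort("`t0` must be > 0.", class = "tir_validation_error")
  if (cooling <= 0 || cooling >= 1) {
    abort("`cooling` must be in (0, 1).", class = "tir_validation_error")
  }
  if (!(identical(objective, "minimize") || identical(objective, "maximize") ||
    (is.numeric(objective) && length(objective) == 1))) {
    abort("`objective` must be 'minimize', 'maximize' or a numeric target.",
      class = "tir_validation_error"
    )
  }
  structure(
    list(
      n_codons = n_codons, chains = as.integer(chains),
      max_iterations = as.integer(max_iterations), t0 = t0,
      cooling = cooling, patience = as.integer(patience), seed = seed,
      objective = objective, forbidden_motifs = forbidden_motifs,
      region = region, fold = fold
    ),
    class = "anneal_config"
  )
}

#' Codon positions open to synonymous substitution
#'
#' The start codon is never substitutable and neither is the final (stop)
#' codon: for `n_codons = k` the replaceable indices are `2 .. k + 1`,
#' clipped (with a warning) when the cds is too short; `"full"` gives
#' `2 .. L - 1`.
#'
#' @param construct A coding construct.
#' @param n_codons Integer or `"full"`.
#' @return Integer vector of 1-based codon indices.
#' @export
replaceable_positions <- function(construct, n_codons = 9) {
  construct <- as_construct(construct)
  n_total <- nchar(construct$cds) / 3L
  upper <- n_total - 1L
  if (identical(n_codons, "full")) {
    k_end <- upper
  } else {
    k_end <- n_codons + 1L
    if (k_end > upper) {
      warn(sprintf(
        "Only %d codons available for substitution (requested %d); clipping.",
        max(0L, upper - 1L), as.integer(n_codons)
      ))
      k_end <- upper
    }
  }
  if (k_end < 2L) {
    return(integer(0))
  }
  seq(2L, k_end)
}

#' Size of the synonymous search space
#'
#' Product over replaceable codons of their synonym-set sizes, minus one
#' (the input itself).
#'
#' @inheritParams replaceable_positions
#' @return Number of distinct synonymous variants excluding the input.
#' @export
count_search_space <- function(construct, n_codons = 9) {
  construct <- as_construct(construct)
  codons <- split_codons(construct$cds)
  pos <- replaceable_positions(construct, n_codons)
  if (length(pos) == 0) {
    return(0)
  }
  prod(vapply(codons[pos], function(cd) length(synonymous_codons(cd)), numeric(1))) - 1
}

#' Screen a sequence for forbidden motifs
#'
#' Fails iff any motif occurs in the sequence or its reverse complement.
#'
#' @param seq Nucleotide string.
#' @param motifs Character vector of motifs (may be empty).
#' @return A list with `pass` (logical) and `hits` (tibble `motif`,
#'   `strand`, `position`).
#' @export
motif_filter <- function(seq, motifs) {
  seq <- normalize_sequence(seq)
  hits <- tibble(
    motif = character(0), strand = character(0), position = integer(0)
  )
  for (nm in seq_along(motifs)) {
    m <- normalize_sequence(motifs[[nm]])
    label <- names(motifs)[nm] %||% m
    if (is.null(names(motifs)) || !nzchar(label)) label <- m
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") m else reverse_complement(m)
      found <- gregexpr(pat, seq, fixed = TRUE)[[1]]
      if (found[1] > 0) {
        hits <- dplyr::bind_rows(hits, tibble(
          motif = label, strand = strand, position = as.integer(found)
        ))
      }
    }
  }
  list(pass = nrow(hits) == 0, hits = hits)
}

#' Metropolis acceptance rule
#'
#' Improving moves (toward the objective) are always accepted; worsening
#' moves are accepted with probability `exp(-|dE| / temperature)`.
#'
#' @param e_new,e_old Energies (kcal/mol) of candidate and current state,
#'   already mapped so that smaller is better.
#' @param temperature Current temperature (> 0).
#' @return Logical: accept the candidate?
#' @export
metropolis_accept <- function(e_new, e_old, temperature) {
  if (temperature <= 0) {
    abort("`temperature` must be > 0.", class = "tir_validation_error")
  }
  if (e_new <= e_old) {
    return(TRUE)
  }
  runif(1) < exp(-(e_new - e_old) / temperature)
}

# Map a raw opening energy onto the 'smaller is better' scale used by the
# chain: identity for minimize, negation for maximize, |E - target| for a
# numeric target.
objective_value <- function(energy, objective) {
  if (identical(objective, "minimize")) {
    energy
  } else if (identical(objective, "maximize")) {
    -energy
  } else {
    abs(energy - objective)
  }
}

#' Propose a synonymous move
#'
#' Substitutes `m = max(1, round(temperature / t0 * n_replaceable))` codons
#' chosen uniformly without replacement among the replaceable positions
#' that have alternative synonyms, each to a uniformly chosen different
#' synonym. At `temperature = t0` the move touches every replaceable codon;
#' as the chain cools it degenerates to single-codon moves.
#'
#' @param codons Character vector of current codons.
#' @param positions Replaceable codon indices with >= 2 synonyms.
#' @param temperature Current temperature.
#' @param t0 Initial temperature.
#' @return The mutated codon vector.
#' @export
propose_move <- function(codons, positions, temperature, t0) {
  if (length(positions) == 0) {
    abort("No replaceable codon has an alternative synonym.",
      class = "tir_validation_error"
    )
  }
  m <- max(1L, min(
    length(positions),
    as.integer(round(temperature / t0 * length(positions)))
  ))
  targets <- if (length(positions) == 1) positions else sample(positions, m)
  for (p in targets) {
    alts <- setdiff(synonymous_codons(codons[p]), codons[p])
    codons[p] <- if (length(alts) == 1) alts else sample(alts, 1)
  }
  codons
}

#' Optimize accessibility by simulated annealing
#'
#' Runs `chains` independent annealing chains over synonymous variants of
#' the first `n_codons` codons, scoring each candidate with `energy_fn`
#' (default: opening energy of the configured region). The best-so-far
#' sequence per chain is retained; solutions are deduplicated across
#' chains, screened against the forbidden motifs, and ranked by the
#' objective.
#'
#' @param construct A coding construct.
#' @param config An [anneal_config()].
#' @param energy_fn Function `construct -> kcal/mol`; defaults to
#'   [opening_energy()] with the config's region and fold settings.
#' @return An object of class `anneal_result`: list with `input` (tibble of
#'   the input sequence and energy), `solutions` (ranked tibble), `trajectory`
#'   (per chain/iteration tibble) and `config`.
#' @export
anneal <- function(construct, config = anneal_config(), energy_fn = NULL) {
  construct <- as_construct(construct)
  if (is.null(energy_fn)) {
    energy_fn <- function(cons) {
      opening_energy(cons, config$region, config$fold)
    }
  }
  if (!is.null(config$seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed)
  }
  codons0 <- split_codons(construct$cds)
  pos <- replaceable_positions(construct, config$n_codons)
  pos <- pos[vapply(
    codons0[pos],
    function(cd) length(synonymous_codons(cd)) > 1, logical(1)
  )]
  e_input <- energy_fn(construct)
  input_tbl <- tibble(
    id = construct$id, cds = construct$cds, opening_energy = e_input
  )
  empty_solutions <- tibble(
    rank = integer(0), cds = character(0), opening_energy = numeric(0),
    n_substitutions = integer(0), codons_changed = integer(0),
    chain = integer(0)
  )
  if (length(pos) == 0) {
    warn("No substitutable codons; returning the input sequence.")
    res <- list(
      input = input_tbl,
      solutions = tibble(
        rank = 1L, cds = construct$cds, opening_energy = e_input,
        n_substitutions = 0L, codons_changed = 0L, chain = NA_integer_
      ),
      trajectory = tibble(
        chain = integer(0), iteration = integer(0), temperature = numeric(0),
        energy = numeric(0), accepted = logical(0)
      ),
      config = config
    )
    class(res) <- "anneal_result"
    return(res)
  }

  candidate_ok <- function(codons) {
    cand <- paste(codons, collapse = "")
    seq_full <- paste0(construct$utr5, cand, construct$utr3)
    motif_filter(seq_full, config$forbidden_motifs)$pass
  }

  run_chain <- function(chain_id) {
    codons <- codons0
    e_cur <- objective_value(e_input, config$objective)
    best_codons <- codons
    best_e <- e_cur
    best_raw <- e_input
    since_improved <- 0L
    traj <- vector("list", config$max_iterations)
    k <- 0L
    while (k < config$max_iterations && since_improved < config$patience) {
      k <- k + 1L
      temp <- config$t0 * config$cooling^(k - 1L)
      cand <- NULL
      for (try in 1:25) {
        prop <- propose_move(codons, pos, temp, config$t0)
        if (candidate_ok(prop)) {
          cand <- prop
          break
        }
      }
      if (is.null(cand)) {
        traj[[k]] <- tibble(
          chain = chain_id, iteration = k, temperature = temp,
          energy = NA_real_, accepted = FALSE
        )
        next
      }
      cons_cand <- construct
      cons_cand$cds <- paste(cand, collapse = "")
      e_raw <- energy_fn(cons_cand)
      e_new <- objective_value(e_raw, config$objective)
      accept <- metropolis_accept(e_new, e_cur, temp)
      if (accept) {
        codons <- cand
        e_cur <- e_new
        if (e_new < best_e) {
          best_e <- e_new
          best_codons <- cand
          best_raw <- e_raw
          since_improved <- 0L
        } else {
          since_improved <- since_improved + 1L
        }
      } else {
        since_improved <- since_improved + 1L
      }
      traj[[k]] <- tibble(
        chain = chain_id, iteration = k, temperature = temp,
        energy = e_raw, accepted = accept
      )
    }
    list(
      best = tibble(
        cds = paste(best_codons, collapse = ""),
        opening_energy = best_raw, chain = chain_id
      ),
      trajectory = dplyr::bind_rows(traj[!vapply(traj, is.null, logical(1))])
    )
  }

  chains <- lapply(seq_len(config$chains), run_chain)
  sols <- dplyr::bind_rows(purrr::map(chains, "best"))
  sols <- dplyr::distinct(sols, .data$cds, .keep_all = TRUE)
  keep <- vapply(sols$cds, function(s) {
    motif_filter(paste0(construct$utr5, s, construct$utr3),
      config$forbidden_motifs
    )$pass
  }, logical(1))
  sols <- sols[keep, , drop = FALSE]
  if (nrow(sols) == 0) {
    warn("All annealing solutions hit a forbidden motif; returning input.")
    sols <- tibble(
      cds = construct$cds, opening_energy = e_input, chain = NA_integer_
    )
  }
  subs <- purrr::map_int(sols$cds, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(construct$cds, "")[[1]])
  })
  changed <- purrr::map_int(sols$cds, function(s) {
    sum(split_codons(s) != codons0)
  })
  sols <- dplyr::mutate(sols,
    n_substitutions = subs, codons_changed = changed,
    .obj = objective_value(.data$opening_energy, config$objective)
  )
  sols <- dplyr::arrange(sols, .data$.obj, .data$cds)
  sols <- dplyr::mutate(sols, rank = dplyr::row_number())
  sols <- dplyr::select(
    sols, "rank", "cds", "opening_energy", "n_substitutions",
    "codons_changed", "chain"
  )
  res <- list(
    input = input_tbl,
    solutions = sols,
    trajectory = dplyr::bind_rows(purrr::map(chains, "trajectory")),
    config = config
  )
  class(res) <- "anneal_result"
  res
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf(
    "<anneal_result: input %.3f kcal/mol -> best %.3f kcal/mol, %d solution(s)>\n",
    x$input$opening_energy, x$solutions$opening_energy[1], nrow(x$solutions)
  ))
  print(x$solutions, ...)
  invisible(x)
}

#' @export
tidy.anneal_result <- function(x, ...) x$solutions

#' @export
glance.anneal_result <- function(x, ...) {
  tibble(
    input_energy = x$input$opening_energy,
    best_energy = x$solutions$opening_energy[1],
    n_solutions = nrow(x$solutions),
    chains = x$config$chains,
    iterations_run = nrow(x$trajectory)
  )
}

#' Plot annealing trajectories
#'
#' @param object An `anneal_result`.
#' @param ... Ignored.
#' @return A ggplot of energy against iteration per chain.
#' @export
autoplot.anneal_result <- function(object, ...) {
  ggplot2::ggplot(
    object$trajectory,
    ggplot2::aes(
      x = .data$iteration, y = .data$energy,
      colour = factor(.data$chain)
    )
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_hline(
      yintercept = object$input$opening_energy, linetype = 2
    ) +
    ggplot2::labs(
      x = "iteration", y = "opening energy (kcal/mol)", colour = "chain"
    ) +
    ggplot2::theme_minimal()
}

#' Exhaustive synonymous optimum
#'
#' Enumerates every synonymous variant of the replaceable codons (guarded
#' by `limit`) and returns the global optimum of `energy_fn` among variants
#' passing the motif filter. Serves as the oracle for annealing tests.
#'
#' @inheritParams anneal
#' @param limit Refuse enumeration when the search space exceeds this.
#' @return A list with `cds`, `opening_energy`, `n_enumerated`.
#' @export
exhaustive_optimum <- function(construct, config = anneal_config(),
                               energy_fn = NULL, limit = 50000) {
  construct <- as_construct(construct)
  if (is.null(energy_fn)) {
    energy_fn <- function(cons) {
      opening_energy(cons, config$region, config$fold)
    }
  }
  space <- count_search_space(construct, config$n_codons)
  if (space > limit) {
    abort(
      sprintf("Search space of %s variants exceeds the limit %s.",
        format(space, big.mark = ","), format(limit, big.mark = ",")
      ),
      class = "tir_validation_error"
    )
  }
  codons0 <- split_codons(construct$cds)
  pos <- replaceable_positions(construct, config$n_codons)
  sets <- lapply(codons0[pos], synonymous_codons)
  combos <- if (length(sets) == 0) {
    list(character(0))
  } else {
    grid <- do.call(tidyr::expand_grid, setNames(sets, paste0("p", seq_along(sets))))
    purrr::pmap(grid, function(...) c(...))
  }
  best <- NULL
  n_eval <- 0L
  for (combo in combos) {
    codons <- codons0
    codons[pos] <- combo
    cds <- paste(codons, collapse = "")
    full <- paste0(construct$utr5, cds, construct$utr3)
    if (!motif_filter(full, config$forbidden_motifs)$pass) next
    cons <- construct
    cons$cds <- cds
    e_raw <- energy_fn(cons)
    e_obj <- objective_value(e_raw, config$objective)
    n_eval <- n_eval + 1L
    if (is.null(best) || e_obj < best$obj ||
      (e_obj == best$obj && cds < best$cds)) {
      best <- list(cds = cds, opening_energy = e_raw, obj = e_obj)
    }
  }
  if (is.null(best)) {
    abort("Every variant hit a forbidden motif.", class = "tir_validation_error")
  }
  list(
    cds = best$cds, opening_energy = best$opening_energy,
    n_enumerated = n_eval
  )
}
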