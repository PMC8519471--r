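#' Folding-engine configuration
#'
#' The accessibility of a region is computed by a pluggable engine. The
#' `production` engine shells out to ViennaRNA (`RNAplfold`, `RNAfold`)
#' using sliding windows of width `window` (nt) and unpaired stretches up to
#' `max_stretch` (nt), both 210 by default. The `toy` engine is a
#' self-contained nested-structure partition function with a uniform,
#' deliberately non-physical per-pair energy (`pair_energy`, default -1
#' kcal/mol) and a minimum hairpin loop of `min_hairpin` unpaired nt; it
#' folds the full sequence exactly and exists so that every opening-energy
#' bookkeeping step can be verified against brute-force enumeration.
#'
#' @param engine `"toy"` or `"production"`.
#' @param window Sliding-window width W in nt (production engine).
#' @param max_stretch Longest unpaired stretch u in nt.
#' @param temperature Temperature in Celsius (default 37; the thermal
#'   energy RT is 0.6163 kcal/mol at 37).
#' @param pair_energy Toy-model energy per base pair, kcal/mol (< 0).
#' @param min_hairpin Toy-model minimum hairpin loop, nt.
#' @return A `fold_config` list.
#' @export
fold_config <- function(engine = c("toy", "production"), window = 210,
                        max_stretch = 210, temperature = 37,
                        pair_energy = -1, min_hairpin = 3) {
  engine <- match.arg(engine)
  if (max_stretch < 1 || max_stretch > window) {
    abort("Need 1 <= max_stretch <= window.", class = "tir_validation_error")
  }
  if (pair_energy >= 0) {
    abort("`pair_energy` must be negative.", class = "tir_validation_error")
  }
  structure(
    list(
      engine = engine, window = as.integer(window),
      max_stretch = as.integer(max_stretch), temperature = temperature,
      pair_energy = pair_energy, min_hairpin = as.integer(min_hairpin)
    ),
    class = "fold_config"
  )
}

# Encode a DNA string as integers 0=A, 1=C, 2=G, 3=T.
encode_seq <- function(seq) {
  match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
}

#' Is the production folding engine available?
#'
#' @return `TRUE` when the ViennaRNA command-line tools are on the PATH.
#' @export
production_engine_available <- function() {
  nzchar(Sys.which("RNAplfold")) && nzchar(Sys.which("RNAfold"))
}

#' @rdname production_engine_available
#' @param config A [fold_config()].
#' @return `engine_info()`: list with engine `name` and `version`.
#' @export
engine_info <- function(config = fold_config()) {
  if (config$engine == "toy") {
    return(list(name = "toy-partition", version = "internal"))
  }
  if (!production_engine_available()) {
    return(list(name = "ViennaRNA", version = NA_character_))
  }
  v <- tryCatch(
    system2("RNAplfold", "--version", stdout = TRUE, stderr = TRUE)[1],
    error = function(e) NA_character_
  )
  list(name = "ViennaRNA", version = v)
}

require_production_engine <- function() {
  if (!production_engine_available()) {
    abort(
      paste(
        "Production folding engine unavailable: RNAplfold/RNAfold not on",
        "PATH. The adapter contract is: given (sequence, W, u) return the",
        "probability that the stretch of length u ending at each position",
        "is unpaired. Install ViennaRNA or use fold_config(engine = 'toy')."
      ),
      class = "tir_dependency_error"
    )
  }
}

# Run RNAplfold on one sequence; returns the lunp matrix (row = end
# position, column = stretch length, value = unpaired probability).
run_rnaplfold <- function(seq, window, max_u, temperature = 37) {
  require_production_engine()
  dir <- tempfile("plfold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fa <- file.path(dir, "query.fa")
  writeLines(c(">query", seq), fa)
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  status <- system2(
    "RNAplfold",
    c("-W", window, "-u", max_u, "-T", temperature),
    stdin = fa, stdout = FALSE, stderr = FALSE
  )
  if (status != 0 || !file.exists("query_lunp")) {
    abort("RNAplfold failed.", class = "tir_dependency_error")
  }
  lunp <- utils::read.table("query_lunp", skip = 2, fill = TRUE)
  as.matrix(lunp[, -1, drop = FALSE])
}

#' Probability that an interval is unpaired
#'
#' The probability, over the Boltzmann ensemble of secondary structures,
#' that every nucleotide of the zero-based half-open `interval` of `seq` is
#' unpaired. The production engine computes it over sliding windows of
#' width `window`; the toy engine computes it exactly over the full
#' sequence as `Z_unpaired / Z`.
#'
#' @param seq Nucleotide string (normalized internally).
#' @param interval Integer `c(from, to)`, zero-based half-open.
#' @param config A [fold_config()].
#' @return Probability in (0, 1].
#' @export
unpaired_probability <- function(seq, interval, config = fold_config()) {
  seq <- normalize_sequence(seq)
  from <- as.integer(interval[[1]])
  to <- as.integer(interval[[2]])
  n <- nchar(seq)
  len <- to - from
  if (from < 0 || to > n || len < 1) {
    abort("`interval` must be a non-empty range within `seq`.",
      class = "tir_bounds_error"
    )
  }
  if (len > config$max_stretch) {
    abort(
      sprintf("Interval length %d exceeds max_stretch %d.", len, config$max_stretch),
      class = "tir_bounds_error"
    )
  }
  if (config$engine == "toy") {
    enc <- encode_seq(seq)
    w <- exp(-config$pair_energy / rt_kcal(config$temperature))
    z <- toy_partition_cpp(enc, w, config$min_hairpin, 0L, 0L)
    zu <- toy_partition_cpp(enc, w, config$min_hairpin, from, to)
    zu / z
  } else {
    lunp <- run_rnaplfold(seq, min(config$window, n), len, config$temperature)
    p <- lunp[to, len]
    if (is.na(p)) {
      abort("Engine returned no probability for the requested stretch.",
        class = "tir_dependency_error"
      )
    }
    p
  }
}

#' Opening energy of an anchored region
#'
#' The pseudo-energy required to make the region single-stranded:
#' `-RT * log(p_unpaired)` over the Boltzmann ensemble, in kcal/mol; always
#' >= 0, and 0 exactly when no structure pairs any base of the region.
#'
#' @param construct A coding construct (one-row tibble or list).
#' @param region A [region()] (default the E. coli preset -24:24).
#' @param config A [fold_config()].
#' @return Opening energy in kcal/mol.
#' @examples
#' oe <- opening_energy(
#'   coding_construct(strrep("A", 48), id = "polyA"),
#'   region(1, 12)
#' )
#' @export
opening_energy <- function(construct, region = host_region("E. coli"),
                           config = fold_config()) {
  construct <- as_construct(construct)
  off <- region_to_offsets(region, construct)
  p <- unpaired_probability(construct_sequence(construct), off, config)
  max(0, -rt_kcal(config$temperature) * log(p))
}

#' Minimum free energy of an anchored region
#'
#' Folds the excised region sequence on its own and reports the free energy
#' of the single most stable structure. The default region -30:30 is the
#' classical MFE window around the start codon.
#'
#' @inheritParams opening_energy
#' @return MFE in kcal/mol (<= 0).
#' @export
mfe_region <- function(construct, region = NULL, config = fold_config()) {
  if (is.null(region)) region <- tirdesign::region(-30, 30)
  construct <- as_construct(construct)
  seq <- region_sequence(region, construct)
  if (config$engine == "toy") {
    config$pair_energy * toy_max_pairs_cpp(encode_seq(seq), config$min_hairpin)
  } else {
    require_production_engine()
    out <- system2("RNAfold", c("--noPS", "-T", config$temperature),
      input = c(">q", seq), stdout = TRUE, stderr = FALSE
    )
    m <- regmatches(out[3], regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)$", out[3]))
    if (length(m) == 0) {
      abort("Could not parse RNAfold output.", class = "tir_dependency_error")
    }
    as.numeric(gsub("[() ]", "", m))
  }
}

#' Opening-energy profile over an (end position, length) grid
#'
#' Computes the opening energy of every region `endpos_len_to_region(i, l)`
#' for `i` in `end_positions` and `l` in `lengths`. Cells whose region
#' extends past the available flanks are undefined (`NA`), never zero.
#'
#' @param construct A coding construct.
#' @param lengths Integer vector of sub-sequence lengths l.
#' @param end_positions Integer vector of anchored end positions i.
#' @param config A [fold_config()].
#' @return A tibble of class `tir_profile` with columns `i`, `l`,
#'   `region_start`, `region_end`, `opening_energy`.
#' @export
scan_profile <- function(construct, lengths, end_positions,
                         config = fold_config()) {
  if (length(lengths) == 0 || length(end_positions) == 0) {
    abort("Empty scan grid.", class = "tir_validation_error")
  }
  construct <- as_construct(construct)
  grid <- tidyr::expand_grid(i = as.integer(end_positions), l = as.integer(lengths))
  seq <- construct_sequence(construct)
  n <- nchar(seq)

  lunp <- NULL
  if (config$engine == "production") {
    max_l <- min(max(lengths), config$max_stretch)
    lunp <- run_rnaplfold(seq, min(config$window, n), max_l, config$temperature)
  }
  cell <- function(i, l) {
    if (i == 0L || l < 1L || l > config$max_stretch) {
      return(list(start = NA_integer_, end = NA_integer_, oe = NA_real_))
    }
    reg <- endpos_len_to_region(i, l)
    off <- tryCatch(region_to_offsets(reg, construct), error = function(e) NULL)
    if (is.null(off)) {
      return(list(start = reg$start, end = reg$end, oe = NA_real_))
    }
    oe <- if (is.null(lunp)) {
      opening_energy(construct, reg, config)
    } else {
      p <- lunp[off[["to"]], l]
      if (is.na(p)) NA_real_ else max(0, -rt_kcal(config$temperature) * log(p))
    }
    list(start = reg$start, end = reg$end, oe = oe)
  }
  cells <- purrr::pmap(grid, function(i, l) cell(i, l))
  out <- dplyr::mutate(grid,
    region_start = purrr::map_int(cells, "start"),
    region_end = purrr::map_int(cells, "end"),
    opening_energy = purrr::map_dbl(cells, "oe")
  )
  if (all(is.na(out$opening_energy))) {
    abort("No valid (i, l) cell in the scan grid.", class = "tir_bounds_error")
  }
  attr(out, "engine") <- engine_info(config)
  class(out) <- c("tir_profile", class(out))
  out
}

#' Plot an opening-energy profile
#'
#' @param object A profile from [scan_profile()].
#' @param ... Ignored.
#' @return A ggplot heatmap of opening energy over the (i, l) grid.
#' @export
autoplot.tir_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$i, y = .data$l)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$opening_energy)) +
    ggplot2::scale_fill_viridis_c(name = "opening energy\n(kcal/mol)") +
    ggplot2::labs(
      x = "end position i (start-codon anchored)",
      y = "sub-sequence length l (nt)"
    ) +
    ggplot2::theme_minimal()
}

#' Brute-force partition oracle for the toy energy model
#'
#' Enumerates every nested secondary structure (Watson-Crick + GU pairs,
#' minimum hairpin loop `min_hairpin`) of a short sequence and sums
#' Boltzmann weights directly: `Z = sum(exp(-E/RT))` with
#' `E = pair_energy * n_pairs`, and `Z_unpaired` restricted to structures
#' leaving `interval` unpaired. Independent of the dynamic-programming toy
#' engine; used to verify it exactly.
#'
#' @param seq Nucleotide string, at most `max_n` nt.
#' @param interval Optional zero-based half-open interval for `Z_unpaired`.
#' @param config A [fold_config()] (toy parameters are used).
#' @param max_n Enumeration guard (default 30 nt).
#' @return List with `z`, `z_unpaired`, `p_unpaired`, `n_structures`,
#'   `mfe`, and `structures` (list of 2-column pair matrices).
#' @export
toy_partition_oracle <- function(seq, interval = NULL,
                                 config = fold_config(), max_n = 30) {
  seq <- normalize_sequence(seq)
  n <- nchar(seq)
  if (n > max_n) {
    abort(
      sprintf("Sequence of %d nt exceeds the enumeration guard (%d).", n, max_n),
      class = "tir_validation_error"
    )
  }
  enc <- encode_seq(seq)
  minloop <- config$min_hairpin
  pairable <- function(a, b) {
    x <- min(a, b)
    y <- max(a, b)
    (x == 0 && y == 3) || (x == 1 && y == 2) || (x == 2 && y == 3)
  }
  memo <- new.env(parent = emptyenv())
  # All structures of enc[i..j] (1-based inclusive) as pair matrices.
  enum <- function(i, j) {
    if (j < i) {
      return(list(matrix(integer(0), ncol = 2)))
    }
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    out <- lapply(enum(i, j - 1), identity) # j unpaired
    for (k in i:max(i, j - minloop - 1)) {
      if (j - k - 1 < minloop) next
      if (!pairable(enc[k], enc[j])) next
      left <- enum(i, k - 1)
      inner <- enum(k + 1, j - 1)
      for (L in left) {
        for (Inr in inner) {
          out[[length(out) + 1L]] <- rbind(L, Inr, c(k, j))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  structures <- enum(1L, n)
  npairs <- vapply(structures, nrow, integer(1))
  rt <- rt_kcal(config$temperature)
  wts <- exp(-config$pair_energy * npairs / rt)
  z <- sum(wts)
  zu <- NA_real_
  p <- NA_real_
  if (!is.null(interval)) {
    from <- interval[[1]]
    to <- interval[[2]]
    free <- vapply(structures, function(m) {
      if (nrow(m) == 0) {
        return(TRUE)
      }
      pos <- c(m[, 1], m[, 2]) # 1-based paired positions
      !any(pos > from & pos <= to)
    }, logical(1))
    zu <- sum(wts[free])
    p <- zu / z
  }
  list(
    z = z, z_unpaired = zu, p_unpaired = p,
    n_structures = length(structures),
    mfe = config$pair_energy * max(npairs),
    structures = structures
  )
}
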