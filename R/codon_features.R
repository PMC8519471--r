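#' Codon weight tables
#'
#' `cai_table()` returns the classical E. coli relative-adaptiveness weights
#' of Sharp & Li as shipped by the seqinr package (`caitab`), with ATG and
#' TGG fixed at 1. `synthetic_tai_table()` and `synthetic_cc_table()` are
#' deterministic, clearly synthetic illustrative tables (the real tRNA
#' adaptation and codon-pair weight sets are not redistributable here);
#' supply your own table of the same shape for production use.
#'
#' @param organism Column of `seqinr::caitab` to use (default `"ec"`,
#'   E. coli).
#' @return A tibble `codon`, `weight` (or `codon_pair`, `weight`) with a
#'   `"table_name"` attribute.
#' @export
cai_table <- function(organism = "ec") {
  caitab <- get_caitab()
  w <- caitab[[organism]]
  codons <- toupper(rownames(caitab))
  tab <- tibble(codon = codons, weight = w)
  for (cd in c("ATG", "TGG")) {
    if (!cd %in% tab$codon) {
      tab <- dplyr::bind_rows(tab, tibble(codon = cd, weight = 1))
    } else {
      tab$weight[tab$codon == cd] <- 1
    }
  }
  # geometric-mean scores must stay positive: floor hard zeros
  tab$weight[tab$weight <= 0] <- 0.01
  attr(tab, "table_name") <- sprintf("cai-sharp-li-%s", organism)
  tab
}

get_caitab <- function() {
  env <- new.env()
  utils::data("caitab", package = "seqinr", envir = env)
  env$caitab
}

#' @rdname cai_table
#' @export
synthetic_tai_table <- function() {
  tab <- codon_table()
  rows <- purrr::map(tab$synonym_sets, function(set) {
    set <- sort(set)
    tibble(codon = set, weight = 0.6^(seq_along(set) - 1))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "table_name") <- "tai-synthetic-illustrative"
  out
}

#' @rdname cai_table
#' @export
synthetic_cc_table <- function() {
  tai <- synthetic_tai_table()
  w <- setNames(tai$weight, tai$codon)
  grid <- tidyr::expand_grid(first = tai$codon, second = tai$codon)
  out <- tibble(
    codon_pair = paste0(grid$first, grid$second),
    weight = sqrt(w[grid$first] * w[grid$second])
  )
  attr(out, "table_name") <- "cc-synthetic-illustrative"
  out
}

# Codons of a cds scored by cai/tai/cc: drop the start codon and a trailing
# stop codon.
scored_codons <- function(cds) {
  codons <- split_codons(normalize_sequence(cds))
  if (length(codons) < 2) {
    abort("cds has no scored codons after excluding the start codon.",
      class = "tir_validation_error"
    )
  }
  codons <- codons[-1]
  last <- codons[length(codons)]
  if (genetic_code_map()[[last]] == "*") codons <- codons[-length(codons)]
  if (length(codons) == 0) {
    abort("cds has no scored codons.", class = "tir_validation_error")
  }
  codons
}

geom_mean_weights <- function(keys, table, key_col) {
  idx <- match(keys, table[[key_col]])
  if (anyNA(idx)) {
    abort(
      sprintf(
        "No weight for %s '%s' in table %s.",
        key_col, keys[which(is.na(idx))[1]],
        attr(table, "table_name") %||% "<unnamed>"
      ),
      class = "tir_validation_error"
    )
  }
  w <- table$weight[idx]
  if (any(w <= 0)) {
    abort("Weights must be positive.", class = "tir_validation_error")
  }
  exp(mean(log(w)))
}

#' Codon adaptation index
#'
#' Geometric mean of per-codon relative-adaptiveness weights over the cds,
#' excluding the start codon and a trailing stop codon.
#'
#' @param cds Coding sequence.
#' @param table Weight table as from [cai_table()].
#' @return Score in (0, 1].
#' @export
cai <- function(cds, table = cai_table()) {
  geom_mean_weights(scored_codons(cds), table, "codon")
}

#' tRNA adaptation index
#'
#' Same contract as [cai()] with a tAI weight table.
#'
#' @inheritParams cai
#' @export
tai <- function(cds, table = synthetic_tai_table()) {
  geom_mean_weights(scored_codons(cds), table, "codon")
}

#' Codon-context score
#'
#' Geometric mean over adjacent codon-pair weights (order-sensitive), again
#' excluding the start codon and a trailing stop codon.
#'
#' @param cds Coding sequence (at least two scored codons).
#' @param pair_table Tibble `codon_pair`, `weight`.
#' @return Score in (0, 1].
#' @export
codon_context <- function(cds, pair_table = synthetic_cc_table()) {
  codons <- scored_codons(cds)
  if (length(codons) < 2) {
    abort("Codon context needs at least two scored codons.",
      class = "tir_validation_error"
    )
  }
  pairs <- paste0(codons[-length(codons)], codons[-1])
  geom_mean_weights(pairs, pair_table, "codon_pair")
}

#' G+C content
#'
#' @param seq Nucleotide string.
#' @return Percent G+C in `[0, 100]`.
#' @export
gc_content <- function(seq) {
  seq <- normalize_sequence(seq)
  100 * lengths(regmatches(seq, gregexpr("[GC]", seq))) / nchar(seq)
}

#' Local G+C content of an anchored region
#'
#' @param construct A coding construct.
#' @param region A [region()].
#' @return Percent G+C of the excised region.
#' @export
local_gc <- function(construct, region) {
  gc_content(region_sequence(region, as_construct(construct)))
}

#' Avoidance configuration
#'
#' Settings for scoring unwanted mRNA:ncRNA interactions: the mRNA region
#' scanned (default 1:30), the ncRNA set, and the interaction engine. The
#' `"rnaup"` engine shells out to ViennaRNA RNAup (`-b -o`); the `"stub"`
#' engine calls `stub_fn(mrna_seq, ncrna_seq)` which must return
#' `c(dg_u, dg_h)` and exists to make the min-selection logic testable
#' without the dependency.
#'
#' @param ncrna ncRNA set: a tibble with `id` and `sequence` columns, or a
#'   FASTA path.
#' @param region mRNA region to scan.
#' @param engine `"rnaup"` or `"stub"`.
#' @param stub_fn Scripted interaction function for the stub engine.
#' @return An `avoidance_config` list.
#' @export
avoidance_config <- function(ncrna, region = NULL,
                             engine = c("rnaup", "stub"), stub_fn = NULL) {
  engine <- match.arg(engine)
  if (is.null(region)) region <- tirdesign::region(1, 30)
  if (is.character(ncrna) && length(ncrna) == 1) {
    recs <- read_fasta_sequences(ncrna)
    ncrna <- tibble(id = recs$id, sequence = recs$sequence)
  }
  if (!is.data.frame(ncrna) || nrow(ncrna) == 0) {
    abort("ncRNA set must be non-empty.", class = "tir_validation_error")
  }
  if (engine == "stub" && !is.function(stub_fn)) {
    abort("Stub engine needs a `stub_fn`.", class = "tir_validation_error")
  }
  structure(
    list(ncrna = ncrna, region = region, engine = engine, stub_fn = stub_fn),
    class = "avoidance_config"
  )
}

# RNAup adapter: interaction between two RNAs; returns c(dg_u, dg_h).
rnaup_interaction <- function(seq_a, seq_b, temperature = 37) {
  if (!nzchar(Sys.which("RNAup"))) {
    abort(
      paste(
        "Interaction engine unavailable: RNAup not on PATH. The adapter",
        "contract is: given two sequences return c(dg_u, dg_h) of their",
        "most stable interaction."
      ),
      class = "tir_dependency_error"
    )
  }
  out <- system2("RNAup", c("-b", "-o", "-T", temperature),
    input = c(">a", seq_a, ">b", seq_b), stdout = TRUE, stderr = FALSE
  )
  line <- grep("=", out, value = TRUE)[1]
  if (is.na(line)) {
    abort("Could not parse RNAup output.", class = "tir_dependency_error")
  }
  inner <- regmatches(line, regexpr("\\(([^()]*=[^()]*)\\)", line))
  nums <- as.numeric(regmatches(
    inner,
    gregexpr("-?[0-9]+\\.?[0-9]*", inner)
  )[[1]])
  # (total = dg_h + dg_u terms...)
  c(dg_u = sum(nums[-(1:2)]), dg_h = nums[2])
}

#' ncRNA-avoidance score
#'
#' Hybridization energy of the most stable interaction between the mRNA
#' region (default 1:30) and any ncRNA in the set: `min` over ncRNAs of
#' `dG_h`. The unpairing component `dG_u` is computed by the engine but
#' deliberately excluded from the returned score.
#'
#' @param construct A coding construct.
#' @param config An [avoidance_config()].
#' @return Most negative hybridization energy `dG_h` in kcal/mol, with the
#'   per-ncRNA energies as the `"interactions"` attribute.
#' @export
avoidance <- function(construct, config) {
  stopifnot(inherits(config, "avoidance_config"))
  construct <- as_construct(construct)
  mrna <- region_sequence(config$region, construct)
  fn <- if (config$engine == "stub") {
    config$stub_fn
  } else {
    rnaup_interaction
  }
  res <- purrr::map(config$ncrna$sequence, function(nc) fn(mrna, nc))
  tab <- tibble(
    ncrna = config$ncrna$id,
    dg_u = purrr::map_dbl(res, function(x) unname(x[[1]])),
    dg_h = purrr::map_dbl(res, function(x) unname(x[[2]]))
  )
  out <- min(tab$dg_h)
  attr(out, "interactions") <- tab
  out
}
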