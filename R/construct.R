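#' Create a coding construct
#'
#' A coding construct is one transcript record anchored at the start codon:
#' an optional 5' UTR, a protein-coding sequence, and an optional 3' UTR.
#' Constructs are stored as one-row tibbles so that multi-record sets are
#' ordinary tibbles that pipe through dplyr verbs.
#'
#' @param cds Coding sequence (length a positive multiple of 3).
#' @param utr5,utr3 Flanking untranslated sequences (may be empty).
#' @param id Record identifier.
#' @param description Optional FASTA description text.
#' @param canonical If `TRUE` (default) require the cds to begin with ATG.
#' @param require_stop If `TRUE` also require a terminal stop codon.
#' @return A one-row tibble with columns `id`, `utr5`, `cds`, `utr3`,
#'   `description`.
#' @examples
#' coding_construct("ATGGCTAAATAA", utr5 = "GGGAAA", id = "demo")
#' @export
coding_construct <- function(cds, utr5 = "", utr3 = "", id = "construct",
                             description = "", canonical = TRUE,
                             require_stop = FALSE) {
  cds <- normalize_sequence(cds)
  utr5 <- if (nzchar(utr5)) normalize_sequence(utr5) else ""
  utr3 <- if (nzchar(utr3)) normalize_sequence(utr3) else ""
  if (nchar(cds) %% 3L != 0L || nchar(cds) == 0L) {
    abort("`cds` length must be a positive multiple of 3.",
      class = "tir_validation_error"
    )
  }
  if (canonical && substr(cds, 1L, 3L) != "ATG") {
    abort("Canonical cds must begin with ATG.", class = "tir_validation_error")
  }
  if (require_stop) {
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (!last %in% c("TAA", "TAG", "TGA")) {
      abort("cds must end with a stop codon (TAA/TAG/TGA).",
        class = "tir_validation_error"
      )
    }
  }
  tibble(
    id = as.character(id), utr5 = utr5, cds = cds, utr3 = utr3,
    description = as.character(description)
  )
}

# Accept a one-row tibble / named list and return it as a plain list with
# utr5, cds, utr3, id fields.
as_construct <- function(construct) {
  if (is.data.frame(construct)) {
    if (nrow(construct) != 1L) {
      abort("Expected a single construct (one row).", class = "tir_validation_error")
    }
    construct <- as.list(construct)
  }
  if (is.null(construct$cds)) {
    abort("Construct needs a `cds` field.", class = "tir_validation_error")
  }
  construct$utr5 <- construct$utr5 %||% ""
  construct$utr3 <- construct$utr3 %||% ""
  construct$id <- construct$id %||% "construct"
  construct
}

# Full transcript sequence utr5 + cds + utr3.
construct_sequence <- function(construct) {
  construct <- as_construct(construct)
  paste0(construct$utr5, construct$cds, construct$utr3)
}

#' Generate a random coding construct
#'
#' Fixture generator: `cds = ATG + (n_codons - 2) random sense codons +
#' random stop`, with a random 5' UTR. Deterministic for a fixed seed.
#'
#' @param n_codons Total codon count including start and stop (>= 2).
#' @param utr5_len Length of the random 5' UTR.
#' @param seed Optional integer seed.
#' @param id Record id.
#' @return A one-row construct tibble.
#' @export
random_construct <- function(n_codons, utr5_len = 24, seed = NULL,
                             id = "random_construct") {
  if (n_codons < 2) {
    abort("`n_codons` must be at least 2 (start + stop).",
      class = "tir_validation_error"
    )
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  map <- genetic_code_map()
  sense <- setdiff(names(map)[map != "*"], character(0))
  stops <- names(map)[map == "*"]
  body <- if (n_codons > 2) sample(sense, n_codons - 2L, replace = TRUE) else character(0)
  cds <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
  utr5 <- if (utr5_len > 0) {
    paste(sample(c("A", "C", "G", "T"), utr5_len, replace = TRUE), collapse = "")
  } else {
    ""
  }
  coding_construct(cds, utr5 = utr5, id = id, require_stop = TRUE)
}

# Save/restore global RNG state so seeded helpers do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
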