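#' Normalize a raw nucleotide string
#'
#' Upper-cases, maps RNA `U` to DNA `T` and strips whitespace. Any character
#' outside `A`, `C`, `G`, `T` (after mapping) is an error naming the first
#' offending position in the stripped sequence.
#'
#' @param raw A character scalar with the raw sequence.
#' @return A normalized DNA character scalar.
#' @examples
#' normalize_sequence("augGcu")
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    abort("`raw` must be a single character string.", class = "tir_validation_error")
  }
  s <- gsub("[[:space:]]+", "", raw)
  if (!nzchar(s)) {
    abort("Sequence is empty after stripping whitespace.", class = "tir_validation_error")
  }
  s <- chartr("u", "t", s)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L) {
    abort(
      sprintf(
        "Invalid nucleotide '%s' at position %d (alphabet is A/C/G/T, U maps to T).",
        substr(s, bad, bad), bad
      ),
      class = "tir_validation_error"
    )
  }
  s
}

# Standard genetic code (translation table 1), built once from seqinr.
genetic_code_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bases <- c("T", "C", "A", "G")
      codons <- as.vector(outer(
        outer(bases, bases, paste0), bases, paste0
      ))
      aas <- vapply(
        codons,
        function(cd) seqinr::translate(strsplit(tolower(cd), "")[[1]]),
        character(1)
      )
      cache <<- setNames(aas, codons)
    }
    cache
  }
})

#' Codon table for the standard genetic code
#'
#' @return A list with `codon_to_aa` (named character vector over all 64
#'   codons, stop = `"*"`) and `synonym_sets` (list of sense-codon sets per
#'   amino acid).
#' @export
codon_table <- function() {
  map <- genetic_code_map()
  sense <- map[map != "*"]
  list(
    codon_to_aa = map,
    synonym_sets = split(names(sense), sense)
  )
}

#' Synonymous codons of a sense codon
#'
#' @param codon A single sense codon (DNA triplet).
#' @return Character vector of all codons (including `codon`) encoding the
#'   same amino acid.
#' @examples
#' synonymous_codons("CTG")
#' @export
synonymous_codons <- function(codon) {
  codon <- normalize_sequence(codon)
  if (nchar(codon) != 3L) {
    abort("`codon` must be a triplet.", class = "tir_validation_error")
  }
  aa <- genetic_code_map()[[codon]]
  if (aa == "*") {
    abort(
      sprintf("Stop codon %s is not substitutable.", codon),
      class = "tir_validation_error"
    )
  }
  unname(codon_table()$synonym_sets[[aa]])
}

# Split a cds into codon triplets.
split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Translate a cds (DNA) to an amino-acid string, stop as '*'.
translate_cds <- function(cds) {
  paste(genetic_code_map()[split_codons(cds)], collapse = "")
}

# Reverse complement of a DNA string.
reverse_complement <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
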