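#' Read coding constructs from a FASTA file
#'
#' Records are normalized (upper case, U mapped to T) and split into
#' `utr5 | cds | utr3` according to the stated flank lengths, which apply to
#' every record in the file.
#'
#' @param path FASTA file path.
#' @param utr5_len,utr3_len Number of leading / trailing nucleotides to
#'   treat as untranslated flanks (default 0).
#' @param canonical Require the cds to start with ATG (default `FALSE`
#'   because arbitrary fragments are allowed on input).
#' @return A construct tibble (columns `id`, `utr5`, `cds`, `utr3`,
#'   `description`), one row per record, in file order.
#' @export
read_fasta <- function(path, utr5_len = 0, utr3_len = 0, canonical = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "tir_validation_error")
  }
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE, whole.header = TRUE),
    error = function(e) {
      abort(sprintf("Failed to parse FASTA %s: %s", path, conditionMessage(e)),
        class = "tir_validation_error"
      )
    }
  )
  if (length(recs) == 0L) {
    abort("FASTA file contains no records.", class = "tir_validation_error")
  }
  headers <- vapply(recs, function(r) attr(r, "name"), character(1))
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids)) {
    abort(
      sprintf(
        "Duplicate FASTA ids: %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")
      ),
      class = "tir_validation_error"
    )
  }
  rows <- purrr::pmap(
    list(unname(unlist(lapply(recs, as.character))), ids, desc),
    function(s, id, d) {
      s <- normalize_sequence(s)
      n <- nchar(s)
      if (utr5_len + utr3_len >= n) {
        abort(
          sprintf("Record %s (%d nt) shorter than stated flanks.", id, n),
          class = "tir_validation_error"
        )
      }
      coding_construct(
        cds = substr(s, utr5_len + 1L, n - utr3_len),
        utr5 = if (utr5_len > 0) substr(s, 1L, utr5_len) else "",
        utr3 = if (utr3_len > 0) substr(s, n - utr3_len + 1L, n) else "",
        id = id, description = d, canonical = canonical
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Read a FASTA file as plain sequences
#'
#' No coding-frame validation; for ncRNA sets and other arbitrary records.
#'
#' @param path FASTA file path.
#' @return A tibble `id`, `sequence`, `description`.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "tir_validation_error")
  }
  recs <- seqinr::read.fasta(path,
    as.string = TRUE, forceDNAtolower = FALSE, whole.header = TRUE
  )
  if (length(recs) == 0L) {
    abort("FASTA file contains no records.", class = "tir_validation_error")
  }
  headers <- vapply(recs, function(r) attr(r, "name"), character(1))
  tibble(
    id = sub("\\s.*$", "", headers),
    sequence = vapply(recs, function(r) normalize_sequence(as.character(r)), character(1)),
    description = sub("^\\S+\\s*", "", headers)
  )
}

#' Write coding constructs to a FASTA file
#'
#' Writes `utr5 + cds + utr3` per record, wrapped at 60 columns; the header
#' is `id description`.
#'
#' @param constructs A construct tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(constructs, path) {
  stopifnot(is.data.frame(constructs), nrow(constructs) > 0)
  names_out <- ifelse(
    nzchar(constructs$description %||% ""),
    paste(constructs$id, constructs$description),
    constructs$id
  )
  seqs <- lapply(seq_len(nrow(constructs)), function(i) {
    strsplit(construct_sequence(constructs[i, ]), "")[[1]]
  })
  seqinr::write.fasta(seqs, names = names_out, file.out = path, nbchar = 60)
  invisible(path)
}

#' Read / write labeled expression datasets
#'
#' Delimited text with header columns `id`, `outcome` (0/1) and at least one
#' of `opening_energy` or `sequence`.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return A tibble with the dataset.
#' @export
read_labeled <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_labeled(df)
  as_tibble(df)
}

#' @rdname read_labeled
#' @param data Labeled dataset tibble.
#' @export
write_labeled <- function(data, path, sep = "\t") {
  validate_labeled(data)
  utils::write.table(data, path,
    sep = sep, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

validate_labeled <- function(data, require_energy = FALSE) {
  if (!is.data.frame(data)) {
    abort("Labeled dataset must be a data frame.", class = "tir_validation_error")
  }
  if (is.null(data$outcome)) {
    abort("Labeled dataset needs an `outcome` column.", class = "tir_validation_error")
  }
  if (!all(data$outcome %in% c(0, 1))) {
    abort("`outcome` must be binary 0/1.", class = "tir_validation_error")
  }
  if (require_energy && is.null(data$opening_energy)) {
    abort("Dataset needs an `opening_energy` column.", class = "tir_validation_error")
  }
  invisible(data)
}
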