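#' Start-codon-anchored region
#'
#' Regions are 1-based and anchored at the start codon: coordinate +1 is the
#' first nucleotide of the start codon, -1 the nucleotide immediately
#' upstream; there is no position 0. Ends are inclusive.
#'
#' @param start,end Non-zero integers with `start` before or equal to `end`.
#' @return An object of class `tir_region`.
#' @examples
#' region(-24, 24)
#' @export
region <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (start == 0L || end == 0L) {
    abort("Anchored coordinates have no position 0.", class = "tir_validation_error")
  }
  if (start > end) {
    abort("`start` must precede or equal `end`.", class = "tir_validation_error")
  }
  structure(list(start = start, end = end), class = "tir_region")
}

#' @export
format.tir_region <- function(x, ...) sprintf("%d:%d", x$start, x$end)

#' @export
print.tir_region <- function(x, ...) {
  cat(sprintf(
    "<anchored region %s, %d nt>\n", format(x), region_length(x)
  ))
  invisible(x)
}

#' Length of an anchored region in nucleotides
#'
#' Because position 0 does not exist, a region spanning the anchor is one
#' shorter than the naive difference: `end - start + 1` when both ends share
#' a sign, `end - start` otherwise.
#'
#' @param region A [region()].
#' @return Integer length in nt.
#' @examples
#' region_length(region(1, 10)) # 10
#' region_length(region(-30, 18)) # 48
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "tir_region"))
  if (sign(region$start) == sign(region$end)) {
    region$end - region$start + 1L
  } else {
    region$end - region$start
  }
}

#' Region from an end position and a length
#'
#' Inverse of [region_length()] paired with end extraction: the region of
#' length `l` whose last nucleotide sits at anchored coordinate `i`.
#'
#' @param i Anchored end coordinate (non-zero).
#' @param l Length in nt (>= 1).
#' @return A [region()].
#' @examples
#' endpos_len_to_region(24, 48) # -24:24
#' @export
endpos_len_to_region <- function(i, l) {
  i <- as.integer(i)
  l <- as.integer(l)
  if (i == 0L) abort("`i` cannot be 0.", class = "tir_validation_error")
  if (l < 1L) abort("`l` must be >= 1.", class = "tir_validation_error")
  start <- i - l + 1L
  if (i > 0L && start <= 0L) start <- start - 1L
  region(start, i)
}

#' Map an anchored region to zero-based offsets in the transcript
#'
#' Returns the half-open interval `[from, to)` into the concatenated
#' `utr5 + cds + utr3` sequence covered by `region`.
#'
#' @param region A [region()].
#' @param construct A coding construct (one-row tibble or list).
#' @return Integer vector `c(from, to)`, zero-based half-open.
#' @export
region_to_offsets <- function(region, construct) {
  stopifnot(inherits(region, "tir_region"))
  construct <- as_construct(construct)
  n_utr5 <- nchar(construct$utr5)
  total <- nchar(construct_sequence(construct))
  anchored_to_offset <- function(coord) {
    if (coord > 0L) n_utr5 + coord - 1L else n_utr5 + coord
  }
  from <- anchored_to_offset(region$start)
  to <- anchored_to_offset(region$end) + 1L
  if (from < 0L) {
    abort(
      sprintf(
        "Region %s extends %d nt past the available 5' flank.",
        format(region), -from
      ),
      class = "tir_bounds_error"
    )
  }
  if (to > total) {
    abort(
      sprintf(
        "Region %s extends %d nt past the available 3' end.",
        format(region), to - total
      ),
      class = "tir_bounds_error"
    )
  }
  c(from = from, to = to)
}

# Excise the region's nucleotides from a construct.
region_sequence <- function(region, construct) {
  off <- region_to_offsets(region, construct)
  substr(construct_sequence(construct), off[["from"]] + 1L, off[["to"]])
}

#' Host presets for the accessibility scoring region
#'
#' Start-codon-anchored regions whose opening energy best predicts
#' expression in each host: E. coli -24:24, S. cerevisiae -7:89,
#' M. musculus -8:11, and -24:89 for other hosts.
#'
#' @param host One of `"E. coli"`, `"S. cerevisiae"`, `"M. musculus"`,
#'   `"Other"`.
#' @return A [region()].
#' @export
host_region <- function(host = c("E. coli", "S. cerevisiae", "M. musculus", "Other")) {
  host <- match.arg(host)
  switch(host,
    "E. coli" = region(-24, 24),
    "S. cerevisiae" = region(-7, 89),
    "M. musculus" = region(-8, 11),
    "Other" = region(-24, 89)
  )
}

#' @rdname host_region
#' @return `host_presets()`: a tibble of the named presets and their regions.
#' @export
host_presets <- function() {
  tibble(
    host = c("E. coli", "S. cerevisiae", "M. musculus", "Other"),
    region_start = c(-24L, -7L, -8L, -24L),
    region_end = c(24L, 89L, 11L, 89L)
  )
}
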