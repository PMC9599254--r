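# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Plain-character reverse complement over the ACGTN alphabet.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# base indices 1..4 = A,C,G,T; 5 = anything else (N)
.base_index <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], DNA_BASES)
  idx[is.na(idx)] <- 5L
  idx
}

.assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside %s: %s", what,
                 if (allow_n) "ACGTN" else "ACGT",
                 substr(x[bad][1], 1, 40)), call. = FALSE)
  }
  invisible(x)
}

# Gene-relative coordinates use the biologist convention: +1 is the first
# base of the start codon, -1 the base immediately upstream, and there is
# no position 0.  Internally we map them onto a contiguous "linear" axis
# where +1 -> 0, -1 -> -1, so interval arithmetic is ordinary.
.rel_to_lin <- function(rel) ifelse(rel > 0, rel - 1L, rel)
.lin_to_rel <- function(lin) ifelse(lin >= 0, lin + 1L, lin)

# absolute 0-based index of the base at gene-relative position `rel`
.rel_to_abs <- function(rel, strand, cds_start, cds_end) {
  lin <- .rel_to_lin(rel)
  if (strand == "+") cds_start + lin else cds_end - 1L - lin
}

.stopifnot_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("%s must be a single string", what), call. = FALSE)
}
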