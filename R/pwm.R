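# Position weight matrices: construction from curated operator alignments,
# scoring, information content, threshold calibration and serialization.
#
# The weight convention is the log-count one used by the classic bacterial
# regulon-reconstruction tools:
#   w(b,k) = ln(N(b,k) + p) - (1/4) * sum_b' ln(N(b',k) + p)
# so every column sums to zero and site scores are sums of column weights.
# Score thresholds (e.g. the canonical 4.3 used for NagR scans) are
# meaningful on this scale only.

#' Construct a site alignment
#'
#' @param sites Character vector of equal-length DNA strings (ACGT), >= 2.
#' @param provenance Optional data.frame with one row per site
#'   (e.g. genome_id, locus_tag, position).
#' @return Object of class `site_alignment`.
#' @export
site_alignment <- function(sites, provenance = NULL) {
  sites <- toupper(sites)
  if (length(sites) < 2L) stop("need at least 2 sites", call. = FALSE)
  if (length(unique(nchar(sites))) != 1L)
    stop("sites must all have the same length", call. = FALSE)
  .assert_dna(sites, allow_n = FALSE, what = "site")
  if (!is.null(provenance) && nrow(provenance) != length(sites))
    stop("provenance must have one row per site", call. = FALSE)
  structure(list(sites = sites, provenance = provenance),
            class = "site_alignment")
}

#' Read training sites
#'
#' Plain text (one site per line) or TSV with a `site` column plus optional
#' provenance columns (`genome_id`, `locus_tag`, `position`).
#'
#' @param path Input file.
#' @return A [site_alignment()].
#' @export
read_sites <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"site" %in% names(tab)) stop("TSV needs a 'site' column", call. = FALSE)
    site_alignment(tab$site, tab[setdiff(names(tab), "site")])
  } else {
    x <- readLines(path, warn = FALSE)
    site_alignment(x[nzchar(trimws(x))])
  }
}

.count_matrix <- function(sites) {
  L <- nchar(sites[1])
  m <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(sites, ""))
  for (k in seq_len(L)) {
    tb <- table(factor(chars[, k], levels = DNA_BASES))
    m[, k] <- as.integer(tb)
  }
  m
}

#' Build a position weight matrix
#'
#' Computes per-column weights
#' \eqn{w(b,k) = \ln(N(b,k)+p) - \frac{1}{4}\sum_{b'} \ln(N(b',k)+p)} from an
#' alignment of binding sites. With `palindromic = TRUE` the reverse
#' complement of every site is added to the counts before the weights are
#' computed, which makes the matrix self-reverse-complementary (as expected
#' for operators bound by symmetric dimers).
#'
#' @param alignment A [site_alignment()] or a character vector of sites.
#' @param palindromic Symmetrize counts with reverse complements.
#' @param pseudocount Positive pseudocount `p` (default 0.5).
#' @return Object of class `weight_matrix`: weights (4 x L, rows A,C,G,T),
#'   retained counts, `palindromic`, `pseudocount`, `n_sites`, and a
#'   `threshold` slot (NA until calibrated).
#' @export
build_pwm <- function(alignment, palindromic = FALSE, pseudocount = 0.5) {
  if (is.character(alignment)) alignment <- site_alignment(alignment)
  if (!inherits(alignment, "site_alignment"))
    stop("alignment must be a site_alignment or character vector",
         call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  sites <- alignment$sites
  if (palindromic) sites <- c(sites, revcomp(sites))
  counts <- .count_matrix(sites)
  lg <- log(counts + pseudocount)
  weights <- sweep(lg, 2L, colMeans(lg))
  structure(list(length = ncol(weights), weights = weights, counts = counts,
                 n_sites = length(alignment$sites), palindromic = palindromic,
                 pseudocount = pseudocount, threshold = NA_real_,
                 training = alignment$sites),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf(
    "<weight_matrix> L=%d, %d training site(s)%s, threshold=%s\n  consensus: %s\n",
    x$length, x$n_sites, if (x$palindromic) ", palindromic" else "",
    if (is.na(x$threshold)) "unset" else format(x$threshold, digits = 4),
    pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a weight matrix
#' @param pwm A `weight_matrix`.
#' @return Character string of length L.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$weights, 2L, which.max)], collapse = "")
}

#' Score a sequence of motif length
#'
#' Sum of per-position weights. Any `N` yields `-Inf` (never a hit).
#'
#' @param pwm A `weight_matrix`.
#' @param seq DNA string of length `pwm$length` (ACGTN).
#' @return A single numeric score.
#' @export
score_sequence <- function(pwm, seq) {
  seq <- toupper(seq)
  if (nchar(seq) != pwm$length)
    stop(sprintf("sequence length %d != motif length %d", nchar(seq),
                 pwm$length), call. = FALSE)
  .assert_dna(seq)
  idx <- .base_index(seq)
  if (any(idx == 5L)) return(-Inf)
  sum(pwm$weights[cbind(idx, seq_len(pwm$length))])
}

# Score every L-window of `seq` (single strand). Returns numeric vector of
# length nchar(seq)-L+1 (or length 0); windows containing N score -Inf.
.score_windows <- function(pwm, seq) {
  L <- pwm$length
  n <- nchar(seq)
  if (n < L) return(numeric(0))
  idx <- .base_index(toupper(seq))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (k in seq_len(L)) {
    wk <- c(pwm$weights[, k], -Inf)   # 5th entry: N sentinel
    sc <- sc + wk[idx[k:(k + nw - 1L)]]
  }
  sc
}

#' Per-column information content
#'
#' Column IC in bits, \eqn{2 + \sum_b f_b \log_2 f_b}, computed from raw
#' count frequencies (no pseudocount).
#'
#' @param pwm A `weight_matrix` with retained counts.
#' @return List with `per_column` (numeric, bits) and `total`.
#' @export
information_content <- function(pwm) {
  f <- sweep(pwm$counts, 2L, colSums(pwm$counts), "/")
  term <- ifelse(f > 0, f * log2(f), 0)
  per_col <- 2 + colSums(term)
  list(per_column = per_col, total = sum(per_col))
}

#' Calibrate a score threshold
#'
#' @param pwm A `weight_matrix`.
#' @param rule `"fixed"` (return `value` verbatim), `"min_training_site"`
#'   (minimum score of the training sites), or `"percentile"` (the `q`-th
#'   percentile of training-site scores).
#' @param value Threshold for `rule = "fixed"`.
#' @param q Percentile in `[0, 100]`.
#' @param sites Optional [site_alignment()] or character vector overriding
#'   the training sites stored in the matrix.
#' @param allowance Non-negative slack subtracted from the calibrated value;
#'   lets scans tolerate site divergence accumulated since the training
#'   alignment (default 0).
#' @return The threshold (numeric scalar).
#' @export
calibrate_threshold <- function(pwm,
                                rule = c("fixed", "min_training_site",
                                         "percentile"),
                                value = NULL, q = NULL, sites = NULL,
                                allowance = 0) {
  rule <- match.arg(rule)
  if (allowance < 0) stop("allowance must be >= 0", call. = FALSE)
  if (rule == "fixed") {
    if (is.null(value)) stop("rule 'fixed' needs a value", call. = FALSE)
    return(value - allowance)
  }
  if (is.null(sites)) sites <- pwm$training
  if (inherits(sites, "site_alignment")) sites <- sites$sites
  if (is.null(sites) || !length(sites))
    stop("no training sites available for calibration", call. = FALSE)
  sc <- vapply(sites, function(s) score_sequence(pwm, s), numeric(1))
  if (rule == "min_training_site") return(min(sc) - allowance)
  if (is.null(q) || q < 0 || q > 100)
    stop("percentile q must be in [0, 100]", call. = FALSE)
  unname(stats::quantile(sc, q / 100, type = 7)) - allowance
}

#' Set the operating threshold on a weight matrix
#' @param pwm A `weight_matrix`.
#' @param threshold Numeric scalar.
#' @return The modified `weight_matrix`.
#' @export
set_threshold <- function(pwm, threshold) {
  pwm$threshold <- threshold
  pwm
}

#' Logo data: per-column base frequencies and information content
#' @param pwm A `weight_matrix`.
#' @return data.frame with position, A/C/G/T frequencies and `ic` (bits).
#' @export
logo_data <- function(pwm) {
  f <- sweep(pwm$counts, 2L, colSums(pwm$counts), "/")
  ic <- information_content(pwm)$per_column
  out <- data.frame(position = seq_len(pwm$length), t(f), ic = ic)
  names(out)[2:5] <- DNA_BASES
  out
}

#' Write / read a weight matrix
#'
#' TSV matrix (header A C G T, one row per position) plus a JSON sidecar
#' (`<path>.json`) holding length, threshold, palindromic flag, pseudocount
#' and counts, so a matrix can be re-used or refit.
#'
#' @param pwm A `weight_matrix`.
#' @param path TSV path.
#' @return `write_pwm`: invisibly the path. `read_pwm`: a `weight_matrix`.
#' @export
write_pwm <- function(pwm, path) {
  tab <- as.data.frame(t(pwm$weights))
  names(tab) <- DNA_BASES
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(length = pwm$length, threshold = pwm$threshold,
               palindromic = pwm$palindromic, pseudocount = pwm$pseudocount,
               n_sites = pwm$n_sites, counts = pwm$counts,
               training = pwm$training)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  weights <- t(as.matrix(tab[, DNA_BASES]))
  dimnames(weights) <- list(DNA_BASES, NULL)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  counts <- if (!is.null(meta$counts)) {
    # jsonlite stores matrices row-wise
    m <- do.call(rbind, lapply(meta$counts, function(r)
      as.integer(unlist(r))))
    dimnames(m) <- list(DNA_BASES, NULL)
    m
  } else NULL
  structure(list(
    length = ncol(weights), weights = weights, counts = counts,
    n_sites = meta$n_sites %||% NA_integer_,
    palindromic = isTRUE(meta$palindromic),
    pseudocount = meta$pseudocount %||% NA_real_,
    threshold = if (is.null(meta$threshold)) NA_real_ else
      as.numeric(meta$threshold),
    training = if (is.null(meta$training)) NULL else
      unlist(meta$training)), class = "weight_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
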