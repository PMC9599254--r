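# Sigma70 promoter element prediction (-35/-10 hexamer PWMs) and
# operator-promoter overlap classification.

#' Train -35 and -10 promoter weight matrices
#'
#' Builds two non-palindromic hexamer PWMs with [build_pwm()]. Without
#' arguments, a bundled synthetic training set is used: paired hexamers
#' drawn around the canonical TTGACA / TATAAT sigma70 consensus (the
#' package ships no experimentally mapped promoter collection). The
#' combined-score cutoff is the minimum of (s35 + s10) over the paired
#' training promoters.
#'
#' @param minus35,minus10 Character vectors of 6-mers (paired by index), or
#'   paths to plain-text hexamer lists; NULL loads the bundled set.
#' @param pseudocount Passed to [build_pwm()].
#' @return List with `pwm35`, `pwm10`, `cutoff`.
#' @export
train_promoter_pwms <- function(minus35 = NULL, minus10 = NULL,
                                pseudocount = 0.5) {
  load_hex <- function(x, default_file) {
    if (is.null(x))
      x <- readLines(system.file("extdata", default_file, package = "regrec"),
                     warn = FALSE)
    else if (length(x) == 1L && file.exists(x))
      x <- readLines(x, warn = FALSE)
    x <- toupper(trimws(x[nzchar(trimws(x))]))
    if (length(x) < 5L) stop("need at least 5 training hexamers",
                             call. = FALSE)
    if (any(nchar(x) != 6L)) stop("training hexamers must be 6 bp",
                                  call. = FALSE)
    x
  }
  h35 <- load_hex(minus35, "sigma70_minus35_synthetic.txt")
  h10 <- load_hex(minus10, "sigma70_minus10_synthetic.txt")
  pwm35 <- build_pwm(h35, palindromic = FALSE, pseudocount = pseudocount)
  pwm10 <- build_pwm(h10, palindromic = FALSE, pseudocount = pseudocount)
  cutoff <- if (length(h35) == length(h10)) {
    min(vapply(seq_along(h35), function(i)
      score_sequence(pwm35, h35[i]) + score_sequence(pwm10, h10[i]),
      numeric(1)))
  } else {
    min(vapply(h35, function(s) score_sequence(pwm35, s), numeric(1))) +
      min(vapply(h10, function(s) score_sequence(pwm10, s), numeric(1)))
  }
  list(pwm35 = pwm35, pwm10 = pwm10, cutoff = cutoff)
}

#' Call sigma70 promoters in an upstream region
#'
#' Scores every hexamer of the region's coding strand with both matrices
#' and returns all (-35, -10) pairs whose spacer (bp between the -35 end
#' and the -10 start) lies within `spacer` bounds, whose -10 element starts
#' at or upstream of position +1, and whose combined score reaches
#' `min_score`. Sorted by combined score, best first.
#'
#' @param region An `upstream_region`.
#' @param pwm35,pwm10 Hexamer weight matrices.
#' @param spacer Length-2 spacer bounds in bp (default `c(15, 19)`).
#' @param min_score Combined-score cutoff (default `-Inf`).
#' @return data.frame: m35_start, m35_end, m10_start, m10_end (gene-relative
#'   inclusive bounds), s35, s10, spacer, score.
#' @export
call_promoters <- function(region, pwm35, pwm10, spacer = c(15L, 19L),
                           min_score = -Inf) {
  n <- nchar(region$sequence)
  empty <- data.frame(m35_start = integer(0), m35_end = integer(0),
                      m10_start = integer(0), m10_end = integer(0),
                      s35 = numeric(0), s10 = numeric(0),
                      spacer = integer(0), score = numeric(0))
  if (n < 12L + spacer[1]) return(empty)
  s35 <- .score_windows(pwm35, region$sequence)
  s10 <- .score_windows(pwm10, region$sequence)
  lin0 <- .rel_to_lin(region$rel_start)
  out <- list()
  for (i in seq_along(s35)) {
    jmin <- i + 6L + spacer[1]
    jmax <- min(i + 6L + spacer[2], length(s10))
    if (jmin > length(s10)) next
    for (j in jmin:jmax) {
      # -10 element must start at or upstream of +1 (linear coord 0)
      if (lin0 + (j - 1L) > 0L) next
      sc <- s35[i] + s10[j]
      if (sc < min_score || !is.finite(sc)) next
      out[[length(out) + 1L]] <- data.frame(
        m35_start = .lin_to_rel(lin0 + i - 1L),
        m35_end = .lin_to_rel(lin0 + i + 4L),
        m10_start = .lin_to_rel(lin0 + j - 1L),
        m10_end = .lin_to_rel(lin0 + j + 4L),
        s35 = s35[i], s10 = s10[j],
        spacer = j - i - 6L, score = sc)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$score), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify operator-promoter overlap
#'
#' Intersects the operator interval with the -35 and -10 hexamer intervals
#' (all in the gene-relative frame). Any positive overlap is interpreted as
#' repression-consistent architecture (the bound factor occludes RNA
#' polymerase).
#'
#' @param operator One row of a site table (uses `rel_start`) or a list
#'   with `rel_start`; operator length from `motif_length`.
#' @param promoter One row of a [call_promoters()] result.
#' @param motif_length Operator length in bp (default 21).
#' @return List: `element` ("minus35", "minus10", "both", "none"),
#'   `overlap_bp`, `architecture` ("repression-consistent" or
#'   "not-overlapping").
#' @export
classify_overlap <- function(operator, promoter, motif_length = 21L) {
  op1 <- .rel_to_lin(operator$rel_start[1])
  op2 <- op1 + motif_length - 1L
  ov <- function(a1, a2) max(0L, min(op2, a2) - max(op1, a1) + 1L)
  o35 <- ov(.rel_to_lin(promoter$m35_start[1]),
            .rel_to_lin(promoter$m35_end[1]))
  o10 <- ov(.rel_to_lin(promoter$m10_start[1]),
            .rel_to_lin(promoter$m10_end[1]))
  element <- if (o35 > 0L && o10 > 0L) "both"
  else if (o35 > 0L) "minus35"
  else if (o10 > 0L) "minus10"
  else "none"
  list(element = element, overlap_bp = o35 + o10,
       architecture = if (element == "none") "not-overlapping"
       else "repression-consistent")
}
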