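# Sliding-window operator scans over upstream regions.

#' Scan configuration
#'
#' @param window Gene-relative window scanned upstream of each gene
#'   (default `c(-500, 50)`).
#' @param threshold Score cutoff (on the log-count weight scale; the NagR
#'   workflow uses 4.3 on its published matrix scale).
#' @param both_strands Score the reverse complement as well (default TRUE).
#' @param dedup_radius Opposite-strand hits whose starts differ by at most
#'   this many bp collapse to the higher-scoring one (palindrome artifact;
#'   default 2).
#' @return Object of class `scan_config`.
#' @export
scan_config <- function(window = c(-500L, 50L), threshold = 4.3,
                        both_strands = TRUE, dedup_radius = 2L) {
  if (window[1] >= window[2]) stop("window start must be < end", call. = FALSE)
  structure(list(window = as.integer(window), threshold = threshold,
                 both_strands = both_strands,
                 dedup_radius = as.integer(dedup_radius)),
            class = "scan_config")
}

.empty_sites <- function() {
  data.frame(genome_id = character(0), locus_tag = character(0),
             replicon = character(0), abs_start = integer(0),
             abs_end = integer(0), rel_start = integer(0),
             strand = character(0), score = numeric(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Scan one gene's upstream region for operator hits
#'
#' Every motif-length window of the region is scored on the coding strand
#' and (optionally) its reverse complement; windows must lie entirely inside
#' the region. Hits at or above the threshold are returned sorted by
#' gene-relative position; near-coincident opposite-strand hits are
#' deduplicated (see [scan_config()]).
#'
#' A hit's `rel_start` is the gene-relative position of its 5'-most base on
#' the gene's coding strand; `strand` is the genome strand of the match;
#' `sequence` is the match-strand L-mer.
#'
#' @param genome An [annotated_genome()].
#' @param locus_tag Gene to scan.
#' @param pwm A `weight_matrix` (threshold taken from `config`).
#' @param config A [scan_config()].
#' @return data.frame of candidate sites (possibly empty).
#' @export
scan_gene <- function(genome, locus_tag, pwm, config = scan_config()) {
  region <- extract_upstream(genome, locus_tag, config$window)
  L <- pwm$length
  n <- nchar(region$sequence)
  if (n < L) {
    message("region for ", locus_tag, " shorter than motif; no scan")
    return(.empty_sites())
  }
  fwd <- .score_windows(pwm, region$sequence)
  fkeep <- which(fwd >= config$threshold)
  hits <- data.frame(offset = fkeep - 1L, score = fwd[fkeep],
                     match_strand = rep("+", length(fkeep)),
                     stringsAsFactors = FALSE)
  if (isTRUE(config$both_strands)) {
    rev_seq <- revcomp(region$sequence)
    rv <- .score_windows(pwm, rev_seq)
    keep <- which(rv >= config$threshold)
    if (length(keep)) {
      # offset on the coding strand of a hit found on the reverse strand
      hits <- rbind(hits, data.frame(
        offset = n - L - (keep - 1L), score = rv[keep],
        match_strand = rep("-", length(keep)), stringsAsFactors = FALSE))
    }
  }
  if (!nrow(hits)) return(.empty_sites())

  # dedup: collapse opposite-strand near-duplicates, keep higher score
  hits <- hits[order(-hits$score, hits$match_strand != "+", hits$offset), ,
               drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(hits))) {
    dup <- FALSE
    for (j in kept) {
      if (hits$match_strand[i] != hits$match_strand[j] &&
          abs(hits$offset[i] - hits$offset[j]) <= config$dedup_radius) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  hits <- hits[kept, , drop = FALSE]

  gene <- .gene_row(genome, locus_tag)
  lin0 <- .rel_to_lin(region$rel_start)   # linear coord of region offset 0
  rel_start <- .lin_to_rel(lin0 + hits$offset)
  if (gene$strand == "+") {
    abs_start <- region$abs_start + hits$offset
    genome_strand <- ifelse(hits$match_strand == "+", "+", "-")
  } else {
    abs_start <- region$abs_end - hits$offset - L
    genome_strand <- ifelse(hits$match_strand == "+", "-", "+")
  }
  seqs <- vapply(seq_len(nrow(hits)), function(i) {
    s <- substr(genome$replicons[[gene$replicon]],
                abs_start[i] + 1L, abs_start[i] + L)
    if (genome_strand[i] == "-") revcomp(s) else s
  }, character(1))
  out <- data.frame(
    genome_id = genome$genome_id, locus_tag = locus_tag,
    replicon = gene$replicon, abs_start = as.integer(abs_start),
    abs_end = as.integer(abs_start + L), rel_start = as.integer(rel_start),
    strand = genome_strand, score = hits$score, sequence = seqs,
    stringsAsFactors = FALSE)
  out <- out[order(out$rel_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan every gene of a genome
#'
#' Union of [scan_gene()] over all genes. A physical site lying in the
#' windows of two genes (e.g. a shared divergent-promoter intergenic
#' region) yields one row per gene with identical absolute coordinates;
#' genome-level operator tallies count distinct absolute intervals once.
#'
#' @inheritParams scan_gene
#' @return data.frame of candidate sites.
#' @export
scan_genome <- function(genome, pwm, config = scan_config()) {
  res <- lapply(genome$genes$locus_tag, function(lt)
    suppressMessages(scan_gene(genome, lt, pwm, config)))
  out <- do.call(rbind, res)
  if (is.null(out)) out <- .empty_sites()
  rownames(out) <- NULL
  out
}

#' Count distinct operators in a site table
#' @param sites Site table from [scan_genome()].
#' @return Integer count of distinct absolute intervals.
#' @export
n_operators <- function(sites) {
  if (!nrow(sites)) return(0L)
  nrow(unique(sites[, c("genome_id", "replicon", "abs_start", "abs_end")]))
}

#' Design an EMSA probe around a candidate site
#'
#' Returns the operator sequence extended by `flank` bp of genomic context
#' on each side (49 bp for a 21-bp operator with the default 14-bp flanks),
#' oriented on the match strand.
#'
#' @param genome An [annotated_genome()].
#' @param site One row of a site table.
#' @param flank Flank length in bp (default 14).
#' @return The probe as a character string.
#' @export
make_emsa_probe <- function(genome, site, flank = 14L) {
  site <- as.list(site[1, , drop = FALSE])
  rep_seq <- genome$replicons[[site$replicon]]
  a <- site$abs_start - flank
  b <- site$abs_end + flank
  if (a < 0L || b > nchar(rep_seq))
    stop("flank extends beyond replicon end", call. = FALSE)
  probe <- substr(rep_seq, a + 1L, b)
  if (site$strand == "-") probe <- revcomp(probe)
  probe
}

#' Write a site table as TSV or BED6
#'
#' BED uses 0-based half-open coordinates, `name` = locus_tag and
#' `score` = site score times 100, rounded.
#'
#' @param sites Site table.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return Invisibly, the path.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(sites$replicon, sites$abs_start, sites$abs_end,
                      sites$locus_tag, round(sites$score * 100),
                      sites$strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
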