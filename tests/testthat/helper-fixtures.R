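# Shared fixtures, all built in code.

# deterministic random DNA
rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# two-gene toy genome on one 1200-bp replicon: g1 on +, g2 on -
toy_genome <- function(seed = 11) {
  set.seed(seed)
  seq <- rand_dna(1200)
  genes <- data.frame(
    locus_tag = c("g1", "g2"),
    replicon = "chr",
    strand = c("+", "-"),
    cds_start = c(600L, 900L),
    cds_end = c(750L, 1100L),
    protein = "",
    stringsAsFactors = FALSE)
  annotated_genome("toy", c(chr = seq), genes)
}

# hand-written GenBank flat file for two CDS on a short replicon
write_toy_genbank <- function(path, seq) {
  n <- nchar(seq)
  blocks <- substring(seq, seq(1, n, 60), pmin(seq(60, n + 59, 60), n))
  origin <- vapply(seq_along(blocks), function(i) {
    b <- blocks[i]
    chunks <- substring(b, seq(1, nchar(b), 10), pmin(seq(10, nchar(b) + 9, 10),
                                                      nchar(b)))
    sprintf("%9d %s", (i - 1) * 60 + 1, paste(tolower(chunks), collapse = " "))
  }, character(1))
  writeLines(c(
    sprintf("LOCUS       chr %d bp    DNA     linear   BCT 01-JAN-2000", n),
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    "     CDS             31..90",
    '                     /locus_tag="tg1"',
    '                     /translation="MAAAAAAAAAAAAAAAAAA"',
    "     CDS             complement(121..180)",
    '                     /locus_tag="tg2"',
    "ORIGIN",
    origin,
    "//"), path)
  path
}

# independent naive scanner used as the brute-force oracle: enumerates every
# window of every gene's upstream region on both strands with plain loops
oracle_scan <- function(genome, pwm, config) {
  rc1 <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s),
                                        "")[[1]]), collapse = "")
  L <- pwm$length
  rows <- list()
  for (lt in genome$genes$locus_tag) {
    reg <- extract_upstream(genome, lt, config$window)
    n <- nchar(reg$sequence)
    if (n < L) next
    for (off in 0:(n - L)) {
      for (ms in if (config$both_strands) c("+", "-") else "+") {
        w <- substr(reg$sequence, off + 1, off + L)
        if (ms == "-") w <- rc1(w)
        ch <- strsplit(w, "")[[1]]
        sc <- 0
        for (k in 1:L) {
          b <- match(ch[k], c("A", "C", "G", "T"))
          sc <- if (is.na(b)) -Inf else sc + pwm$weights[b, k]
        }
        if (sc >= config$threshold)
          rows[[length(rows) + 1L]] <- data.frame(
            locus_tag = lt, offset = off, match_strand = ms, score = sc,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  all_rows <- do.call(rbind, rows)
  # declared dedup convention: opposite-strand hits whose starts differ by
  # <= dedup_radius collapse to the higher-scoring one (ties: "+", then the
  # smaller offset)
  out <- NULL
  for (lt in unique(all_rows$locus_tag)) {
    d <- all_rows[all_rows$locus_tag == lt, ]
    d <- d[order(-d$score, d$match_strand != "+", d$offset), ]
    kept <- integer(0)
    for (i in seq_len(nrow(d))) {
      dup <- FALSE
      for (j in kept) {
        if (d$match_strand[i] != d$match_strand[j] &&
            abs(d$offset[i] - d$offset[j]) <= config$dedup_radius) {
          dup <- TRUE; break
        }
      }
      if (!dup) kept <- c(kept, i)
    }
    out <- rbind(out, d[kept, ])
  }
  out
}

# map package scan output back to (locus, region offset, match strand)
scan_as_offsets <- function(genome, sites, config, L) {
  if (!nrow(sites)) return(NULL)
  out <- lapply(seq_len(nrow(sites)), function(i) {
    gene <- genome$genes[genome$genes$locus_tag == sites$locus_tag[i], ]
    reg <- extract_upstream(genome, sites$locus_tag[i], config$window)
    if (gene$strand == "+") {
      off <- sites$abs_start[i] - reg$abs_start
      ms <- if (sites$strand[i] == gene$strand) "+" else "-"
    } else {
      off <- reg$abs_end - sites$abs_end[i]
      ms <- if (sites$strand[i] == gene$strand) "+" else "-"
    }
    data.frame(locus_tag = sites$locus_tag[i], offset = off,
               match_strand = ms, score = sites$score[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# small clade used by several integration tests
small_clade <- function(seed = 7, ...) {
  suppressMessages(simulate_clade(n_genomes = 3, n_genes = 12,
                                  n_regulon = 4, n_decoys = 3, seed = seed,
                                  ...))
}
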