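# Upstream scanning: plant-and-recover, dedup, strand handling, probes.

plant_in_genome <- function(genome, locus_tag, rel_start, site) {
  gene <- genome$genes[genome$genes$locus_tag == locus_tag, ]
  L <- nchar(site)
  lin <- ifelse(rel_start > 0, rel_start - 1L, rel_start)
  if (gene$strand == "+") {
    a <- gene$cds_start + lin
    s <- site
  } else {
    a <- gene$cds_end - 1L - lin - (L - 1L)
    s <- revcomp(site)
  }
  seq <- genome$replicons[[gene$replicon]]
  substr(seq, a + 1L, a + L) <- s
  genome$replicons[[gene$replicon]] <- seq
  genome
}

test_that("a planted consensus site is recovered at its planted position", {
  set.seed(201)
  pwm <- build_pwm(sample_sites(default_generating_pwm(), 10),
                   palindromic = TRUE)
  g <- toy_genome(seed = 201)
  g <- plant_in_genome(g, "g1", -75L, pwm_consensus(pwm))
  cfg <- scan_config(threshold = 0.8 * score_sequence(pwm, pwm_consensus(pwm)))
  hits <- scan_gene(g, "g1", pwm, cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$rel_start, -75L)
  expect_equal(hits$score, score_sequence(pwm, pwm_consensus(pwm)),
               tolerance = 1e-9)
  # palindromic matrix: dedup leaves one hit, not two strand mirrors
  cfg2 <- scan_config(threshold = cfg$threshold, dedup_radius = 0L)
  expect_equal(nrow(scan_gene(g, "g1", pwm, cfg2)), 1L)

  # minus-strand gene: same machinery, gene-relative position preserved
  g2 <- plant_in_genome(toy_genome(seed = 202), "g2", -60L,
                        pwm_consensus(pwm))
  hits2 <- scan_gene(g2, "g2", pwm, cfg)
  expect_equal(hits2$rel_start, -60L)
})

test_that("a quiet region yields no hits and short regions scan empty", {
  set.seed(203)
  pwm <- build_pwm(sample_sites(default_generating_pwm(), 10),
                   palindromic = TRUE)
  g <- toy_genome(seed = 203)
  cfg <- scan_config(threshold = 0.9 * score_sequence(pwm, pwm_consensus(pwm)))
  expect_equal(nrow(scan_gene(g, "g1", pwm, cfg)), 0L)
  # gene 10 bp from the contig start, window of 15 bp < motif length
  genes <- data.frame(locus_tag = "tiny", replicon = "c", strand = "+",
                      cds_start = 10L, cds_end = 40L, protein = "")
  gt <- annotated_genome("t", c(c = rand_dna(60)), genes)
  expect_message(h <- scan_gene(gt, "tiny", pwm, scan_config(
    window = c(-10L, 5L), threshold = 0)), "shorter")
  expect_equal(nrow(h), 0L)
})

test_that("a site in a shared divergent intergenic region is reported per gene", {
  set.seed(204)
  pwm <- build_pwm(sample_sites(default_generating_pwm(), 10),
                   palindromic = TRUE)
  # divergent pair: gA on - strand [100, 400), gB on + strand [600, 900)
  seq <- rand_dna(1000)
  genes <- data.frame(locus_tag = c("gA", "gB"), replicon = "c",
                      strand = c("-", "+"), cds_start = c(100L, 600L),
                      cds_end = c(400L, 900L), protein = "")
  g <- annotated_genome("t", c(c = seq), genes)
  g <- plant_in_genome(g, "gB", -100L, pwm_consensus(pwm))
  cfg <- scan_config(threshold = 0.8 * score_sequence(pwm, pwm_consensus(pwm)))
  tab <- scan_genome(g, pwm, cfg)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$locus_tag, c("gA", "gB"))
  expect_equal(unique(tab$abs_start), 500L)   # one physical interval
  expect_equal(n_operators(tab), 1L)
})

test_that("the scanner agrees exactly with brute-force enumeration", {
  set.seed(205)
  pwm <- build_pwm(sample_sites(default_generating_pwm(), 15),
                   palindromic = TRUE)
  sim <- small_clade(seed = 205)
  g <- sim$genomes[[1]]
  cfg <- scan_config(threshold = 20)
  got <- scan_as_offsets(g, scan_genome(g, pwm, cfg), cfg, pwm$length)
  want <- oracle_scan(g, pwm, cfg)
  key <- function(d) {
    d <- d[order(d$locus_tag, d$offset, d$match_strand), ]
    paste(d$locus_tag, d$offset, d$match_strand, round(d$score, 9))
  }
  expect_false(is.null(want))   # the clade genomes contain hits
  expect_identical(key(got), key(want))
})

test_that("hit coordinates are shift-equivariant", {
  set.seed(206)
  pwm <- build_pwm(sample_sites(default_generating_pwm(), 10),
                   palindromic = TRUE)
  g <- plant_in_genome(toy_genome(seed = 206), "g1", -75L,
                       pwm_consensus(pwm))
  k <- 37L
  shifted_genes <- g$genes
  shifted_genes$cds_start <- shifted_genes$cds_start + k
  shifted_genes$cds_end <- shifted_genes$cds_end + k
  g2 <- annotated_genome("t2", c(chr = paste0(rand_dna(k),
                                              g$replicons[["chr"]])),
                         shifted_genes)
  cfg <- scan_config(threshold = 0.8 * score_sequence(pwm, pwm_consensus(pwm)))
  h1 <- scan_genome(g, pwm, cfg)
  h2 <- scan_genome(g2, pwm, cfg)
  expect_equal(h2$abs_start, h1$abs_start + k)
  expect_equal(h2$rel_start, h1$rel_start)
  expect_equal(h2$score, h1$score)
})

test_that("EMSA probes carry symmetric flanks on the match strand", {
  set.seed(207)
  pwm <- build_pwm(sample_sites(default_generating_pwm(), 10),
                   palindromic = TRUE)
  g <- plant_in_genome(toy_genome(seed = 207), "g1", -75L,
                       pwm_consensus(pwm))
  cfg <- scan_config(threshold = 0.8 * score_sequence(pwm, pwm_consensus(pwm)))
  site <- scan_gene(g, "g1", pwm, cfg)[1, ]
  probe <- make_emsa_probe(g, site, flank = 14L)
  expect_equal(nchar(probe), 49L)   # 21 + 2 x 14
  expect_equal(substr(probe, 15, 35), site$sequence)
  expect_equal(make_emsa_probe(g, site, flank = 0L), site$sequence)
  # opposite-strand representation of the same interval gives the revcomp
  flip <- site; flip$strand <- if (site$strand == "+") "-" else "+"
  expect_equal(make_emsa_probe(g, flip, 14L), revcomp(probe))
  # flank beyond the contig edge errors
  edge <- site; edge$abs_start <- 3L; edge$abs_end <- 24L
  expect_error(make_emsa_probe(g, edge, 14L), "flank")
})

test_that("site tables export as TSV and BED6", {
  set.seed(208)
  pwm <- build_pwm(sample_sites(default_generating_pwm(), 10),
                   palindromic = TRUE)
  g <- plant_in_genome(toy_genome(seed = 208), "g1", -75L,
                       pwm_consensus(pwm))
  tab <- scan_genome(g, pwm, scan_config(
    threshold = 0.8 * score_sequence(pwm, pwm_consensus(pwm))))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites(tab, tsv)
  write_sites(tab, bed, format = "bed")
  back <- read.delim(tsv)
  expect_equal(back$abs_start, tab$abs_start)
  bed_tab <- read.delim(bed, header = FALSE)
  expect_equal(bed_tab$V2, tab$abs_start)
  expect_equal(bed_tab$V5, round(tab$score * 100))
})
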