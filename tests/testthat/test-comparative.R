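# Orthology, operons, consistency filtering, regulon assembly, footprints
# and per-clade refinement.

test_that("BBH on identical proteomes is the identity map", {
  sim <- small_clade(seed = 301)
  a <- sim$genomes[[1]]
  b <- a; b$genome_id <- "copy"
  b$genes$locus_tag <- sub("sim1", "copy", b$genes$locus_tag)
  m <- bbh_orthologs(a, b)
  expect_equal(nrow(m), nrow(a$genes))
  expect_equal(sub("sim1", "copy", m$locus_a), m$locus_b)
  expect_true(all(m$identity == 1))

  # deleting one protein removes exactly that pair
  b2 <- b
  b2$genes <- b2$genes[b2$genes$locus_tag != "copy_0005", ]
  m2 <- bbh_orthologs(a, b2)
  expect_equal(setdiff(m$locus_a, m2$locus_a), "sim1_0005")
})

test_that("BBH recovers simulated ortholog pairs at 10% divergence", {
  sim <- suppressMessages(simulate_clade(
    n_genomes = 2, n_genes = 30, n_regulon = 5, n_decoys = 0,
    divergence = 0.10, seed = 302))
  m <- bbh_orthologs(sim$genomes[[1]], sim$genomes[[2]])
  tp <- sim$truth$ortholog_pairs
  truth_keys <- paste(tp$locus_a, tp$locus_b)
  got_keys <- paste(m$locus_a, m$locus_b)
  expect_gte(sum(got_keys %in% truth_keys) / length(truth_keys), 0.95)
  expect_error(bbh_orthologs(sim$genomes[[1]], annotated_genome(
    "empty", c(c = "ACGTACGT"), data.frame(
      locus_tag = "x", replicon = "c", strand = "+", cds_start = 0L,
      cds_end = 8L, protein = ""))), "empty proteome")
})

test_that("operon prediction groups same-strand runs by the gap rule", {
  mk <- function(strands, starts, ends) {
    annotated_genome("t", c(c = strrep("A", max(ends) + 10)),
                     data.frame(locus_tag = paste0("g", seq_along(strands)),
                                replicon = "c", strand = strands,
                                cds_start = starts, cds_end = ends,
                                protein = ""))
  }
  # single gene -> singleton operon
  ops <- predict_operons(mk("+", 0L, 300L))
  expect_equal(nrow(ops), 1L)
  expect_true(ops$lead)
  # three same-strand contiguous genes -> one operon led by the 5'-most
  g3 <- mk(c("+", "+", "+"), c(0L, 350L, 700L), c(300L, 650L, 1000L))
  ops3 <- predict_operons(g3, max_gap = 150L)
  expect_equal(length(unique(ops3$operon_id)), 1L)
  expect_equal(ops3$locus_tag[ops3$lead], "g1")
  # gaps 100 and 300 split after the second gene
  g_split <- mk(c("+", "+", "+"), c(0L, 400L, 1100L), c(300L, 800L, 1400L))
  ops_split <- predict_operons(g_split, max_gap = 150L)
  grouped <- tapply(ops_split$locus_tag, ops_split$operon_id, paste,
                    collapse = ",")
  expect_equal(as.character(grouped[unique(ops_split$operon_id)]),
               c("g1,g2", "g3"))
  # minus-strand operon: the highest-coordinate gene leads
  gm <- mk(c("-", "-"), c(0L, 350L), c(300L, 650L))
  opsm <- predict_operons(gm, max_gap = 150L)
  expect_equal(opsm$locus_tag[opsm$lead], "g2")
  # strand switch always breaks an operon
  gs <- mk(c("+", "-"), c(0L, 310L), c(300L, 600L))
  expect_equal(length(unique(predict_operons(gs)$operon_id)), 2L)
})

test_that("operons partition the gene set", {
  sim <- small_clade(seed = 303)
  for (g in sim$genomes) {
    ops <- predict_operons(g)
    expect_setequal(ops$locus_tag, g$genes$locus_tag)
    expect_equal(anyDuplicated(ops$locus_tag), 0L)
  }
})

# hand-built three-genome fixture for the consistency filter: gene "a" has a
# conserved site in all genomes, gene "b" a decoy in genome 1 only
filter_fixture <- function() {
  site_row <- function(g, lt, a) data.frame(
    genome_id = g, locus_tag = lt, replicon = "c", abs_start = a,
    abs_end = a + 21L, rel_start = -50L, strand = "+", score = 30,
    sequence = strrep("A", 21), stringsAsFactors = FALSE)
  genomes <- paste0("G", 1:3)
  sites <- list(
    G1 = rbind(site_row("G1", "a1", 100L), site_row("G1", "b1", 500L)),
    G2 = site_row("G2", "a2", 120L),
    G3 = site_row("G3", "a3", 90L))
  operons <- lapply(1:3, function(i) data.frame(
    locus_tag = paste0(c("a", "b"), i), operon_id = paste0("op", c("A", "B")),
    lead = TRUE, strand = "+", stringsAsFactors = FALSE))
  names(operons) <- genomes
  mk_map <- function(a, b, i, j) structure(
    data.frame(locus_a = paste0(c("a", "b"), i),
               locus_b = paste0(c("a", "b"), j),
               score = 100, identity = 1, coverage = 1,
               stringsAsFactors = FALSE),
    class = c("ortholog_map", "data.frame"), genome_a = a, genome_b = b)
  maps <- list("G1|G2" = mk_map("G1", "G2", 1, 2),
               "G1|G3" = mk_map("G1", "G3", 1, 3),
               "G2|G3" = mk_map("G2", "G3", 2, 3))
  list(sites = sites, operons = operons, maps = maps)
}

test_that("consistency filter keeps conserved sites and drops solitary ones", {
  fx <- filter_fixture()
  fl <- consistency_filter(fx$sites, fx$maps, fx$operons, min_support = 2)
  expect_equal(fl$G1$locus_tag, "a1")      # decoy at b1 removed
  expect_equal(fl$G2$locus_tag, "a2")
  expect_equal(fl$G3$locus_tag, "a3")
  supp <- attr(fl, "support")
  expect_equal(supp$support[supp$genome_id == "G1" & supp$operon_id == "opA"],
               2L)
  expect_equal(supp$support[supp$genome_id == "G1" & supp$operon_id == "opB"],
               0L)
})

test_that("raising min_support never adds retained sites, and the filter is idempotent", {
  fx <- filter_fixture()
  counts <- vapply(0:3, function(ms) {
    fl <- consistency_filter(fx$sites, fx$maps, fx$operons, min_support = ms)
    sum(vapply(fl, nrow, integer(1)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  fl1 <- consistency_filter(fx$sites, fx$maps, fx$operons, min_support = 2)
  fl2 <- consistency_filter(unclass(fl1)[names(fx$sites)], fx$maps,
                            fx$operons, min_support = 2)
  for (g in names(fx$sites)) expect_equal(fl2[[g]], fl1[[g]])
  # missing genome pair in the maps is an error
  expect_error(consistency_filter(fx$sites, fx$maps["G1|G2"], fx$operons),
               "no ortholog map")
})

test_that("regulon assembly expands operons from their operator-bearing leads", {
  # one operator upstream of a 3-gene operon -> 3 member genes, 1 operator
  operons <- data.frame(locus_tag = c("x1", "x2", "x3"), operon_id = "op1",
                        lead = c(TRUE, FALSE, FALSE), strand = "+",
                        stringsAsFactors = FALSE)
  genes <- data.frame(locus_tag = c("x1", "x2", "x3"), replicon = "c",
                      strand = "+", cds_start = c(0L, 400L, 800L),
                      cds_end = c(300L, 700L, 1100L), protein = "")
  g <- annotated_genome("t", c(c = strrep("A", 1200)), genes)
  site <- data.frame(genome_id = "t", locus_tag = "x1", replicon = "c",
                     abs_start = 10L, abs_end = 31L, rel_start = -50L,
                     strand = "+", score = 25, sequence = strrep("A", 21),
                     stringsAsFactors = FALSE)
  reg <- assemble_regulon(site, operons, g, tf_name = "NagR",
                          tf_locus = "x1")
  expect_setequal(reg$genes, c("x1", "x2", "x3"))
  expect_equal(reg$n_operators, 1L)
  expect_equal(reg$n_genes, 3L)
  expect_equal(reg$n_genes_excl_tf, 2L)
  # a hit on an interior gene recruits the same operon
  site2 <- site; site2$locus_tag <- "x2"
  expect_setequal(assemble_regulon(site2, operons, g)$genes,
                  c("x1", "x2", "x3"))
  # no retained sites -> empty regulon
  empty <- assemble_regulon(site[0, ], operons, g)
  expect_equal(empty$n_genes, 0L)
  expect_equal(empty$n_operators, 0L)
})

test_that("footprint alignment anchors at operators and scores conservation", {
  mk_region <- function(seq, rel_start = -60L) structure(
    list(locus_tag = "x", strand = "+", replicon = "c",
         rel_start = rel_start, rel_end = 9L, abs_start = 0L,
         abs_end = nchar(seq), sequence = seq, clipped = FALSE),
    class = "upstream_region")
  mk_site <- function(rel) data.frame(rel_start = rel)
  set.seed(304)
  base <- rand_dna(70)
  regions <- list(g1 = mk_region(base), g2 = mk_region(base))
  sites <- list(g1 = mk_site(-40L), g2 = mk_site(-40L))
  fp <- footprint_alignment(regions, sites, motif_length = 21L)
  expect_true(all(fp$conservation == 1))
  expect_equal(length(fp$operator_cols), 21L)

  # one substitution inside the operator across two genomes -> 0.5 column
  mut <- base
  pos <- 25L   # inside the operator (offset 21..41 for rel -40 of -60 start)
  substr(mut, pos, pos) <- if (substr(mut, pos, pos) == "A") "C" else "A"
  fp2 <- footprint_alignment(list(g1 = mk_region(base), g2 = mk_region(mut)),
                             sites, motif_length = 21L)
  expect_equal(sum(fp2$conservation == 0.5), 1L)
  expect_true(pos %in% fp2$operator_cols)

  # a region lacking a site is listed unanchored
  fp3 <- footprint_alignment(
    list(g1 = mk_region(base), g2 = mk_region(base), g3 = mk_region(mut)),
    list(g1 = mk_site(-40L), g2 = mk_site(-40L), g3 = NULL))
  expect_equal(fp3$unanchored, "g3")
})

test_that("operator columns are more conserved than flanks in a simulated family", {
  sim <- suppressMessages(simulate_clade(
    n_genomes = 5, n_genes = 10, n_regulon = 3, n_decoys = 0,
    divergence = 0.05, in_site_divergence = 0.01, seed = 305))
  tr <- sim$truth$sites[sim$truth$sites$source == "regulon", ]
  anchor <- tr[tr$gene_index == tr$gene_index[1], ]
  regions <- list(); sites <- list()
  for (i in seq_len(nrow(anchor))) {
    g <- anchor$genome_id[i]
    regions[[g]] <- extract_upstream(sim$genomes[[g]], anchor$locus_tag[i])
    # gene-relative start of the planted interval
    gene <- sim$genomes[[g]]$genes[
      sim$genomes[[g]]$genes$locus_tag == anchor$locus_tag[i], ]
    lin <- if (gene$strand == "+") anchor$abs_start[i] - gene$cds_start else
      gene$cds_end - anchor$abs_end[i]
    sites[[g]] <- data.frame(rel_start = ifelse(lin >= 0, lin + 1, lin))
  }
  fp <- footprint_alignment(regions, sites)
  flank <- setdiff(seq_along(fp$conservation), fp$operator_cols)
  expect_gt(mean(fp$conservation[fp$operator_cols], na.rm = TRUE),
            mean(fp$conservation[flank], na.rm = TRUE))
})

test_that("per-clade refinement recovers clade-specific motifs", {
  v1 <- default_generating_pwm()
  half <- "GGCGTACTAC"
  cons2 <- paste0(half, "A", revcomp(half))
  v2 <- matrix(0.1 / 3, 4, 21, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(cons2, "")[[1]], c("A", "C", "G", "T"))
  v2[cbind(idx, 1:21)] <- 0.9
  v2[, 11] <- 0.25
  set.seed(306)
  tabs <- list(
    a1 = data.frame(sequence = sample_sites(v1, 12)),
    a2 = data.frame(sequence = sample_sites(v1, 12)),
    b1 = data.frame(sequence = sample_sites(v2, 12)),
    b2 = data.frame(sequence = sample_sites(v2, 12)))
  init <- build_pwm(sample_sites(v1, 6), palindromic = FALSE)
  clades <- list(cladeA = c("a1", "a2"), cladeB = c("b1", "b2"))
  ref <- refine_pwm_per_clade(clades, init, tabs)
  cons <- function(f) paste(c("A", "C", "G", "T")[apply(f, 2, which.max)],
                            collapse = "")
  # ignore the free central column when comparing consensus strings
  drop11 <- function(s) paste0(substr(s, 1, 10), substr(s, 12, 21))
  expect_equal(drop11(pwm_consensus(ref$cladeA)), drop11(cons(v1)))
  expect_equal(drop11(pwm_consensus(ref$cladeB)), drop11(cons(v2)))
  # a single clade with all genomes equals the pooled rebuild
  ref_all <- refine_pwm_per_clade(list(all = names(tabs)), init, tabs)
  pooled <- build_pwm(unlist(lapply(tabs, `[[`, "sequence"),
                             use.names = FALSE))
  expect_equal(ref_all$all$weights, pooled$weights, tolerance = 1e-12)
  # clade with a single retained site falls back to the global matrix
  tabs_sparse <- tabs
  tabs_sparse$b1 <- tabs$b1[1, , drop = FALSE]
  tabs_sparse$b2 <- tabs$b2[0, , drop = FALSE]
  expect_message(
    ref_fb <- refine_pwm_per_clade(list(lone = "b2"), init, tabs_sparse),
    "falling back")
  expect_equal(ref_fb$lone$weights, ref_fb$global$weights)
})

test_that("newick trees split into root clades", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1,e:1):1);")
  groups <- clade_groups(tree)
  expect_equal(length(groups), 2L)
  expect_setequal(groups[[1]], c("a", "b"))
  expect_setequal(groups[[2]], c("c", "d", "e"))
})
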