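# Ground-truthed simulator: clades of annotated genomes with planted
# operators and single-genome decoys, plus titration and growth curves.
#
# The clade generator emulates the comparative setting the reconstruction
# assumes: a family of related high-GC genomes whose regulon members carry
# orthologous operators under purifying selection (lower in-site mutation
# rate than background), while decoy sites — drawn from the same generating
# motif, so indistinguishable by score — occur in a single genome only and
# can be removed only by cross-genome support.

#' Default generating frequency matrix for a 21-bp palindromic operator
#'
#' A palindromic consensus with per-column consensus probability
#' `consensus_prob` (remaining mass split over the other bases) and a
#' uniform central column.
#'
#' @param consensus_prob Probability of the consensus base per column
#'   (default 0.9).
#' @return 4 x 21 column-stochastic matrix (rows A,C,G,T).
#' @export
default_generating_pwm <- function(consensus_prob = 0.9) {
  half <- "AATTACAACC"
  consensus <- paste0(half, "A", revcomp(half))
  L <- nchar(consensus)
  f <- matrix((1 - consensus_prob) / 3, 4L, L,
              dimnames = list(DNA_BASES, NULL))
  cons <- .base_index(consensus)
  f[cbind(cons, seq_len(L))] <- consensus_prob
  f[, (L + 1L) / 2] <- 0.25   # free central column
  f
}

#' Sample sites from a generating frequency matrix
#'
#' @param freq 4 x L column-stochastic matrix (rows A,C,G,T).
#' @param n Number of sites.
#' @param seed Optional RNG seed.
#' @return Character vector of n L-mers.
#' @export
sample_sites <- function(freq, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(freq)
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(L), function(k)
      sample(DNA_BASES, 1L, prob = freq[, k]), character(1)), collapse = "")
  }, character(1))
}

.random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

.STOPS <- c("TAA", "TAG", "TGA")

# rewrite a CDS (character vector of the whole replicon, coding-strand
# extracted) into a valid ORF: ATG start, TGA stop, no internal stops
.fix_orf <- function(cds, gc) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  codons[1] <- "ATG"
  codons[length(codons)] <- "TGA"
  internal <- codons[-c(1L, length(codons))]
  bad <- internal %in% .STOPS
  while (any(bad)) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    internal[bad] <- vapply(which(bad), function(i)
      paste(sample(DNA_BASES, 3L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    bad <- internal %in% .STOPS
  }
  codons[-c(1L, length(codons))] <- internal
  paste(codons, collapse = "")
}

# substitute positions of a character-vector sequence at per-position rates
.mutate <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(hit, function(i)
      sample(setdiff(DNA_BASES, chars[i]), 1L), character(1))
  }
  chars
}

#' Simulate a clade of annotated genomes with planted operators
#'
#' Builds one ancestral genome (random sequence at the target GC, genes on
#' alternating strands with sampled intergenic gaps, proteins = translated
#' CDS), plants operator instances sampled from the generating motif into
#' the upstream windows of a designated regulon, derives each leaf by
#' i.i.d. substitutions (a lower rate inside planted sites models purifying
#' selection), and finally plants each decoy — drawn from the same motif —
#' into a single random non-regulon gene's window of a single leaf.
#'
#' The returned truth lists, per genome, every planted interval with its
#' source, the ortholog pairs, and the regulon gene set. Because upstream
#' windows of neighboring genes overlap (shared intergenic regions), the
#' truth regulon is derived as the set of genes *governed* by the planted
#' operators: all members of every transcription unit (same-strand runs
#' with gaps <= `operon_max_gap`) in which some gene's window fully
#' contains a planted site. Decoy genes are drawn outside that governed
#' set, at positions whose intervals fall in no governed gene's window.
#'
#' @param n_genomes,n_genes Clade size and genes per genome.
#' @param gene_length,intergenic Uniform sampling bounds (bp).
#' @param gc GC content of the ancestral sequence.
#' @param generating_pwms List of 4 x L frequency matrices, one per clade.
#' @param clade_assignment Integer vector (length `n_genomes`) assigning
#'   each leaf to a clade; default all clade 1.
#' @param n_regulon Number of regulon anchor genes.
#' @param site_positions Bounds for the planted site's gene-relative start
#'   (default `c(-120, -30)`).
#' @param divergence Background per-site substitution probability per leaf.
#' @param in_site_divergence Substitution probability inside planted sites.
#' @param n_decoys Number of decoy sites (each in exactly one genome).
#' @param window Upstream window convention used to derive the governed
#'   truth set.
#' @param operon_max_gap Operon gap rule used to derive the truth set.
#' @param seed RNG seed (full reproducibility).
#' @param out_dir If non-NULL, writes FASTA+GFF3 per leaf, `truth.json`,
#'   `clade.nwk` and `training_sites.txt` there.
#' @return List: `genomes` (named list of [annotated_genome()]), `truth`
#'   (sites table, regulon gene indices/locus tags, ortholog pairs,
#'   governed TU table), `training_sites` (per clade: the clade-ancestral
#'   planted sites), `generating_pwms`, `clade_assignment`, `tree`
#'   (newick string), `dir`.
#' @export
simulate_clade <- function(n_genomes = 5L, n_genes = 50L,
                           gene_length = c(300L, 1500L),
                           intergenic = c(50L, 400L), gc = 0.60,
                           generating_pwms = list(default_generating_pwm()),
                           clade_assignment = rep(1L, n_genomes),
                           n_regulon = 20L,
                           site_positions = c(-120L, -30L),
                           divergence = 0.05, in_site_divergence = 0.02,
                           n_decoys = 10L, window = c(-500L, 50L),
                           operon_max_gap = 150L, seed = 1L,
                           out_dir = NULL) {
  stopifnot(n_regulon <= n_genes, length(clade_assignment) == n_genomes)
  set.seed(seed)
  names(generating_pwms) <- as.character(seq_along(generating_pwms))
  L <- ncol(generating_pwms[[1]])

  # --- ancestral layout -------------------------------------------------
  glen <- sample(seq(gene_length[1], gene_length[2]), n_genes, replace = TRUE)
  glen <- pmax(300L, (glen %/% 3L) * 3L)
  gaps <- sample(seq(intergenic[1], intergenic[2]), n_genes, replace = TRUE)
  gaps[1] <- 550L   # room for the first gene's window
  strand <- rep(c("+", "-"), length.out = n_genes)
  cds_start <- integer(n_genes); cds_end <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    pos <- pos + gaps[i]
    cds_start[i] <- pos
    cds_end[i] <- pos + glen[i]
    pos <- cds_end[i]
  }
  total <- pos + 550L
  anc <- strsplit(.random_dna(total, gc), "")[[1]]
  for (i in seq_len(n_genes)) {
    cds <- paste(anc[(cds_start[i] + 1L):cds_end[i]], collapse = "")
    if (strand[i] == "-") cds <- revcomp(cds)
    cds <- .fix_orf(cds, gc)
    if (strand[i] == "-") cds <- revcomp(cds)
    anc[(cds_start[i] + 1L):cds_end[i]] <- strsplit(cds, "")[[1]]
  }

  win_lo <- .rel_to_lin(window[1]); win_hi <- .rel_to_lin(window[2])
  window_abs <- function(i) {
    if (strand[i] == "+") c(cds_start[i] + win_lo, cds_start[i] + win_hi)
    else c(cds_end[i] - 1L - win_hi, cds_end[i] - 1L - win_lo)
  }  # inclusive base-index bounds, unclipped then clamped
  win_tab <- t(vapply(seq_len(n_genes), window_abs, numeric(2)))
  win_tab[, 1] <- pmax(win_tab[, 1], 0); win_tab[, 2] <- pmin(win_tab[, 2],
                                                              total - 1L)

  # --- plant regulon sites (positions shared by all leaves) -------------
  regulon_idx <- sort(sample(seq_len(n_genes), n_regulon))
  site_abs <- matrix(NA_integer_, n_regulon, 2L)
  for (r in seq_along(regulon_idx)) {
    i <- regulon_idx[r]
    repeat {
      rel <- sample(seq(site_positions[1], site_positions[2]), 1L)
      lin <- .rel_to_lin(rel)
      if (strand[i] == "+") {
        a <- cds_start[i] + lin
      } else {
        a <- cds_end[i] - 1L - lin - (L - 1L)
      }
      b <- a + L - 1L
      if (a < 0L || b >= total) next
      clash <- any(!is.na(site_abs[, 1]) & site_abs[, 1] <= b &
                     site_abs[, 2] >= a)
      if (!clash) break
      message("resampling planted-site position for gene ", i,
              " (overlap)")
    }
    site_abs[r, ] <- c(a, b)
  }

  # --- governed truth set ----------------------------------------------
  op_break <- c(TRUE, strand[-1] != strand[-n_genes] |
                  (cds_start[-1] - cds_end[-n_genes]) > operon_max_gap)
  tu <- cumsum(op_break)
  governed_tu <- integer(0)
  site_genes <- vector("list", n_regulon)
  for (r in seq_len(n_regulon)) {
    inside <- which(win_tab[, 1] <= site_abs[r, 1] &
                      win_tab[, 2] >= site_abs[r, 2])
    site_genes[[r]] <- inside
    governed_tu <- union(governed_tu, tu[inside])
  }
  truth_genes_idx <- sort(which(tu %in% governed_tu))

  # --- clade-ancestral site sequences and leaf genomes ------------------
  clades <- sort(unique(clade_assignment))
  clade_sites <- lapply(clades, function(cl)
    sample_sites(generating_pwms[[cl]], n_regulon))
  names(clade_sites) <- as.character(clades)

  site_mask <- rep(FALSE, total)
  for (r in seq_len(n_regulon))
    site_mask[(site_abs[r, 1] + 1L):(site_abs[r, 2] + 1L)] <- TRUE
  rate <- ifelse(site_mask, in_site_divergence, divergence)

  genome_ids <- sprintf("sim%d", seq_len(n_genomes))
  tags <- lapply(genome_ids, function(g)
    sprintf("%s_%04d", g, seq_len(n_genes)))
  names(tags) <- genome_ids

  plant <- function(chars, a, b, site_seq, gene_strand) {
    s <- if (gene_strand == "-") revcomp(site_seq) else site_seq
    chars[(a + 1L):(b + 1L)] <- strsplit(s, "")[[1]]
    chars
  }

  leaves <- list()
  for (gi in seq_len(n_genomes)) {
    cl <- as.character(clade_assignment[gi])
    chars <- anc
    for (r in seq_len(n_regulon)) {
      i <- regulon_idx[r]
      chars <- plant(chars, site_abs[r, 1], site_abs[r, 2],
                     clade_sites[[cl]][r], strand[i])
    }
    chars <- .mutate(chars, rate)
    leaves[[genome_ids[gi]]] <- chars
  }

  # --- decoys: one genome each, outside governed windows ----------------
  governed_gene_idx <- which(tu %in% governed_tu)
  free_genes <- setdiff(seq_len(n_genes), governed_gene_idx)
  decoy_rows <- list()
  decoy_genes <- sample(free_genes, min(n_decoys, length(free_genes)))
  decoy_leaf <- sample(seq_len(n_genomes), length(decoy_genes),
                       replace = TRUE)
  for (d in seq_along(decoy_genes)) {
    i <- decoy_genes[d]
    ok <- FALSE
    for (try in 1:50) {
      rel <- sample(seq(site_positions[1], site_positions[2]), 1L)
      lin <- .rel_to_lin(rel)
      a <- if (strand[i] == "+") cds_start[i] + lin else
        cds_end[i] - 1L - lin - (L - 1L)
      b <- a + L - 1L
      if (a < 0L || b >= total) next
      in_governed_window <- any(win_tab[governed_gene_idx, 1] <= a &
                                  win_tab[governed_gene_idx, 2] >= b)
      clash <- any(site_abs[, 1] <= b & site_abs[, 2] >= a)
      if (!in_governed_window && !clash) { ok <- TRUE; break }
    }
    if (!ok) {
      message("could not place decoy in gene ", i, "; skipped")
      next
    }
    gi <- decoy_leaf[d]
    cl <- as.character(clade_assignment[gi])
    dseq <- sample_sites(generating_pwms[[cl]], 1L)
    leaves[[genome_ids[gi]]] <- plant(leaves[[genome_ids[gi]]], a, b, dseq,
                                      strand[i])
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      genome_id = genome_ids[gi], gene_index = i,
      locus_tag = tags[[genome_ids[gi]]][i], replicon = "chr",
      abs_start = a, abs_end = b + 1L, source = "decoy",
      stringsAsFactors = FALSE)
  }

  # --- assemble annotated genomes --------------------------------------
  genomes <- list()
  for (gi in seq_len(n_genomes)) {
    g <- genome_ids[gi]
    seqchr <- paste(leaves[[g]], collapse = "")
    genes <- data.frame(
      locus_tag = tags[[g]], replicon = "chr", strand = strand,
      cds_start = cds_start, cds_end = cds_end, protein = "",
      stringsAsFactors = FALSE)
    cds <- vapply(seq_len(n_genes), function(i) {
      s <- substr(seqchr, cds_start[i] + 1L, cds_end[i])
      if (strand[i] == "-") revcomp(s) else s
    }, character(1))
    genes$protein <- .translate_batch(cds)
    genomes[[g]] <- annotated_genome(g, c(chr = seqchr), genes)
  }

  # --- truth tables -----------------------------------------------------
  site_rows <- do.call(rbind, lapply(seq_len(n_genomes), function(gi) {
    g <- genome_ids[gi]
    do.call(rbind, lapply(seq_len(n_regulon), function(r) {
      i <- regulon_idx[r]
      data.frame(genome_id = g, gene_index = i, locus_tag = tags[[g]][i],
                 replicon = "chr", abs_start = site_abs[r, 1],
                 abs_end = site_abs[r, 2] + 1L, source = "regulon",
                 stringsAsFactors = FALSE)
    }))
  }))
  if (length(decoy_rows)) site_rows <- rbind(site_rows,
                                             do.call(rbind, decoy_rows))
  ortholog_pairs <- if (n_genomes >= 2L)
    do.call(rbind, lapply(utils::combn(n_genomes, 2, simplify = FALSE),
      function(pr) data.frame(genome_a = genome_ids[pr[1]],
                              genome_b = genome_ids[pr[2]],
                              locus_a = tags[[pr[1]]], locus_b = tags[[pr[2]]],
                              stringsAsFactors = FALSE)))
  else data.frame(genome_a = character(0), genome_b = character(0),
                  locus_a = character(0), locus_b = character(0))
  regulon_tags <- lapply(genome_ids, function(g) tags[[g]][truth_genes_idx])
  names(regulon_tags) <- genome_ids

  # --- tree -------------------------------------------------------------
  tree <- if (length(clades) == 1L) {
    paste0("(", paste0(genome_ids, ":1", collapse = ","), ");")
  } else {
    paste0("(",
           paste(vapply(clades, function(cl) paste0(
             "(", paste0(genome_ids[clade_assignment == cl], ":1",
                         collapse = ","), "):1"), character(1)),
             collapse = ","),
           ");")
  }

  truth <- list(sites = site_rows, regulon_gene_index = truth_genes_idx,
                regulon_anchor_index = regulon_idx,
                regulon_tags = regulon_tags,
                ortholog_pairs = ortholog_pairs,
                tu = data.frame(gene_index = seq_len(n_genes), tu = tu,
                                governed = tu %in% governed_tu))
  training_sites <- clade_sites

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in genome_ids)
      write_genome(genomes[[g]], file.path(out_dir, paste0(g, ".fasta")),
                   file.path(out_dir, paste0(g, ".gff3")))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(tree, file.path(out_dir, "clade.nwk"))
    writeLines(unlist(training_sites, use.names = FALSE),
               file.path(out_dir, "training_sites.txt"))
  }
  list(genomes = genomes, truth = truth, training_sites = training_sites,
       generating_pwms = generating_pwms,
       clade_assignment = clade_assignment, tree = tree, dir = out_dir)
}

#' Simulate a titration curve from a 4PL model
#'
#' Concentrations are log-spaced over `[e/30, 30e]`; responses are the 4PL
#' value plus Gaussian noise, clipped to `[0, 1]`.
#'
#' @param e True EC50. @param b True slope (negative = increasing response).
#' @param n_points Number of concentrations. @param noise_sd Gaussian SD.
#' @param seed Optional RNG seed.
#' @return A [titration_curve()].
#' @export
simulate_titration <- function(e, b = -1.5, n_points = 8L, noise_sd = 0.03,
                               seed = NULL) {
  stopifnot(e > 0, n_points >= 4L)
  if (!is.null(seed)) set.seed(seed)
  x <- exp(seq(log(e / 30), log(30 * e), length.out = n_points))
  y <- 1 / (1 + (x / e)^b)
  if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
  titration_curve(x, pmin(1, pmax(0, y)))
}

#' Simulate a logistic growth curve with lag
#'
#' OD follows a logistic trajectory from `od0` to carrying capacity `K`
#' after a lag, plus Gaussian noise floored at 0.
#'
#' @param K Carrying capacity (OD). @param r Growth rate (1/h).
#' @param lag Lag time (h). @param od0 Inoculum OD.
#' @param t_max Duration (h). @param n_points Number of readings.
#' @param noise_sd Gaussian SD. @param seed Optional RNG seed.
#' @return List with `t` and `od`.
#' @export
simulate_growth <- function(K = 1, r = 0.6, lag = 2, od0 = 0.01,
                            t_max = 24, n_points = 25L, noise_sd = 0.01,
                            seed = NULL) {
  stopifnot(K > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, t_max, length.out = n_points)
  te <- pmax(0, t - lag)
  od <- K / (1 + ((K - od0) / od0) * exp(-r * te))
  if (noise_sd > 0) od <- pmax(0, od + stats::rnorm(n_points, 0, noise_sd))
  list(t = t, od = od)
}
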