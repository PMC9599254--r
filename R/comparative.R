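# Cross-genome machinery: BBH orthology, operon prediction, consistency
# filtering of candidate sites (phylogenetic footprinting), regulon
# assembly, operator-anchored footprint alignments and per-clade PWM
# refinement.

.strip_stop <- function(p) sub("\\*+$", "", p)

.kmer_sets <- function(p, k = 4L) {
  lapply(p, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

# score matrix of all-vs-all global protein alignments (rows = a, cols = b).
# Pairs that cannot reach min_coverage (length ratio) are skipped, as are
# pairs sharing fewer than `prescreen` of the shorter protein's 4-mers
# (shared fraction ~ identity^4, so the default 0.05 only discards pairs
# below roughly 47% identity); skipped entries stay -Inf.
.protein_score_matrix <- function(pa, pb, min_coverage, submat,
                                  prescreen = 0.05) {
  la <- nchar(pa); lb <- nchar(pb)
  m <- matrix(-Inf, length(pa), length(pb))
  ka <- if (prescreen > 0) .kmer_sets(pa) else NULL
  kb <- if (prescreen > 0) .kmer_sets(pb) else NULL
  ii <- integer(0); jj <- integer(0)
  for (j in seq_along(pb)) {
    ok <- pmin(la, lb[j]) / pmax(la, lb[j]) >= min_coverage
    if (prescreen > 0 && any(ok)) {
      share <- vapply(which(ok), function(i) {
        nmin <- min(length(ka[[i]]), length(kb[[j]]))
        if (!nmin) return(0)
        sum(ka[[i]] %in% kb[[j]]) / nmin
      }, numeric(1))
      ok[which(ok)[share < prescreen]] <- FALSE
    }
    ii <- c(ii, which(ok)); jj <- c(jj, rep(j, sum(ok)))
  }
  if (length(ii)) {
    # one elementwise call for all surviving candidate pairs
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pa[ii]), Biostrings::AAStringSet(pb[jj]),
      type = "global", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 1, scoreOnly = TRUE)
    m[cbind(ii, jj)] <- sc
  }
  m
}

.aa_submat <- function(match = 1, mismatch = -1) {
  letters <- c(Biostrings::AA_ALPHABET)
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Bidirectional-best-hit orthologs between two genomes
#'
#' Global pairwise protein alignment (match +1, mismatch -1, gap open -5,
#' extend -1); a pair is kept iff the proteins are each other's best hit,
#' percent identity over the alignment is at least `min_identity` and
#' mutual length coverage (shorter/longer) is at least `min_coverage`.
#'
#' @param genome_a,genome_b [annotated_genome()] objects with proteins.
#' @param min_identity Identity fraction cutoff (default 0.4).
#' @param min_coverage Coverage fraction cutoff (default 0.7).
#' @param prescreen Shared-4-mer fraction below which a protein pair is not
#'   aligned at all (default 0.05, roughly 47% identity; set 0 to align
#'   every length-compatible pair).
#' @return Object of class `ortholog_map`: data.frame (locus_a, locus_b,
#'   score, identity, coverage) with genome ids in attributes.
#' @export
bbh_orthologs <- function(genome_a, genome_b, min_identity = 0.4,
                          min_coverage = 0.7, prescreen = 0.05) {
  pa <- .strip_stop(genome_a$genes$protein)
  pb <- .strip_stop(genome_b$genes$protein)
  ka <- nzchar(pa); kb <- nzchar(pb)
  if (!any(ka) || !any(kb))
    stop("empty proteome in ", if (!any(ka)) genome_a$genome_id else
      genome_b$genome_id, call. = FALSE)
  la <- genome_a$genes$locus_tag[ka]; pa <- pa[ka]
  lb <- genome_b$genes$locus_tag[kb]; pb <- pb[kb]
  submat <- .aa_submat()
  sm <- .protein_score_matrix(pa, pb, min_coverage, submat, prescreen)
  best_ab <- apply(sm, 1L, which.max)
  best_ba <- apply(sm, 2L, which.max)
  rows <- which(is.finite(sm[cbind(seq_along(pa), best_ab)]) &
                  best_ba[best_ab] == seq_along(pa))
  res <- data.frame(locus_a = character(0), locus_b = character(0),
                    score = numeric(0), identity = numeric(0),
                    coverage = numeric(0))
  if (length(rows)) {
    cols <- best_ab[rows]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pa[rows]), Biostrings::AAStringSet(pb[cols]),
      type = "global", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 1)
    identity <- Biostrings::pid(aln, type = "PID1") / 100
    coverage <- pmin(nchar(pa[rows]), nchar(pb[cols])) /
      pmax(nchar(pa[rows]), nchar(pb[cols]))
    keep <- identity >= min_identity & coverage >= min_coverage
    res <- data.frame(locus_a = la[rows][keep], locus_b = lb[cols][keep],
                      score = sm[cbind(rows, cols)][keep],
                      identity = identity[keep], coverage = coverage[keep],
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
  }
  structure(res, class = c("ortholog_map", "data.frame"),
            genome_a = genome_a$genome_id, genome_b = genome_b$genome_id)
}

#' All pairwise BBH maps for a set of genomes
#' @param genomes Named list of [annotated_genome()].
#' @param ... Passed to [bbh_orthologs()].
#' @return List of `ortholog_map`, named "<a>|<b>".
#' @export
bbh_all_pairs <- function(genomes, ...) {
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  maps <- list()
  n <- length(genomes)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    maps[[paste(ids[i], ids[j], sep = "|")]] <-
      bbh_orthologs(genomes[[i]], genomes[[j]], ...)
  }
  maps
}

# orthologs of `locus` (in genome `from`) in genome `to`, over a map list
.orthologs_of <- function(maps, from, to, locus) {
  key1 <- paste(from, to, sep = "|"); key2 <- paste(to, from, sep = "|")
  if (!is.null(maps[[key1]])) {
    m <- maps[[key1]]
    m$locus_b[m$locus_a %in% locus]
  } else if (!is.null(maps[[key2]])) {
    m <- maps[[key2]]
    m$locus_a[m$locus_b %in% locus]
  } else {
    stop("no ortholog map for genome pair ", from, " / ", to, call. = FALSE)
  }
}

#' Predict operons as same-strand runs with bounded intergenic gaps
#'
#' Maximal runs of adjacent same-strand genes on one replicon whose
#' intergenic gaps are at most `max_gap` bp. The lead gene is the 5'-most
#' in transcription order (highest-coordinate gene for minus-strand
#' operons). Every gene belongs to exactly one operon.
#'
#' @param genome An [annotated_genome()].
#' @param max_gap Maximum intergenic gap in bp (default 150).
#' @return data.frame with columns `locus_tag`, `operon_id`, `lead`
#'   (logical), `strand`; operon ids are "<replicon>:<k>".
#' @export
predict_operons <- function(genome, max_gap = 150L) {
  g <- genome$genes   # already sorted by replicon, cds_start
  if (!nrow(g))
    return(data.frame(locus_tag = character(0), operon_id = character(0),
                      lead = logical(0), strand = character(0)))
  new_block <- c(TRUE, g$replicon[-1] != g$replicon[-nrow(g)] |
                   g$strand[-1] != g$strand[-nrow(g)] |
                   (g$cds_start[-1] - g$cds_end[-nrow(g)]) > max_gap)
  op <- cumsum(new_block)
  out <- data.frame(locus_tag = g$locus_tag,
                    operon_id = paste0(g$replicon, ":", op),
                    lead = FALSE, strand = g$strand,
                    stringsAsFactors = FALSE)
  for (id in unique(out$operon_id)) {
    idx <- which(out$operon_id == id)
    lead_idx <- if (g$strand[idx[1]] == "+") idx[1] else idx[length(idx)]
    out$lead[lead_idx] <- TRUE
  }
  out
}

.tu_lookup <- function(operons) {
  stats::setNames(operons$operon_id, operons$locus_tag)
}

.tu_members <- function(operons) split(operons$locus_tag, operons$operon_id)

#' Cross-genome consistency filter (phylogenetic footprinting)
#'
#' A candidate site upstream of gene x in genome g is retained iff in at
#' least `min_support` other genomes an ortholog of x — or of any gene in
#' x's operon — also carries an above-threshold hit in its window. Support
#' is counted at the transcription-unit level, and all sites upstream of
#' one transcription unit share one fate.
#'
#' @param site_tables Named list (by genome id) of site tables from
#'   [scan_genome()].
#' @param maps List of `ortholog_map` covering every genome pair (from
#'   [bbh_all_pairs()]).
#' @param operons Named list (by genome id) of [predict_operons()] outputs.
#' @param min_support Minimum number of supporting other genomes
#'   (default 2).
#' @return Named list of filtered site tables, with a `support` attribute
#'   (data.frame: genome_id, operon_id, support, retained).
#' @export
consistency_filter <- function(site_tables, maps, operons, min_support = 2L) {
  ids <- names(site_tables)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("site_tables must be named by genome id", call. = FALSE)
  tu_of <- lapply(operons[ids], .tu_lookup)
  members <- lapply(operons[ids], .tu_members)
  # transcription units carrying at least one hit, per genome
  hit_tus <- lapply(ids, function(g) {
    st <- site_tables[[g]]
    unique(unname(tu_of[[g]][st$locus_tag]))
  })
  names(hit_tus) <- ids
  hit_loci <- lapply(ids, function(g) {
    unique(unlist(members[[g]][hit_tus[[g]]], use.names = FALSE))
  })
  names(hit_loci) <- ids

  support_rows <- list()
  filtered <- site_tables
  for (g in ids) {
    st <- site_tables[[g]]
    if (!nrow(st)) next
    st_tu <- unname(tu_of[[g]][st$locus_tag])
    keep <- logical(nrow(st))
    for (tu in unique(st_tu)) {
      tu_genes <- members[[g]][[tu]]
      supp <- 0L
      for (h in setdiff(ids, g)) {
        orth <- .orthologs_of(maps, g, h, tu_genes)
        if (length(orth) && any(orth %in% hit_loci[[h]])) supp <- supp + 1L
      }
      retained <- supp >= min_support
      keep[st_tu == tu] <- retained
      support_rows[[length(support_rows) + 1L]] <- data.frame(
        genome_id = g, operon_id = tu, support = supp, retained = retained,
        stringsAsFactors = FALSE)
    }
    filtered[[g]] <- st[keep, , drop = FALSE]
    rownames(filtered[[g]]) <- NULL
  }
  attr(filtered, "support") <- if (length(support_rows))
    do.call(rbind, support_rows) else NULL
  filtered
}

#' Assemble a regulon for one genome
#'
#' Hits upstream of interior operon genes are reassigned to the operon
#' lead; member genes are the union of genes of every operon whose lead
#' carries at least one retained operator; operators are distinct absolute
#' intervals.
#'
#' @param sites Filtered site table for the genome.
#' @param operons [predict_operons()] output for the genome.
#' @param genome The [annotated_genome()].
#' @param tf_name Transcription factor name (label only).
#' @param tf_locus Optional locus tag of the TF gene itself, to report the
#'   member count with and without the autoregulated TF.
#' @return Object of class `regulon`: list with `genome_id`, `tf_name`,
#'   `operators` (data.frame), `operon_ids`, `genes`, `n_operators`,
#'   `n_genes`, `n_genes_excl_tf`.
#' @export
assemble_regulon <- function(sites, operons, genome, tf_name = "TF",
                             tf_locus = NULL) {
  tu_of <- .tu_lookup(operons)
  members <- .tu_members(operons)
  if (nrow(sites)) {
    tus <- unique(unname(tu_of[sites$locus_tag]))
    genes <- unique(unlist(members[tus], use.names = FALSE))
    ops <- unique(sites[, c("replicon", "abs_start", "abs_end")])
    # keep one representative row (max score) per distinct interval
    key <- paste(sites$replicon, sites$abs_start, sites$abs_end)
    rep_rows <- vapply(split(seq_len(nrow(sites)), key), function(i)
      i[which.max(sites$score[i])], integer(1))
    operators <- sites[sort(rep_rows), , drop = FALSE]
    rownames(operators) <- NULL
  } else {
    tus <- character(0); genes <- character(0)
    operators <- sites
  }
  n_genes <- length(genes)
  structure(list(
    genome_id = genome$genome_id, tf_name = tf_name,
    operators = operators, operon_ids = tus, genes = genes,
    n_operators = if (nrow(sites)) nrow(unique(
      sites[, c("replicon", "abs_start", "abs_end")])) else 0L,
    n_genes = n_genes,
    n_genes_excl_tf = n_genes - sum(genes %in% tf_locus)),
    class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s in %s: %d operator(s), %d gene(s) in %d TU(s)\n",
              x$tf_name, x$genome_id, x$n_operators, x$n_genes,
              length(x$operon_ids)))
  invisible(x)
}

#' Operator-anchored footprint alignment of orthologous upstream regions
#'
#' Ungapped alignment anchored at each region's operator start; reports the
#' aligned block, which columns are operator columns, and per-column
#' conservation (frequency of the commonest base among covered rows).
#' Regions without a site are listed as unanchored.
#'
#' @param regions Named list of `upstream_region` (names = genome ids or
#'   any row labels).
#' @param sites Named list (same names) of single-row site tables giving
#'   each region's operator; entries may be missing/empty.
#' @param motif_length Operator length (bp).
#' @return Object of class `footprint_alignment`: list with `block` (named
#'   character vector, "-"-padded), `operator_cols` (integer range),
#'   `conservation` (numeric per column), `unanchored` (names).
#' @export
footprint_alignment <- function(regions, sites, motif_length = 21L) {
  nm <- names(regions)
  anchored <- nm[vapply(nm, function(k)
    !is.null(sites[[k]]) && nrow(sites[[k]]) >= 1L, logical(1))]
  unanchored <- setdiff(nm, anchored)
  if (length(anchored) < 2L)
    stop("need at least 2 anchored regions", call. = FALSE)
  offs <- vapply(anchored, function(k) {
    r <- regions[[k]]; s <- sites[[k]][1, , drop = FALSE]
    .rel_to_lin(s$rel_start) - .rel_to_lin(r$rel_start)
  }, numeric(1))
  lens <- vapply(anchored, function(k) nchar(regions[[k]]$sequence),
                 numeric(1))
  left <- max(offs)
  right <- max(lens - offs)
  width <- left + right
  block <- vapply(anchored, function(k) {
    pre <- strrep("-", left - offs[[k]])
    post <- strrep("-", width - (left - offs[[k]]) - lens[[k]])
    paste0(pre, regions[[k]]$sequence, post)
  }, character(1))
  chars <- do.call(rbind, strsplit(block, ""))
  conservation <- apply(chars, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_real_)
    max(table(col)) / length(col)
  })
  structure(list(block = block,
                 operator_cols = seq(left + 1L, left + motif_length),
                 conservation = conservation,
                 unanchored = unanchored),
            class = "footprint_alignment")
}

#' @export
print.footprint_alignment <- function(x, ...) {
  marker <- rep(" ", length(x$conservation))
  marker[x$operator_cols] <- "*"
  cat(paste0(strrep(" ", max(nchar(names(x$block))) + 2),
             paste(marker, collapse = "")), "\n")
  for (nm in names(x$block))
    cat(sprintf("%-*s  %s\n", max(nchar(names(x$block))), nm, x$block[[nm]]))
  if (length(x$unanchored))
    cat("unanchored:", paste(x$unanchored, collapse = ", "), "\n")
  invisible(x)
}

#' Rebuild weight matrices per phylogenetic clade
#'
#' Pools the retained sites of each clade's genomes and reruns
#' [build_pwm()]; clades with fewer than 2 retained sites fall back to the
#' global matrix (with a message). Clades come from an explicit list of
#' genome-id groups or from the immediate subtrees of the root of a newick
#' tree whose tips are genome ids.
#'
#' @param clades Named list of character vectors of genome ids, or an
#'   `ape::phylo` tree, or a path to a newick file.
#' @param initial_pwm The global `weight_matrix` (fallback; supplies
#'   palindromy and pseudocount).
#' @param site_tables Named list of retained site tables per genome.
#' @return Named list of `weight_matrix` per clade plus `$global`.
#' @export
refine_pwm_per_clade <- function(clades, initial_pwm, site_tables) {
  if (is.character(clades) && length(clades) == 1L && file.exists(clades))
    clades <- ape::read.tree(clades)
  if (inherits(clades, "phylo"))
    clades <- clade_groups(clades)
  all_sites <- unlist(lapply(site_tables, function(s) s$sequence),
                      use.names = FALSE)
  global <- if (length(all_sites) >= 2L)
    build_pwm(all_sites, palindromic = initial_pwm$palindromic,
              pseudocount = initial_pwm$pseudocount) else initial_pwm
  out <- list(global = global)
  for (nm in names(clades)) {
    sites <- unlist(lapply(site_tables[clades[[nm]]],
                           function(s) if (is.null(s)) character(0) else
                             s$sequence), use.names = FALSE)
    if (length(sites) < 2L) {
      message("clade ", nm, ": <2 retained sites, falling back to global PWM")
      out[[nm]] <- global
    } else {
      out[[nm]] <- build_pwm(sites, palindromic = initial_pwm$palindromic,
                             pseudocount = initial_pwm$pseudocount)
    }
  }
  out
}

#' Split a tree's tips into clades at the root
#' @param tree An `ape::phylo` object; tip labels are genome ids.
#' @return Named list of tip-label groups, one per child of the root.
#' @export
clade_groups <- function(tree) {
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  groups <- lapply(kids, function(k) {
    if (k <= length(tree$tip.label)) tree$tip.label[k]
    else ape::extract.clade(tree, k)$tip.label
  })
  names(groups) <- paste0("clade", seq_along(groups))
  groups
}
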