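# End-to-end orchestration: build/calibrate PWM -> scan genomes -> BBH maps
# -> consistency filter -> operons -> regulon -> promoter overlap ->
# footprints -> per-clade refinement -> reports.

#' Pipeline configuration
#'
#' @param genomes Named list of [annotated_genome()] objects, or a character
#'   vector of genome file paths (GenBank, or FASTA with a sibling GFF3).
#' @param pwm A `weight_matrix` or a path readable by [read_pwm()]; NULL to
#'   build one from `training_sites`.
#' @param training_sites Character vector of sites, a [site_alignment()], or
#'   a path for [read_sites()].
#' @param palindromic Symmetrize the trained matrix (default TRUE, the
#'   operator-dimer case).
#' @param threshold_rule,threshold_value,allowance Passed to
#'   [calibrate_threshold()].
#' @param window,both_strands,dedup_radius Passed to [scan_config()].
#' @param min_support Consistency-filter support (default 2).
#' @param operon_max_gap Operon gap rule in bp (default 150).
#' @param tree Newick path/string or explicit clade list for per-clade PWM
#'   refinement; NULL skips refinement.
#' @param tf_name,tf_locus TF label and (optional) its locus tag(s).
#' @param call_promoters Classify operator-promoter overlaps (default TRUE).
#' @param out_dir Output directory; NULL keeps results in memory only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genomes, pwm = NULL, training_sites = NULL,
                            palindromic = TRUE,
                            threshold_rule = "min_training_site",
                            threshold_value = NULL, allowance = 0,
                            window = c(-500L, 50L), both_strands = TRUE,
                            dedup_radius = 2L, min_support = 2L,
                            operon_max_gap = 150L, tree = NULL,
                            tf_name = "TF", tf_locus = NULL,
                            call_promoters = TRUE, out_dir = NULL) {
  if (is.null(pwm) && is.null(training_sites))
    stop("provide a PWM or training sites", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

# no timestamps: rerunning on identical inputs must give identical reports
.log_line <- function(log, ...) {
  msg <- sprintf(...)
  message(msg)
  c(log, msg)
}

#' Run the full regulon-reconstruction pipeline
#'
#' Executes every stage of the comparative reconstruction on the configured
#' genomes and (optionally) writes a report bundle: per-genome site tables,
#' a regulon JSON + TSV, a promoter-overlap TSV, operator-anchored
#' footprint text, logo data, the calibrated PWM and a manifest. With a
#' single genome the consistency filter cannot run; the regulon is then
#' returned unfiltered and flagged `"unsupported"` (with a warning).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `pwm`, `sites` (raw), `filtered`, `operons`,
#'   `maps`, `regulons` (one per genome), `overlaps`, `footprints`,
#'   `clade_pwms`, `support_status`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)

  genomes <- config$genomes
  if (is.character(genomes)) {
    paths <- genomes
    genomes <- lapply(paths, read_genome)
    names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  }
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  ids <- names(genomes)
  log <- .log_line(log, "stage genomes: %d genome(s): %s", length(ids),
                   paste(ids, collapse = ", "))

  # --- PWM --------------------------------------------------------------
  pwm <- config$pwm
  if (is.character(pwm)) pwm <- read_pwm(pwm)
  if (is.null(pwm)) {
    sites <- config$training_sites
    if (is.character(sites) && length(sites) == 1L && file.exists(sites))
      sites <- read_sites(sites)
    pwm <- build_pwm(sites, palindromic = config$palindromic)
  }
  thr <- calibrate_threshold(pwm, rule = config$threshold_rule,
                             value = config$threshold_value,
                             allowance = config$allowance)
  pwm <- set_threshold(pwm, thr)
  log <- .log_line(log,
                   "stage pwm: L=%d, rule=%s, allowance=%g, threshold=%.3f",
                   pwm$length, config$threshold_rule, config$allowance, thr)

  # --- scan -------------------------------------------------------------
  sc <- scan_config(window = config$window, threshold = thr,
                    both_strands = config$both_strands,
                    dedup_radius = config$dedup_radius)
  site_tables <- lapply(genomes, scan_genome, pwm = pwm, config = sc)
  log <- .log_line(log, "stage scan: %s hit rows",
                   paste(vapply(site_tables, nrow, integer(1)),
                         collapse = "/"))

  # --- operons ----------------------------------------------------------
  operons <- lapply(genomes, predict_operons, max_gap = config$operon_max_gap)

  # --- consistency filter -----------------------------------------------
  if (length(genomes) >= 2L) {
    maps <- bbh_all_pairs(genomes)
    filtered <- consistency_filter(site_tables, maps, operons,
                                   min_support = config$min_support)
    support_status <- "filtered"
    log <- .log_line(log, "stage filter: min_support=%d, %s rows retained",
                     config$min_support,
                     paste(vapply(filtered, nrow, integer(1)),
                           collapse = "/"))
  } else {
    warning("single genome: consistency filter skipped; regulon is ",
            "unsupported", call. = FALSE)
    maps <- list()
    filtered <- site_tables
    support_status <- "unsupported"
    log <- .log_line(log, "stage filter: skipped (single genome)")
  }

  # --- regulon assembly -------------------------------------------------
  regulons <- lapply(ids, function(g)
    assemble_regulon(filtered[[g]], operons[[g]], genomes[[g]],
                     tf_name = config$tf_name, tf_locus = config$tf_locus))
  names(regulons) <- ids
  log <- .log_line(log, "stage regulon: %s",
                   paste(sprintf("%s: %d op/%d genes", ids,
                                 vapply(regulons, `[[`, integer(1),
                                        "n_operators"),
                                 vapply(regulons, `[[`, integer(1),
                                        "n_genes")), collapse = "; "))

  # --- promoter overlap -------------------------------------------------
  overlaps <- NULL
  if (isTRUE(config$call_promoters)) {
    pp <- train_promoter_pwms()
    rows <- list()
    for (g in ids) {
      st <- filtered[[g]]
      if (!nrow(st)) next
      for (i in seq_len(nrow(st))) {
        region <- extract_upstream(genomes[[g]], st$locus_tag[i],
                                   config$window)
        calls <- call_promoters(region, pp$pwm35, pp$pwm10)
        if (!nrow(calls)) next
        oc <- classify_overlap(st[i, ], calls[1, ],
                               motif_length = pwm$length)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = g, locus_tag = st$locus_tag[i],
          op_start = st$rel_start[i],
          op_end = .lin_to_rel(.rel_to_lin(st$rel_start[i]) + pwm$length - 1L),
          element = oc$element, overlap_bp = oc$overlap_bp,
          architecture = oc$architecture, stringsAsFactors = FALSE)
      }
    }
    overlaps <- if (length(rows)) do.call(rbind, rows) else NULL
    log <- .log_line(log, "stage promoters: %d overlap call(s)",
                     if (is.null(overlaps)) 0L else nrow(overlaps))
  }

  # --- footprints: one block per gene family with >=2 anchored sites ----
  footprints <- list()
  if (length(genomes) >= 2L && nrow(filtered[[ids[1]]])) {
    ref <- ids[1]
    for (lt in unique(filtered[[ref]]$locus_tag)) {
      regions <- list(); fam_sites <- list()
      regions[[ref]] <- extract_upstream(genomes[[ref]], lt, config$window)
      fam_sites[[ref]] <- filtered[[ref]][filtered[[ref]]$locus_tag == lt, ]
      for (h in ids[-1]) {
        orth <- .orthologs_of(maps, ref, h, lt)
        if (!length(orth)) next
        regions[[h]] <- extract_upstream(genomes[[h]], orth[1],
                                         config$window)
        fam_sites[[h]] <- filtered[[h]][filtered[[h]]$locus_tag == orth[1], ]
      }
      n_anch <- sum(vapply(fam_sites, nrow, integer(1)) > 0)
      if (n_anch >= 2L)
        footprints[[lt]] <- footprint_alignment(regions, fam_sites,
                                                motif_length = pwm$length)
    }
    log <- .log_line(log, "stage footprint: %d family block(s)",
                     length(footprints))
  }

  # --- per-clade refinement ---------------------------------------------
  clade_pwms <- NULL
  if (!is.null(config$tree)) {
    clade_pwms <- refine_pwm_per_clade(config$tree, pwm, filtered)
    log <- .log_line(log, "stage refine: %d clade matrix(es)",
                     length(clade_pwms) - 1L)
  }

  result <- list(pwm = pwm, sites = site_tables, filtered = filtered,
                 operons = operons, maps = maps, regulons = regulons,
                 overlaps = overlaps, footprints = footprints,
                 clade_pwms = clade_pwms, support_status = support_status,
                 log = log)

  if (!is.null(config$out_dir)) .write_reports(result, genomes, config)
  invisible(result)
}

.write_reports <- function(result, genomes, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- character(0)
  p <- function(...) file.path(config$out_dir, ...)
  for (g in names(genomes)) {
    write_sites(result$sites[[g]], p(sprintf("sites_%s.tsv", g)))
    outs <- c(outs, sprintf("sites_%s.tsv", g))
  }
  reg_json <- lapply(result$regulons, function(r) list(
    genome_id = r$genome_id, tf_name = r$tf_name,
    n_operators = r$n_operators, n_genes = r$n_genes,
    n_genes_excl_tf = r$n_genes_excl_tf,
    support_status = result$support_status,
    operators = r$operators, operons = r$operon_ids, genes = r$genes))
  jsonlite::write_json(reg_json, p("regulon.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  reg_tsv <- do.call(rbind, lapply(result$regulons, function(r)
    if (length(r$genes)) data.frame(genome_id = r$genome_id,
                                    locus_tag = r$genes,
                                    stringsAsFactors = FALSE) else NULL))
  utils::write.table(reg_tsv, p("regulon.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(result$overlaps))
    utils::write.table(result$overlaps, p("promoter_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(result$footprints)) {
    con <- file(p("footprint.txt"), "w")
    for (nm in names(result$footprints)) {
      writeLines(paste0(">", nm), con)
      fp <- result$footprints[[nm]]
      writeLines(sprintf("%-12s %s", names(fp$block), fp$block), con)
      writeLines(sprintf("operator columns %d..%d; mean conservation %.3f",
                         min(fp$operator_cols), max(fp$operator_cols),
                         mean(fp$conservation[fp$operator_cols],
                              na.rm = TRUE)), con)
    }
    close(con)
    outs <- c(outs, "footprint.txt")
  }
  utils::write.table(logo_data(result$pwm), p("logo.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_pwm(result$pwm, p("pwm.tsv"))
  outs <- c(outs, "regulon.json", "regulon.tsv", "logo.tsv", "pwm.tsv")
  writeLines(result$log, p("run.log"))
  jsonlite::write_json(
    list(outputs = sort(unique(outs)),
         parameters = list(
           threshold = result$pwm$threshold, window = config$window,
           min_support = config$min_support,
           operon_max_gap = config$operon_max_gap,
           genomes = names(genomes))),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
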