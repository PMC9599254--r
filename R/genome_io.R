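# Genome and annotation I/O with explicit coordinate conventions.
#
# Internal coordinates are 0-based half-open throughout.  Gene-relative
# coordinates follow the convention used for bacterial promoter windows:
# +1 is the first base of the start codon, -1 abuts it upstream, there is
# no position 0 (see utils.R for the linearization helpers).

#' Construct an annotated genome
#'
#' Bundles replicon sequences with gene models. Coordinates are 0-based
#' half-open; strand is "+" or "-".
#'
#' @param genome_id Single string identifying the genome.
#' @param replicons Named character vector of replicon sequences (ACGTN).
#' @param genes A data.frame with columns `locus_tag`, `replicon`, `strand`,
#'   `cds_start`, `cds_end` and optionally `protein` (amino-acid string,
#'   may be empty).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, replicons, genes) {
  .stopifnot_scalar_chr(genome_id, "genome_id")
  if (is.null(names(replicons)) || any(names(replicons) == ""))
    stop("replicons must be a named character vector", call. = FALSE)
  replicons <- vapply(replicons, toupper, character(1))
  .assert_dna(unname(replicons), allow_n = TRUE, what = "replicon sequence")
  need <- c("locus_tag", "replicon", "strand", "cds_start", "cds_end")
  if (!all(need %in% names(genes)))
    stop("genes must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(genes$protein)) genes$protein <- ""
  genes <- genes[, c(need, "protein")]
  genes$cds_start <- as.integer(genes$cds_start)
  genes$cds_end <- as.integer(genes$cds_end)
  if (anyDuplicated(genes$locus_tag))
    stop("duplicate locus_tag in genome ", genome_id, call. = FALSE)
  if (any(genes$cds_start >= genes$cds_end))
    stop("cds_start must be < cds_end (0-based half-open)", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (!all(genes$replicon %in% names(replicons)))
    stop("gene replicon not present in replicons", call. = FALSE)
  rl <- nchar(replicons)[genes$replicon]
  if (any(genes$cds_start < 0L) || any(genes$cds_end > rl))
    stop("gene interval outside replicon bounds", call. = FALSE)
  genes <- genes[order(genes$replicon, genes$cds_start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, replicons = replicons, genes = genes),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d replicon(s), %d gene(s), %s bp\n",
              x$genome_id, length(x$replicons), nrow(x$genes),
              format(sum(nchar(x$replicons)), big.mark = ",")))
  invisible(x)
}

.gene_row <- function(genome, locus_tag) {
  i <- match(locus_tag, genome$genes$locus_tag)
  if (is.na(i)) stop("unknown locus tag: ", locus_tag, call. = FALSE)
  genome$genes[i, , drop = FALSE]
}

# ---- GenBank flat-file reader (minimal: CDS features, locus_tag,
# translation, single or multiple records) -------------------------------

.parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|complement", loc)) return(NULL)  # compound: skip
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) != 3L) return(NULL)
  # GenBank is 1-based closed; convert to 0-based half-open
  list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]), strand = strand)
}

.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  rec_starts <- grep("^LOCUS", lines)
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  replicons <- character(0)
  genes <- list()
  for (r in seq_along(rec_starts)) {
    block <- lines[rec_starts[r]:rec_ends[r]]
    rep_id <- strsplit(trimws(sub("^LOCUS\\s+", "", block[1])), "\\s+")[[1]][1]
    ori <- grep("^ORIGIN", block)
    if (!length(ori))
      stop(sprintf("GenBank record %s (line %d): no ORIGIN section",
                   rep_id, rec_starts[r]), call. = FALSE)
    seq_lines <- block[(ori + 1):length(block)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    .assert_dna(seq, what = sprintf("record %s ORIGIN", rep_id))
    replicons[rep_id] <- seq

    feat0 <- grep("^FEATURES", block)
    if (!length(feat0)) next
    fblock <- block[(feat0 + 1):(ori - 1)]
    # feature lines start at col 6; qualifier/continuation lines at col 22
    key_idx <- grep("^\\s{5}\\S", fblock)
    if (!length(key_idx)) next
    key_end <- c(key_idx[-1] - 1L, length(fblock))
    for (k in seq_along(key_idx)) {
      fl <- fblock[key_idx[k]:key_end[k]]
      parts <- strsplit(trimws(fl[1]), "\\s+")[[1]]
      if (parts[1] != "CDS") next
      qual_start <- grep("^\\s+/", fl)
      loc_lines <- if (length(qual_start)) fl[1:(qual_start[1] - 1)] else fl
      loc_txt <- paste(c(parts[-1], trimws(loc_lines[-1])), collapse = "")
      loc <- .parse_gb_location(loc_txt)
      if (is.null(loc)) {
        warning(sprintf("record %s: skipping CDS with unsupported location '%s'",
                        rep_id, loc_txt), call. = FALSE)
        next
      }
      # collapse qualifiers (they may wrap across lines)
      qtxt <- paste(trimws(fl[-1]), collapse = "\n")
      get_qual <- function(name) {
        m <- regmatches(qtxt, regexec(sprintf('/%s="([^"]*)"', name), qtxt))[[1]]
        if (length(m) == 2L) gsub("\\s", "", m[2]) else NA_character_
      }
      lt <- get_qual("locus_tag")
      if (is.na(lt)) {
        warning(sprintf("record %s: skipping CDS at %s without locus_tag",
                        rep_id, loc_txt), call. = FALSE)
        next
      }
      prot <- get_qual("translation")
      genes[[length(genes) + 1L]] <- data.frame(
        locus_tag = lt, replicon = rep_id, strand = loc$strand,
        cds_start = loc$start, cds_end = loc$end,
        protein = if (is.na(prot)) "" else prot,
        stringsAsFactors = FALSE)
    }
  }
  list(replicons = replicons,
       genes = if (length(genes)) do.call(rbind, genes) else
         data.frame(locus_tag = character(0), replicon = character(0),
                    strand = character(0), cds_start = integer(0),
                    cds_end = integer(0), protein = character(0)))
}

# translate coding-strand CDS sequences in one batch; "" where untranslatable
.translate_batch <- function(cds) {
  out <- character(length(cds))
  ok <- nchar(cds) >= 3L & nchar(cds) %% 3L == 0L & !grepl("N", cds)
  if (any(ok)) {
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds[ok]), if.fuzzy.codon = "X"))
    out[ok] <- sub("\\*$", "", prot)
  }
  out
}

# translate a CDS (genomic coordinates, strand-aware); returns "" on failure
.translate_cds <- function(replicon_seq, start, end, strand) {
  s <- substr(replicon_seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  .translate_batch(s)
}

#' Read an annotated genome
#'
#' Reads either a GenBank flat file or a FASTA + GFF3 pair. All CDS features
#' carrying a `locus_tag` become gene models; input coordinates (1-based
#' closed in both formats) are converted to 0-based half-open. Proteins come
#' from the GenBank `/translation` qualifier when present, otherwise from
#' translating the CDS.
#'
#' @param path Path to the GenBank file, or to the FASTA file when
#'   `format = "fasta+gff3"`.
#' @param format One of `"auto"`, `"genbank"`, `"fasta+gff3"`.
#' @param gff Path to the GFF3 file; defaults to `path` with a `.gff3`/`.gff`
#'   extension.
#' @param genome_id Genome identifier; defaults to the file base name.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(path, format = c("auto", "genbank", "fasta+gff3"),
                        gff = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta+gff3"
  }
  if (is.null(genome_id))
    genome_id <- tools::file_path_sans_ext(basename(path))
  if (format == "genbank") {
    gb <- .read_genbank(path)
    replicons <- gb$replicons
    genes <- gb$genes
  } else {
    if (is.null(gff)) {
      cand <- c(paste0(tools::file_path_sans_ext(path), ".gff3"),
                paste0(tools::file_path_sans_ext(path), ".gff"))
      gff <- cand[file.exists(cand)][1]
      if (is.na(gff)) stop("no GFF3 file found next to ", path, call. = FALSE)
    }
    dss <- Biostrings::readDNAStringSet(path)
    names(dss) <- sub("\\s.*$", "", names(dss))
    replicons <- as.character(dss)
    gr <- rtracklayer::import(gff, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    lt <- gr$locus_tag
    if (is.null(lt)) lt <- rep(NA_character_, length(gr))
    drop <- is.na(lt)
    if (any(drop)) {
      warning(sum(drop), " CDS feature(s) without locus_tag skipped",
              call. = FALSE)
      gr <- gr[!drop]; lt <- lt[!drop]
    }
    genes <- data.frame(
      locus_tag = lt,
      replicon = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      cds_start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based
      cds_end = GenomicRanges::end(gr),
      protein = "", stringsAsFactors = FALSE)
  }
  need_prot <- !nzchar(genes$protein)
  if (any(need_prot) && nrow(genes)) {
    cds <- vapply(which(need_prot), function(i) {
      s <- substr(replicons[[genes$replicon[i]]], genes$cds_start[i] + 1L,
                  genes$cds_end[i])
      if (genes$strand[i] == "-") revcomp(s) else s
    }, character(1))
    genes$protein[need_prot] <- .translate_batch(cds)
  }
  annotated_genome(genome_id, replicons, genes)
}

#' Write an annotated genome as FASTA + GFF3
#'
#' @param genome An [annotated_genome()].
#' @param fasta,gff Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta, gff) {
  dss <- Biostrings::DNAStringSet(genome$replicons)
  Biostrings::writeXStringSet(dss, fasta)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$replicon,
    ranges = IRanges::IRanges(start = g$cds_start + 1L, end = g$cds_end),
    strand = g$strand)
  gr$type <- "CDS"
  gr$source <- "regrec"
  gr$locus_tag <- g$locus_tag
  gr$ID <- g$locus_tag
  gr$phase <- 0L
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

#' Extract a strand-normalized upstream region
#'
#' Returns the sequence covering a gene-relative window (default -500..+50;
#' +1 is the first base of the start codon, no position 0), oriented 5'->3'
#' on the gene's coding strand. The window is truncated only at replicon
#' edges, never by neighboring genes; truncation sets `clipped`.
#'
#' @param genome An [annotated_genome()].
#' @param locus_tag Gene identifier.
#' @param window Length-2 integer vector, gene-relative (no 0), e.g.
#'   `c(-500, 50)`.
#' @return An object of class `upstream_region`: list with `locus_tag`,
#'   `strand`, `replicon`, `rel_start`, `rel_end` (realized window),
#'   `abs_start`, `abs_end` (0-based half-open on the replicon), `sequence`,
#'   `clipped`.
#' @export
extract_upstream <- function(genome, locus_tag, window = c(-500L, 50L)) {
  if (length(window) != 2L || any(window == 0L) || window[1] >= window[2])
    stop("window must be two nonzero gene-relative positions, start < end",
         call. = FALSE)
  gene <- .gene_row(genome, locus_tag)
  rep_seq <- genome$replicons[[gene$replicon]]
  n <- nchar(rep_seq)
  a <- .rel_to_abs(window[1], gene$strand, gene$cds_start, gene$cds_end)
  b <- .rel_to_abs(window[2], gene$strand, gene$cds_start, gene$cds_end)
  if (gene$strand == "+") {
    abs_start <- a; abs_end <- b + 1L
  } else {
    abs_start <- b; abs_end <- a + 1L
  }
  clipped <- abs_start < 0L || abs_end > n
  abs_start_c <- max(abs_start, 0L)
  abs_end_c <- min(abs_end, n)
  if (abs_start_c >= abs_end_c)
    stop("window lies entirely outside replicon for ", locus_tag,
         call. = FALSE)
  seq <- substr(rep_seq, abs_start_c + 1L, abs_end_c)
  # realized gene-relative bounds after clipping
  lin1 <- .rel_to_lin(window[1])
  lin2 <- .rel_to_lin(window[2])
  if (gene$strand == "+") {
    lin1 <- lin1 + (abs_start_c - abs_start)
    lin2 <- lin2 - (abs_end - abs_end_c)
  } else {
    lin1 <- lin1 + (abs_end - abs_end_c)
    lin2 <- lin2 - (abs_start_c - abs_start)
    seq <- revcomp(seq)
  }
  structure(list(
    locus_tag = locus_tag, strand = gene$strand, replicon = gene$replicon,
    rel_start = .lin_to_rel(lin1), rel_end = .lin_to_rel(lin2),
    abs_start = abs_start_c, abs_end = abs_end_c,
    sequence = seq, clipped = clipped), class = "upstream_region")
}

#' @export
print.upstream_region <- function(x, ...) {
  cat(sprintf("<upstream_region> %s (%s) %d..%d (%d bp)%s\n",
              x$locus_tag, x$strand, x$rel_start, x$rel_end,
              nchar(x$sequence), if (x$clipped) " [clipped]" else ""))
  invisible(x)
}
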