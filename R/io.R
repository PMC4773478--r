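# File formats: BED6 (0-based half-open), bedGraph, FASTA, JASPAR PFM,
# GMT, and plain TSV tables. Genomic I/O goes through rtracklayer /
# Biostrings; everything is written deterministically so identical inputs
# give byte-identical files.

#' Write the gene annotation as BED6
#'
#' Each gene is written as a 1-bp TSS-anchored interval (0-based
#' half-open), name = gene id, with strand.
#'
#' @param bundle A `genome_bundle` (or its `genes` data.frame).
#' @param path Output path.
#' @export
write_genome_bed <- function(bundle, path) {
  genes <- if (inherits(bundle, "genome_bundle")) bundle$genes else bundle
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$tss, width = 1L),
    strand = genes$strand
  )
  names(gr) <- genes$gene_id
  S4Vectors::mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 annotation into a TSS table
#'
#' The TSS is the interval start for plus-strand genes and the interval end
#' for minus-strand genes (1-based coordinates after import).
#'
#' @param path BED file path.
#' @return Data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("annotation must have explicit strands")
  data.frame(
    gene_id = if (!is.null(gr$name)) gr$name else names(gr),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(strand == "+", GenomicRanges::start(gr),
                 GenomicRanges::end(gr)),
    strand = strand, stringsAsFactors = FALSE
  )
}

#' Write promoter sequences as FASTA (header = gene id)
#' @param bundle A `genome_bundle` or named character vector.
#' @param path Output path.
#' @export
write_promoters_fasta <- function(bundle, path) {
  prom <- if (inherits(bundle, "genome_bundle")) bundle$promoters else bundle
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(prom), path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a binned ChIP profile as a bedGraph coverage track
#'
#' Emits one interval per bin with the bin's tag count as the score, using
#' the annotation to place each gene's strand-corrected window back onto
#' genomic coordinates.
#'
#' @param profile A [chip_profile()] (bin values = tag counts).
#' @param annotation Annotation data.frame (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param path Output path.
#' @export
write_profile_bedgraph <- function(profile, annotation, path) {
  nb <- ncol(profile$mat)
  bs <- profile$bin_size
  wh <- profile$window_half
  rows <- match(annotation$gene_id, rownames(profile$mat))
  chrom <- rep(annotation$chrom, each = nb)
  gbin <- rep(seq_len(nb), times = nrow(annotation))
  tss0 <- rep(annotation$tss - 1L, each = nb)
  start0 <- tss0 - wh + (gbin - 1L) * bs
  minus <- rep(annotation$strand == "-", each = nb)
  matbin <- ifelse(minus, nb + 1L - gbin, gbin)
  score <- profile$mat[cbind(rep(rows, each = nb), matbin)]
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L,
                                                width = bs),
                               score = as.numeric(score))
  gr <- GenomicRanges::sort(gr)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write / read a count matrix with its group sidecar
#' @param cm A [count_matrix()].
#' @param counts_path,groups_path Output paths (TSV).
#' @export
write_counts_tsv <- function(cm, counts_path, groups_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(cm$counts), group = cm$groups),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_path, groups_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  g <- utils::read.delim(groups_path)
  count_matrix(m, stats::setNames(as.character(g$group), g$sample))
}

#' Write / read a survival table (TSV)
#' @param tbl A `survival_table`.
#' @param path TSV path.
#' @export
write_survival_tsv <- function(tbl, path) {
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  survival_table(utils::read.delim(path))
}

#' Read gene sets in GMT format
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a plain gene list (one id per line)
#' @param path File path.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes Character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read an expression compendium (genes x profiles TSV)
#' @param path TSV with a gene id first column.
#' @return Numeric matrix.
#' @export
read_compendium_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a full synthetic input bundle to disk
#'
#' Writes the annotation BED, promoter FASTA, PWM collection, TF-to-gene
#' map, count matrix with group sidecar, per-sample and control coverage
#' bedGraphs, and a plain-text key:value echo of the design.
#'
#' @param bundle A `regulator_bundle` from [plant_master_regulator()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    annotation = file.path(dir, "annotation.bed"),
    promoters = file.path(dir, "promoters.fa"),
    pwms = file.path(dir, "pwms.jaspar"),
    tf_map = file.path(dir, "tf_map.tsv"),
    counts = file.path(dir, "counts.tsv"),
    groups = file.path(dir, "groups.tsv"),
    design = file.path(dir, "design.txt")
  )
  write_genome_bed(bundle$genome, paths["annotation"])
  write_promoters_fasta(bundle$genome, paths["promoters"])
  write_jaspar(bundle$pwms, paths["pwms"])
  utils::write.table(bundle$tf_map, paths["tf_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_counts_tsv(bundle$counts, paths["counts"], paths["groups"])
  for (nm in names(bundle$chip$samples)) {
    p <- file.path(dir, sprintf("chip_%s.bedGraph", nm))
    write_profile_bedgraph(bundle$chip$samples[[nm]], bundle$genome$genes, p)
    paths[paste0("chip_", nm)] <- p
  }
  write_profile_bedgraph(bundle$chip$control, bundle$genome$genes,
                         file.path(dir, "chip_control.bedGraph"))
  paths["chip_control"] <- file.path(dir, "chip_control.bedGraph")
  d <- bundle$design
  scal <- vapply(d, function(v) length(v) == 1 && is.atomic(v), logical(1))
  writeLines(sprintf("%s: %s", names(d)[scal],
                     vapply(d[scal], as.character, character(1))),
             paths["design"])
  invisible(paths)
}
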