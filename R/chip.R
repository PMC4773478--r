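#' TSS-centred binned ChIP profile
#'
#' Container for per-gene binned tag densities over a window centred on the
#' TSS, strand-corrected so that negative bins are biologically upstream.
#'
#' @param mat Numeric genes x bins matrix of per-bin mean coverage
#'   (rownames = gene ids). `NA` marks bins trimmed at a chromosome edge.
#' @param window_half Half window in bp (default 3000).
#' @param bin_size Bin width in bp (default 100).
#' @param sample Sample label.
#' @param library_size Total signal of the originating track (for
#'   reads-per-million style normalization); defaults to the window total.
#' @return An object of class `chip_profile`.
#' @export
chip_profile <- function(mat, window_half = 3000, bin_size = 100,
                         sample = "sample", library_size = NULL) {
  mat <- as.matrix(mat)
  nb <- 2 * window_half / bin_size
  if (nb != round(nb)) stop("bin size must divide the window")
  if (ncol(mat) != nb) {
    stop("expected ", nb, " bins, got ", ncol(mat))
  }
  if (any(mat < 0, na.rm = TRUE)) stop("densities must be non-negative")
  if (is.null(library_size)) library_size <- sum(mat, na.rm = TRUE)
  structure(list(mat = mat, window_half = window_half, bin_size = bin_size,
                 sample = sample, library_size = library_size),
            class = "chip_profile")
}

#' @export
print.chip_profile <- function(x, ...) {
  cat(sprintf("chip_profile '%s': %d genes x %d bins (%d bp window, %d bp bins)\n",
              x$sample, nrow(x$mat), ncol(x$mat), 2 * x$window_half,
              x$bin_size))
  invisible(x)
}

# Bin centres relative to the TSS (negative = upstream).
bin_centers <- function(profile) {
  nb <- ncol(profile$mat)
  seq(-profile$window_half + profile$bin_size / 2, by = profile$bin_size,
      length.out = nb)
}

#' Reverse the bin order of a profile (upstream/downstream flip)
#'
#' Applying this twice restores the original profile.
#'
#' @param profile A [chip_profile()].
#' @return A [chip_profile()] with bins reversed.
#' @export
flip_profile <- function(profile) {
  out <- profile
  out$mat <- profile$mat[, rev(seq_len(ncol(profile$mat))), drop = FALSE]
  out
}

#' Binned TSS profile from a coverage track
#'
#' Bins coverage into a window of `2 * window_half` bp centred on each
#' gene's TSS. Minus-strand genes have their bin order reversed so that
#' negative bins are gene-upstream. Windows that run off the covered
#' coordinate space get `NA` in the trimmed bins.
#'
#' @param coverage A bedGraph file path or a `GRanges` with a `score`
#'   column.
#' @param annotation A BED6 file path, or a data.frame with columns
#'   `gene_id`, `chrom`, `tss` (1-based), `strand`.
#' @param window_half,bin_size Window geometry in bp.
#' @param sample Sample label recorded in the profile.
#' @return A [chip_profile()]; genes with trimmed bins are listed in the
#'   `trimmed` attribute of the matrix-carrying object.
#' @export
tss_profile <- function(coverage, annotation, window_half = 3000,
                        bin_size = 100, sample = "sample") {
  if ((2 * window_half) %% bin_size != 0) {
    stop("bin size must divide the window")
  }
  if (is.character(coverage)) {
    coverage <- rtracklayer::import(coverage, format = "bedGraph")
  }
  if (is.character(annotation)) annotation <- read_annotation_bed(annotation)
  nb <- as.integer(2 * window_half / bin_size)
  lib <- sum(GenomicRanges::score(coverage) *
               GenomicRanges::width(coverage))
  cov <- GenomicRanges::coverage(coverage,
                                 weight = GenomicRanges::score(coverage))
  mat <- matrix(NA_real_, nrow(annotation), nb,
                dimnames = list(annotation$gene_id, NULL))
  trimmed <- character(0)
  for (chr in unique(annotation$chrom)) {
    rows <- which(annotation$chrom == chr)
    if (!chr %in% names(cov)) { trimmed <- c(trimmed, annotation$gene_id[rows]); next }
    rle <- cov[[chr]]
    clen <- length(rle)
    for (i in rows) {
      tss <- annotation$tss[i]
      starts <- tss - window_half + bin_size * (seq_len(nb) - 1L)
      ends <- starts + bin_size - 1L
      ok <- starts >= 1L & ends <= clen
      if (any(!ok)) trimmed <- c(trimmed, annotation$gene_id[i])
      if (any(ok)) {
        v <- IRanges::Views(rle, start = starts[ok], end = ends[ok])
        mat[i, ok] <- IRanges::viewMeans(v)
      }
      if (annotation$strand[i] == "-") mat[i, ] <- rev(mat[i, ])
    }
  }
  pr <- chip_profile(mat, window_half = window_half, bin_size = bin_size,
                     sample = sample, library_size = lib)
  attr(pr, "trimmed") <- unique(trimmed)
  pr
}

#' Call H3K27me3 target genes against a control track
#'
#' One-sided Poisson enrichment test of the summed window signal per gene
#' against the control scaled by total library size, in its exact
#' conditional (binomial) form: given the combined window count, the signal
#' count is binomial with success probability given by the library-size
#' ratio. BH correction across genes; a gene is a target when `q < fdr`.
#'
#' @param signal,control [chip_profile()] objects over the same genes.
#' @param fdr Target false discovery rate.
#' @param mode `"window"` (default; whole-window sums, robust for broad
#'   marks) or `"bin"` (maximal single-bin test, Bonferroni over bins).
#' @return A data.frame (class `target_calls`): `gene_id`, `sample`,
#'   `score` (log2 enrichment over scaled control), `p`, `q`, `is_target`.
#' @export
call_targets <- function(signal, control, fdr = 0.05,
                         mode = c("window", "bin")) {
  mode <- match.arg(mode)
  stopifnot(inherits(signal, "chip_profile"), inherits(control, "chip_profile"))
  if (!identical(rownames(signal$mat), rownames(control$mat))) {
    stop("signal and control profiles cover different genes")
  }
  ts <- signal$library_size
  tc <- control$library_size
  if (tc <= 0 || sum(control$mat, na.rm = TRUE) == 0) {
    stop("control track has no signal")
  }
  pr_sig <- ts / (ts + tc)
  if (mode == "window") {
    x <- round(rowSums(signal$mat, na.rm = TRUE))
    cc <- round(rowSums(control$mat, na.rm = TRUE))
    p <- stats::pbinom(x - 1, x + cc, pr_sig, lower.tail = FALSE)
  } else {
    nb <- ncol(signal$mat)
    pb <- matrix(stats::pbinom(round(signal$mat) - 1,
                               round(signal$mat) + round(control$mat),
                               pr_sig, lower.tail = FALSE),
                 nrow(signal$mat), nb)
    p <- pmin(1, apply(pb, 1, min, na.rm = TRUE) * nb)
    x <- round(apply(signal$mat, 1, max, na.rm = TRUE))
    cc <- round(apply(control$mat, 1, max, na.rm = TRUE))
  }
  q <- bh_adjust(p)
  score <- log2(((x + 0.5) / ts) / ((cc + 0.5) / tc))
  res <- data.frame(gene_id = rownames(signal$mat), sample = signal$sample,
                    score = score, p = p, q = q, is_target = q < fdr,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("target_calls", "data.frame")
  res
}

#' De novo targets: marked in every tumour sample, in no origin sample
#'
#' Strict intersection-minus-union rule: a gene must be called a target in
#' every tumour sample and in none of the origin samples. Adding tumour
#' samples can therefore only shrink the result.
#'
#' @param origin_calls,tumour_calls Lists of [call_targets()] results (one
#'   per sample).
#' @return Sorted character vector of gene ids.
#' @export
de_novo_targets <- function(origin_calls, tumour_calls) {
  as_list <- function(x) {
    if (inherits(x, "data.frame")) list(x) else x
  }
  origin_calls <- as_list(origin_calls)
  tumour_calls <- as_list(tumour_calls)
  if (length(tumour_calls) < 1 || length(origin_calls) < 1) {
    stop("need at least one sample per side")
  }
  tum_sets <- lapply(tumour_calls, function(d) d$gene_id[d$is_target])
  ori_sets <- lapply(origin_calls, function(d) d$gene_id[d$is_target])
  inter <- Reduce(intersect, tum_sets)
  sort(setdiff(inter, Reduce(union, ori_sets)))
}

#' Classify the spatial H3K27me3 pattern around the TSS
#'
#' Computes mean density upstream (`U`, bins in `[-window, 0)`) and
#' downstream (`D`, bins in `(0, +window]`) of the TSS; if
#' `|log2(U/D)| >= lfc_threshold` the gene is `UP` or `DOWN` by the sign of
#' the ratio, otherwise `TSS` (flank enrichment on both sides of the
#' characteristic dip at the TSS itself). Trimmed (`NA`) bins are excluded
#' from the means.
#'
#' @param profile A [chip_profile()] (typically averaged tumour signal), or
#'   a numeric vector for a single gene.
#' @param genes Optional subset of gene ids to classify (e.g. called
#'   targets).
#' @param lfc_threshold Absolute log2 asymmetry needed for UP/DOWN.
#' @return Named character vector with values in `{TSS, UP, DOWN}`.
#' @export
classify_pattern <- function(profile, genes = NULL, lfc_threshold = 1) {
  if (is.numeric(profile) && is.null(dim(profile))) {
    nb <- length(profile)
    profile <- chip_profile(matrix(profile, 1, nb,
                                   dimnames = list("gene", NULL)),
                            window_half = nb * 50, bin_size = 100)
  }
  mat <- profile$mat
  if (!is.null(genes)) mat <- mat[intersect(genes, rownames(mat)), ,
                                  drop = FALSE]
  ctr <- bin_centers(profile)
  up <- ctr < 0
  u <- rowMeans(mat[, up, drop = FALSE], na.rm = TRUE)
  d <- rowMeans(mat[, !up, drop = FALSE], na.rm = TRUE)
  if (any(u == 0 & d == 0)) {
    stop("inconsistent call: zero signal on both flanks for gene(s) ",
         paste(utils::head(rownames(mat)[u == 0 & d == 0], 3),
               collapse = ", "))
  }
  lr <- log2(u / d)
  out <- ifelse(lr >= lfc_threshold, "UP",
                ifelse(lr <= -lfc_threshold, "DOWN", "TSS"))
  names(out) <- rownames(mat)
  out
}

#' Expression consequence of the spatial mark patterns
#'
#' Summarizes a per-gene expression statistic within each spatial class and
#' compares classes pairwise with the two-sided Mann-Whitney test
#' ([mw_test()]; exact with midrank ties for small classes, tie-corrected
#' normal approximation otherwise). Classes with fewer than 2 members are
#' excluded with a warning.
#'
#' @param classes Named character vector of pattern labels per gene.
#' @param expression Named numeric vector of per-gene expression (e.g.
#'   log2 fold change of the transition).
#' @return List with `summary` (per-class n, mean, median) and `pairwise`
#'   (class pair, U statistic, p).
#' @export
expression_by_pattern <- function(classes, expression) {
  common <- intersect(names(classes), names(expression))
  classes <- classes[common]; expression <- expression[common]
  tab <- table(classes)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("class(es) with < 2 members excluded: ",
            paste(small, collapse = ", "))
    keep <- !classes %in% small
    classes <- classes[keep]; expression <- expression[keep]
  }
  cls <- sort(unique(classes))
  if (length(cls) < 2) stop("need >= 2 non-empty classes")
  summ <- do.call(rbind, lapply(cls, function(cl) {
    v <- expression[classes == cl]
    data.frame(class = cl, n = length(v), mean = mean(v),
               median = stats::median(v), stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(cls, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    t <- mw_test(expression[classes == a], expression[classes == b])
    data.frame(class_a = a, class_b = b, U = t$statistic, p = t$p,
               method = t$method, stringsAsFactors = FALSE)
  }))
  list(summary = summ, pairwise = pw)
}
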