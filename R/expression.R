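#' Count matrix with sample group labels
#'
#' Container for a genes x samples matrix of raw (non-negative integer)
#' counts plus one group label per sample.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param groups Character vector of group labels, one per sample (named by
#'   sample id, or in column order).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(groups) != ncol(counts)) {
    stop("need one group label per sample")
  }
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(counts))) {
      stop("group names do not match sample ids")
    }
    groups <- groups[colnames(counts)]
  } else {
    names(groups) <- colnames(counts)
  }
  structure(list(counts = counts, groups = as.character(groups)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

subset_samples <- function(cm, keep) {
  count_matrix(cm$counts[, keep, drop = FALSE], cm$groups[keep])
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with non-zero
#' counts in every sample) of the ratio of the gene's count to its geometric
#' mean across samples.
#'
#' @param cm A [count_matrix()] (or bare matrix).
#' @param pseudocount Optional pseudocount added to all counts before
#'   estimation; the fallback when no gene is expressed in every sample.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(cm, pseudocount = 0) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  m <- m + pseudocount
  logm <- log(m)
  ok <- rowSums(is.finite(logm)) == ncol(m)
  if (!any(ok)) {
    stop("no gene has non-zero counts in all samples; ",
         "re-run with pseudocount > 0")
  }
  loggeo <- rowMeans(logm[ok, , drop = FALSE])
  sf <- apply(logm[ok, , drop = FALSE], 2, function(col) {
    exp(stats::median(col - loggeo))
  })
  names(sf) <- colnames(m)
  sf
}

# Internal: moment dispersion with trend shrinkage -----------------------

# Per-gene method-of-moments NB dispersion on normalized counts, shrunk
# toward a 1/mean trend fitted across genes. Small residual d.f. at typical
# replicate numbers make the raw per-gene estimates extremely noisy; the
# shrinkage weight prior_df plays the role of the prior degrees of freedom.
estimate_dispersions <- function(qn, groups, sf, prior_df = 6) {
  ug <- unique(groups)
  n <- ncol(qn)
  inv_sf_mean <- mean(1 / sf)
  ssq <- rep(0, nrow(qn)); df <- 0
  for (g in ug) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    sub <- qn[, idx, drop = FALSE]
    ssq <- ssq + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(idx) - 1
  }
  m <- rowMeans(qn)
  v <- ssq / max(df, 1)
  raw <- (v - m * inv_sf_mean) / m^2
  raw[!is.finite(raw)] <- NA
  pos <- which(is.finite(raw) & raw > 0 & m > 0)
  trend <- rep(1e-4, nrow(qn))
  if (length(pos) >= 10) {
    fit <- try(stats::lm(raw[pos] ~ I(1 / m[pos])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      a <- pmax(stats::coef(fit), c(1e-6, 0))
      trend <- a[1] + a[2] / pmax(m, 1e-8)
    } else {
      trend <- rep(stats::median(raw[pos]), nrow(qn))
    }
  } else if (length(pos) > 0) {
    trend <- rep(stats::median(raw[pos]), nrow(qn))
  }
  raw_c <- pmin(pmax(ifelse(is.na(raw), trend, raw), 1e-8), 20)
  disp <- (df * raw_c + prior_df * trend) / (df + prior_df)
  pmin(pmax(disp, 1e-8), 20)
}

#' Call differentially expressed genes (NB Wald test)
#'
#' Per-gene negative-binomial test of the tumour group against the origin
#' group: counts are normalized by median-of-ratios size factors, dispersion
#' is estimated by method of moments with shrinkage toward a fitted
#' mean-dispersion trend, and the log2 fold change of normalized group means
#' is tested with a Wald z statistic (delta-method standard error on the
#' log2 scale). P-values are BH-adjusted.
#'
#' @param cm A [count_matrix()].
#' @param origin_group,tumour_group Group labels to compare (fold changes
#'   are tumour over origin).
#' @param alpha Significance level on the BH-adjusted q-value.
#' @param lfc_min Minimum absolute log2 fold change for a DEG call.
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @param pseudocount Passed to [size_factors()].
#' @return A data.frame (class `deg_result`) with columns `gene_id`,
#'   `base_mean`, `log2fc`, `p`, `q`, `direction` (`UP`/`DOWN`/`NS`).
#' @export
call_degs <- function(cm, origin_group, tumour_group, alpha = 0.05,
                      lfc_min = 0, prior_df = 6, pseudocount = 0) {
  stopifnot(inherits(cm, "count_matrix"))
  for (g in c(origin_group, tumour_group)) {
    if (!g %in% cm$groups) stop("group not present in count matrix: ", g)
    if (sum(cm$groups == g) < 2) stop("group ", g, " has < 2 replicates")
  }
  keep <- cm$groups %in% c(origin_group, tumour_group)
  sub <- subset_samples(cm, keep)
  counts <- sub$counts
  groups <- sub$groups
  allzero <- rowSums(counts) == 0
  sf <- size_factors(counts[!allzero, , drop = FALSE],
                     pseudocount = pseudocount)
  qn <- sweep(counts, 2, sf, "/")
  io <- which(groups == origin_group)
  it <- which(groups == tumour_group)
  n_o <- length(io); n_t <- length(it)
  mu_o <- rowMeans(qn[, io, drop = FALSE])
  mu_t <- rowMeans(qn[, it, drop = FALSE])
  disp <- estimate_dispersions(qn, groups, sf, prior_df = prior_df)
  eps <- 0.5
  lfc <- log2((mu_t + eps) / (mu_o + eps))
  var_group <- function(mu, idx) {
    (mu * sum(1 / sf[idx]) / length(idx)^2) + disp * mu^2 / length(idx)
  }
  v_o <- var_group(mu_o, io)
  v_t <- var_group(mu_t, it)
  se2 <- (v_t / (mu_t + eps)^2 + v_o / (mu_o + eps)^2) / log(2)^2
  se <- sqrt(se2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  p[allzero | (mu_o == 0 & mu_t == 0)] <- 1
  lfc[allzero] <- 0
  q <- bh_adjust(p)
  direction <- ifelse(q <= alpha & abs(lfc) >= lfc_min & lfc > 0, "UP",
               ifelse(q <= alpha & abs(lfc) >= lfc_min & lfc < 0, "DOWN",
                      "NS"))
  res <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(qn), log2fc = lfc, p = p, q = q,
                    direction = direction, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "lfc_min") <- lfc_min
  attr(res, "contrast") <- c(origin = origin_group, tumour = tumour_group)
  class(res) <- c("deg_result", "data.frame")
  res
}

#' Row-standardized display matrix
#'
#' Log2-transformed normalized expression, z-scored within each gene row
#' (rows with zero variance are left at zero).
#'
#' @param cm A [count_matrix()] or numeric matrix of expression values.
#' @param log If `TRUE` (default), apply `log2(x + 1)` to normalized counts
#'   first.
#' @return Matrix of the same dimensions, rows mean 0 / sd 1 where defined.
#' @export
display_matrix <- function(cm, log = TRUE) {
  if (inherits(cm, "count_matrix")) {
    sf <- size_factors(cm, pseudocount = if (all(cm$counts == 0)) 1 else 0)
    m <- sweep(cm$counts, 2, sf, "/")
  } else {
    m <- as.matrix(cm)
  }
  if (log) m <- log2(m + 1)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Hierarchical clustering of samples
#'
#' Average-linkage clustering on one-minus-Pearson-correlation distances
#' between sample columns (constant rows are dropped with a warning).
#'
#' @param dm Numeric matrix, genes x samples (e.g. from [display_matrix()]).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param distance `"pearson"` (1 - r) or `"euclidean"`.
#' @return An [stats::hclust] object.
#' @export
cluster_samples <- function(dm, linkage = "average", distance = "pearson") {
  dm <- as.matrix(dm)
  if (ncol(dm) < 2) stop("need at least 2 samples to cluster")
  sdv <- apply(dm, 1, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " constant row(s) dropped before clustering")
    dm <- dm[sdv > 0, , drop = FALSE]
  }
  d <- if (distance == "pearson") {
    stats::as.dist(1 - stats::cor(dm))
  } else {
    stats::dist(t(dm))
  }
  stats::hclust(d, method = linkage)
}

#' PCA of samples with first-component correlations
#'
#' Principal component analysis of the row-centered expression matrix,
#' reporting each sample's Pearson correlation with the first component.
#'
#' @param dm Numeric matrix, genes x samples.
#' @return List with `pca` (a [stats::prcomp] object over sample variables),
#'   `sample_cor_pc1` (named correlations of samples with PC1 scores).
#' @export
pca_samples <- function(dm) {
  dm <- as.matrix(dm)
  if (ncol(dm) < 2) stop("need at least 2 samples for PCA")
  dmc <- dm - rowMeans(dm)
  pc <- stats::prcomp(dmc, center = TRUE, scale. = FALSE)
  cors <- apply(dmc, 2, function(col) {
    if (stats::sd(col) == 0) return(NA_real_)
    stats::cor(col, pc$x[, 1])
  })
  list(pca = pc, sample_cor_pc1 = cors)
}

#' Batch-specific gene clusters
#'
#' Assigns a gene to a batch if and only if it is significantly upregulated
#' in that batch against every other batch (pairwise [call_degs()], BH within
#' each comparison). With fewer than 2 replicates in any batch the test is
#' impossible and a fold-change rule (log2 fold change >= `lfc_fallback`
#' against every other batch) is used instead, with a warning. The clusters
#' are disjoint by construction.
#'
#' @param cm A [count_matrix()] whose groups are batch labels (>= 3 batches).
#' @param alpha Per-comparison q-value threshold.
#' @param lfc_fallback Log2 fold-change threshold for the fallback rule.
#' @return Named list mapping batch label to character vector of gene ids.
#' @export
batch_specific_clusters <- function(cm, alpha = 0.05, lfc_fallback = 1) {
  batches <- unique(cm$groups)
  if (length(batches) < 3) stop("need >= 3 batches")
  reps <- table(cm$groups)
  use_test <- all(reps >= 2)
  if (!use_test) {
    warning("batch with < 2 replicates: falling back to fold-change rule")
  }
  sf <- size_factors(cm, pseudocount = 1)
  qn <- sweep(cm$counts, 2, sf, "/")
  out <- list()
  for (b in batches) {
    sel <- rep(TRUE, nrow(cm$counts))
    for (o in setdiff(batches, b)) {
      if (use_test) {
        deg <- call_degs(cm, origin_group = o, tumour_group = b,
                         alpha = alpha)
        sel <- sel & (deg$q <= alpha & deg$log2fc > 0)
      } else {
        mb <- rowMeans(qn[, cm$groups == b, drop = FALSE])
        mo <- rowMeans(qn[, cm$groups == o, drop = FALSE])
        sel <- sel & (log2((mb + 0.5) / (mo + 0.5)) >= lfc_fallback)
      }
    }
    out[[b]] <- rownames(cm$counts)[sel]
  }
  out
}
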