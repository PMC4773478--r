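#' TF-centred co-expression neighborhood
#'
#' Pearson correlation of every gene with the focal gene across the
#' profiles of an expression compendium; keeps genes with `|r|` at or above
#' the threshold (or the `top_k` strongest), excluding the focal gene
#' itself.
#'
#' @param compendium Numeric matrix, genes x profiles (rownames = gene
#'   ids), with at least 3 profiles.
#' @param focal_gene Gene id present in the compendium.
#' @param min_abs_r Absolute correlation threshold (default 0.5).
#' @param top_k If set, keep the `top_k` genes by `|r|` instead.
#' @return Named numeric vector of correlations (the neighborhood).
#' @export
coexpression_neighborhood <- function(compendium, focal_gene,
                                      min_abs_r = 0.5, top_k = NULL) {
  compendium <- as.matrix(compendium)
  if (ncol(compendium) < 3) stop("need >= 3 profiles")
  if (!focal_gene %in% rownames(compendium)) {
    stop("focal gene not in compendium: ", focal_gene)
  }
  x <- compendium[focal_gene, ]
  if (stats::sd(x) == 0) stop("focal gene has constant expression")
  r <- as.vector(stats::cor(t(compendium), x))
  names(r) <- rownames(compendium)
  r <- r[setdiff(names(r), focal_gene)]
  r <- r[!is.na(r)]
  if (!is.null(top_k)) {
    r <- r[order(-abs(r))][seq_len(min(top_k, length(r)))]
  } else {
    r <- r[abs(r) >= min_abs_r]
  }
  r
}

#' TF-dependent genes from an overexpression contrast
#'
#' Differential expression between a batch and the same batch upon TF
#' overexpression; returns the significant genes split by direction.
#'
#' @param cm A [count_matrix()] containing both conditions.
#' @param base_group,oe_group Group labels (baseline and overexpression).
#' @param alpha q-value threshold.
#' @param ... Passed to [call_degs()].
#' @return List with `up`, `down` (gene ids; direction of the
#'   overexpression response) and `deg` (the full table).
#' @export
tf_dependent_genes <- function(cm, base_group, oe_group, alpha = 0.05,
                               ...) {
  deg <- call_degs(cm, origin_group = base_group, tumour_group = oe_group,
                   alpha = alpha, ...)
  list(up = deg$gene_id[deg$direction == "UP"],
       down = deg$gene_id[deg$direction == "DOWN"],
       deg = deg)
}

#' Exclusive Venn region cardinalities
#'
#' @param sets Named list of character vectors.
#' @return Named integer vector over all `2^k - 1` non-empty membership
#'   patterns (names like `"A"`, `"A&B"`); the counts sum to the size of
#'   the union.
#' @export
venn_regions <- function(sets) {
  k <- length(sets)
  stopifnot(k >= 1)
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(k)]
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1)
  keys <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  patterns <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, paste, collapse = "&")
  }))
  out <- stats::setNames(integer(length(patterns)), patterns)
  tab <- table(keys)
  out[names(tab)] <- as.integer(tab)
  out
}

gsea_es <- function(hits, scores, weight) {
  # hits: logical over the (already sorted) ranking; scores: sorted stats
  N <- length(hits)
  m <- sum(hits)
  w <- abs(scores)^weight
  inc <- numeric(N)
  inc[hits] <- w[hits] / sum(w[hits])
  inc[!hits] <- -1 / (N - m)
  run <- cumsum(inc)
  # signed maximum deviation; on a magnitude tie the positive peak wins
  mp <- max(run); mn <- min(run)
  if (mp >= -mn) mp else mn
}

#' Gene set enrichment analysis (weighted Kolmogorov-Smirnov running sum)
#'
#' Genes are ranked by the score (decreasing); the running sum increases by
#' the gene's `|score|^weight` (normalized over set members) at set hits
#' and decreases by `1/(N - |S|)` at misses. The enrichment score is the
#' signed maximum deviation. The null is a gene-label permutation of set
#' membership; the nominal p-value uses the add-one correction
#' `(1 + #{|es_perm| >= |es|}) / (n_perm + 1)`.
#'
#' @param scores Named numeric vector, the ranking metric (e.g. transition
#'   log2 fold changes).
#' @param gene_set Character vector of set members.
#' @param weight Score weighting exponent (0 = classic KS, 1 = weighted).
#' @param n_perm Number of permutations.
#' @param seed Integer seed; the permutation p is bit-reproducible given
#'   `(n_perm, seed)`.
#' @return List (class `gsea_result`): `es`, `nes`, `nominal_p`, `n_perm`,
#'   `seed`, `leading_edge`, `n_set`.
#' @export
gsea <- function(scores, gene_set, weight = 1, n_perm = 1000, seed = 1) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  gene_set <- unique(gene_set)
  inset <- names(scores) %in% gene_set
  if (!any(inset)) stop("gene set does not intersect the ranked list")
  if (all(inset)) stop("gene set covers the whole ranked list")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hits <- inset[ord]
  N <- length(s); m <- sum(hits)
  es <- gsea_es(hits, s, weight)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(b) {
      h <- logical(N)
      h[sample.int(N, m)] <- TRUE
      gsea_es(h, s, weight)
    }, numeric(1))
  })
  nominal_p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
  same_sign <- perm[sign(perm) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  # leading edge: set members at or before (after, for negative es) the peak
  w <- abs(s)^weight
  inc <- numeric(N); inc[hits] <- w[hits] / sum(w[hits])
  inc[!hits] <- -1 / (N - m)
  run <- cumsum(inc)
  peak <- if (es >= 0) which.max(run) else which.min(run)
  le <- if (es >= 0) names(s)[seq_len(peak)][hits[seq_len(peak)]]
        else names(s)[peak:N][hits[peak:N]]
  structure(list(es = es, nes = nes, nominal_p = nominal_p,
                 n_perm = n_perm, seed = seed, leading_edge = le,
                 n_set = m),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: es = %.3f, nes = %.3f, p = %.4g (%d perms, seed %d)\n",
              x$es, x$nes, x$nominal_p, x$n_perm, x$seed))
  invisible(x)
}

#' Tumour retention of a batch-specific cluster, with shuffling null
#'
#' A cluster gene is "retained" when its expression status (above/below the
#' `quantile_threshold` quantile of the sample-wide distribution) is the
#' same in the matched tumour as in the originating batch. The observed
#' retained fraction is compared with the same statistic on size-matched
#' random gene draws from the shared universe (the shuffling null),
#' yielding a z-score and an add-one-corrected empirical p.
#'
#' @param cluster Character vector of cluster gene ids.
#' @param batch_expr,pt_expr Named numeric vectors of per-gene expression
#'   in the batch and the matched tumour.
#' @param quantile_threshold Quantile defining "expressed" (default 0.5,
#'   the median).
#' @param n_shuffles Number of null draws.
#' @param seed Integer seed.
#' @return List: `fraction`, `null_mean`, `null_sd`, `z`, `p`,
#'   `n_shuffles`, `seed`.
#' @export
retention_fraction <- function(cluster, batch_expr, pt_expr,
                               quantile_threshold = 0.5,
                               n_shuffles = 1000, seed = 1) {
  universe <- intersect(names(batch_expr), names(pt_expr))
  cluster <- intersect(cluster, universe)
  if (length(cluster) == 0) stop("empty cluster")
  tb <- stats::quantile(batch_expr[universe], quantile_threshold)
  tp <- stats::quantile(pt_expr[universe], quantile_threshold)
  status_b <- batch_expr[universe] > tb
  status_p <- pt_expr[universe] > tp
  retained <- status_b == status_p
  names(retained) <- universe
  frac <- mean(retained[cluster])
  with_seed(seed, {
    nulls <- vapply(seq_len(n_shuffles), function(b) {
      mean(retained[sample(universe, length(cluster))])
    }, numeric(1))
  })
  z <- (frac - mean(nulls)) /
    max(stats::sd(nulls), .Machine$double.eps)
  p <- (1 + sum(nulls >= frac)) / (n_shuffles + 1)
  list(fraction = frac, null_mean = mean(nulls), null_sd = stats::sd(nulls),
       z = z, p = p, n_shuffles = n_shuffles, seed = seed)
}
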