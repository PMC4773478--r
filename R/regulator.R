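#' Over-representation analysis by right-tailed Fisher's exact test
#'
#' For each named gene set, tests the overlap with the query against the
#' hypergeometric upper tail of the 2x2 table (in/out query x in/out set)
#' within the universe. Sets are intersected with the universe first;
#' q-values are BH-adjusted across sets.
#'
#' @param query Character vector of gene ids (must be within the universe).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector, the background gene universe.
#' @return Data.frame with `set`, `set_size`, `overlap`, `expected`,
#'   `odds_ratio`, `p` (right tail), `q` (BH).
#' @export
ora_fisher <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  bad <- setdiff(query, universe)
  if (length(bad)) stop("query gene(s) outside the universe: ",
                        paste(utils::head(bad, 3), collapse = ", "))
  nu <- length(universe); nq <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    ns <- length(s)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, ns, nu - ns, nq, lower.tail = FALSE)
    a <- k; b <- nq - k; cc <- ns - k; d <- nu - ns - nq + k
    or <- (a * d) / (b * cc)
    data.frame(set = nm, set_size = ns, overlap = k,
               expected = nq * ns / nu, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}

#' Hypergeometric significance of the overlap of two gene sets
#'
#' @param set_a,set_b Character vectors (subsets of the universe).
#' @param universe Background gene universe.
#' @return List with `overlap` (size), `expected`, `p` (upper tail).
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_b), length(universe) - length(set_b),
                     length(set_a), lower.tail = FALSE)
  list(overlap = k,
       expected = length(set_a) * length(set_b) / length(universe),
       p = p)
}

#' Intersection of downregulated DEGs with de novo mark targets
#'
#' The core gene set of the integration: genes significantly downregulated
#' in the transition that simultaneously acquire the repressive mark de
#' novo, with their DE annotations carried through.
#'
#' @param deg A `deg_result` from [call_degs()].
#' @param denovo Character vector of de novo target gene ids.
#' @return Subset of `deg` rows (downregulated AND de novo marked).
#' @export
intersect_down_denovo <- function(deg, denovo) {
  out <- deg[deg$direction == "DOWN" & deg$gene_id %in% denovo, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate master regulator transcription factors
#'
#' Rows are the motif-enriched TFs (Bonferroni p below `alpha`), mapped to
#' their own genes, annotated with the expression change of the transition
#' and the de novo mark status of their promoter, and sorted by DE q-value
#' (ascending), then absolute log2 fold change (descending), then gene id.
#' A TF is shortlisted when its motif is enriched, its own gene is
#' significantly downregulated, and its promoter is de novo marked.
#'
#' @param enrichment A `motif_enrichment` result.
#' @param deg A `deg_result` over the same transition.
#' @param denovo Character vector of de novo marked gene ids.
#' @param tf_map Data.frame with columns `pwm_id`, `gene_id` mapping motifs
#'   to the TF's own gene.
#' @param alpha Significance level for both the Bonferroni motif p and the
#'   DE q.
#' @return Data.frame (class `regulator_table`): `pwm_id`, `gene_id`,
#'   `motif_p_bonferroni`, `de_log2fc`, `de_q`, `direction`, `mark_status`
#'   (`MARKED`/`UNMARKED`), `shortlisted`.
#' @export
rank_master_regulators <- function(enrichment, deg, denovo, tf_map,
                                   alpha = 0.05) {
  keep <- !is.na(enrichment$p_bonferroni) & enrichment$p_bonferroni < alpha
  enr <- enrichment[keep, , drop = FALSE]
  if (nrow(enr) == 0) {
    out <- data.frame(pwm_id = character(), gene_id = character(),
                      motif_p_bonferroni = numeric(), de_log2fc = numeric(),
                      de_q = numeric(), direction = character(),
                      mark_status = character(), shortlisted = logical())
    class(out) <- c("regulator_table", "data.frame")
    return(out)
  }
  m <- match(enr$pwm_id, tf_map$pwm_id)
  unmapped <- is.na(m)
  if (any(unmapped)) {
    warning("enriched motif(s) without a TF gene mapping excluded: ",
            paste(enr$pwm_id[unmapped], collapse = ", "))
  }
  enr <- enr[!unmapped, , drop = FALSE]
  genes <- tf_map$gene_id[m[!unmapped]]
  dm <- match(genes, deg$gene_id)
  missing <- is.na(dm)
  if (any(missing)) {
    warning("TF gene(s) absent from the DEG universe excluded: ",
            paste(genes[missing], collapse = ", "))
  }
  enr <- enr[!missing, , drop = FALSE]
  genes <- genes[!missing]
  dm <- dm[!missing]
  out <- data.frame(
    pwm_id = enr$pwm_id, gene_id = genes,
    motif_p_bonferroni = enr$p_bonferroni,
    de_log2fc = deg$log2fc[dm], de_q = deg$q[dm],
    direction = deg$direction[dm],
    mark_status = ifelse(genes %in% denovo, "MARKED", "UNMARKED"),
    stringsAsFactors = FALSE
  )
  out$shortlisted <- out$motif_p_bonferroni < alpha &
    out$direction == "DOWN" & out$de_q < alpha &
    out$mark_status == "MARKED"
  ord <- order(out$de_q, -abs(out$de_log2fc), out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regulator_table", "data.frame")
  out
}
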