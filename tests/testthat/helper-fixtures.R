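# Shared fixture builders: everything is generated in code at test time.

tiny_design <- function(n_genes = 200, seed = 1, ...) {
  simulation_design(n_genes = n_genes, seed = seed, ...)
}

# A design with planted DEGs: first n_down genes at -lfc, next n_up at +lfc.
planted_deg_design <- function(n_genes = 1000, n_down = 100, n_up = 100,
                               lfc = 2, seed = 1, ...) {
  ids <- sprintf("g%04d", seq_len(n_genes))
  deg <- stats::setNames(c(rep(-lfc, n_down), rep(lfc, n_up)),
                         ids[seq_len(n_down + n_up)])
  simulation_design(n_genes = n_genes, deg_lfc = deg, seed = seed, ...)
}

# Independent hypergeometric upper-tail oracle by explicit term summation.
hyper_tail_enum <- function(k, set_size, universe, query) {
  ks <- k:min(set_size, query)
  sum(vapply(ks, function(i) {
    choose(set_size, i) * choose(universe - set_size, query - i)
  }, numeric(1))) / choose(universe, query)
}

# Independent GSEA running-sum oracle: position-by-position loop.
gsea_es_oracle <- function(scores, set_members, weight) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% set_members
  N <- length(s); m <- sum(hit)
  denom_hit <- sum(abs(s[hit])^weight)
  run <- numeric(N); acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) abs(s[i])^weight / denom_hit else -1 / (N - m)
    run[i] <- acc
  }
  mp <- max(run); mn <- min(run)
  unname(if (mp >= -mn) mp else mn)
}

# Exact Mann-Whitney two-sided p by full enumeration of group assignments.
mw_p_enum <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  combos <- utils::combn(length(v), n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  e <- mean(sums)
  obs <- sum(r[seq_len(n1)])
  mean(abs(sums - e) >= abs(obs - e) - 1e-9)
}
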