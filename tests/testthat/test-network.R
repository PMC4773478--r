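# Co-expression neighborhoods, Venn regions, GSEA, and cluster retention.

make_compendium <- function(n_genes = 300, n_profiles = 106, seed = 1,
                            module = NULL, loading = 0.95) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_profiles), n_genes, n_profiles,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)), NULL))
  if (!is.null(module)) {
    f <- rnorm(n_profiles)
    m[module, ] <- loading * matrix(f, length(module), n_profiles,
                                    byrow = TRUE) +
      sqrt(1 - loading^2) * m[module, ]
  }
  m
}

test_that("co-expression neighborhood recovers planted modules", {
  set.seed(73)
  module <- sprintf("g%04d", 1:30)
  recov <- replicate(5, {
    m <- make_compendium(seed = sample.int(1e6, 1), module = module)
    nb <- coexpression_neighborhood(m, "g0001")
    mean(module[-1] %in% names(nb))
  })
  expect_gte(mean(recov), 0.95)
  # duplicated gene always included with r = 1
  m <- make_compendium(seed = 2)
  m <- rbind(m, dup = m["g0001", ])
  nb <- coexpression_neighborhood(m, "g0001")
  expect_equal(unname(nb["dup"]), 1)
  # null inclusion rate matches the r tail at n = 106 (essentially zero)
  m0 <- make_compendium(n_genes = 2000, seed = 3)
  nb0 <- coexpression_neighborhood(m0, "g0001")
  p_tail <- 2 * stats::pt(-0.5 * sqrt(104 / (1 - 0.25)), df = 104)
  expect_lte(length(nb0), stats::qbinom(0.999, 1999, max(p_tail, 1e-6)) + 1)
  # constant focal gene -> error
  m0["g0002", ] <- 1
  expect_error(coexpression_neighborhood(m0, "g0002"), "constant")
  expect_error(coexpression_neighborhood(m0[, 1:2], "g0001"), "profiles")
})

test_that("venn regions partition the union", {
  sets <- list(A = letters[1:10], B = letters[5:15], C = letters[8:20])
  v <- venn_regions(sets)
  expect_length(v, 7)
  expect_equal(sum(v), length(unique(unlist(sets))))
  expect_equal(unname(v["A&B&C"]), length(Reduce(intersect, sets)))
  # three identical sets put all mass in the triple region
  same <- venn_regions(list(A = letters[1:5], B = letters[1:5],
                            C = letters[1:5]))
  expect_equal(unname(same["A&B&C"]), 5)
  expect_equal(sum(same), 5)
})

test_that("tf-dependent gene sets respond to planted overexpression", {
  ids <- sprintf("g%04d", 1:400)
  lfc <- stats::setNames(rep(2, 40), ids[1:40])
  d <- simulation_design(n_genes = 400,
                         n_per_group = c(base = 3, oe = 3),
                         deg_lfc = lfc, seed = 31)
  cm <- simulate_counts(d)
  res <- tf_dependent_genes(cm, "base", "oe")
  expect_gte(length(intersect(res$up, ids[1:40])), 36)
  expect_lte(length(res$down), 5)
  # identical conditions -> empty
  same <- count_matrix(cm$counts[, c(1:3, 1:3)],
                       rep(c("base", "oe"), each = 3))
  res0 <- tf_dependent_genes(same, "base", "oe")
  expect_length(c(res0$up, res0$down), 0)
})

test_that("gsea running sum matches the brute-force oracle", {
  # |S| = 1 at rank 1, weight 0 -> es = 1
  sc <- stats::setNames(seq(10, 1), letters[1:10])
  expect_equal(gsea(sc, "a", weight = 0, n_perm = 99, seed = 1)$es, 1)
  # N = 10, set at ranks {1,2,3}, weight 0: position-by-position oracle
  es <- gsea(sc, c("a", "b", "c"), weight = 0, n_perm = 99, seed = 1)$es
  expect_equal(es, gsea_es_oracle(sc, c("a", "b", "c"), 0))
  # random instances, N <= 20, both weights
  set.seed(12)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    sc <- stats::setNames(rnorm(n), paste0("x", seq_len(n)))
    members <- sample(names(sc), sample(seq_len(n - 1), 1))
    for (w in c(0, 1)) {
      expect_equal(gsea(sc, members, weight = w, n_perm = 19, seed = 2)$es,
                   gsea_es_oracle(sc, members, w), tolerance = 1e-12)
    }
  }
})

test_that("gsea es is invariant to monotone score transforms at weight 0", {
  sc <- stats::setNames(rnorm(50), paste0("x", 1:50))
  members <- sample(names(sc), 12)
  a <- gsea(sc, members, weight = 0, n_perm = 49, seed = 3)
  b <- gsea(exp(2 * sc) + 5, members, weight = 0, n_perm = 49, seed = 3)
  expect_equal(a$es, b$es, tolerance = 1e-12)
  expect_equal(a$nominal_p, b$nominal_p)
})

test_that("gsea agrees with fgsea's enrichment statistic", {
  set.seed(21)
  sc <- stats::setNames(rnorm(200), paste0("x", 1:200))
  members <- sample(names(sc), 25)
  ours <- gsea(sc, members, weight = 1, n_perm = 19, seed = 1)$es
  ord <- order(sc, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(sc[ord],
                             which(names(sc)[ord] %in% members),
                             gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("gsea permutation p is reproducible and null-uniform", {
  sc <- stats::setNames(rnorm(100), paste0("x", 1:100))
  members <- sample(names(sc), 15)
  a <- gsea(sc, members, n_perm = 201, seed = 7)
  b <- gsea(sc, members, n_perm = 201, seed = 7)
  expect_identical(a$nominal_p, b$nominal_p)
  expect_true(a$nominal_p > 0 && a$nominal_p <= 1)
  expect_true(abs(a$es) <= 1)
  # null: random sets against a random ranking give uniform p
  set.seed(33)
  ps <- replicate(200, {
    sc <- stats::setNames(rnorm(60), paste0("x", 1:60))
    gsea(sc, sample(names(sc), 10), n_perm = 199,
         seed = sample.int(1e6, 1))$nominal_p
  })
  expect_lt(suppressWarnings(stats::ks.test(ps, "punif")$statistic), 0.1)
  expect_error(gsea(sc, "not_there"), "intersect")
})

test_that("retention fraction separates planted retention from the null", {
  set.seed(8)
  universe <- sprintf("g%04d", 1:500)
  batch <- stats::setNames(rnorm(500), universe)
  # identical tumour expression retains everything
  self <- retention_fraction(universe[1:50], batch, batch, n_shuffles = 99)
  expect_equal(self$fraction, 1.0)
  # planted retained module: cluster genes high in both batch and tumour
  cluster <- universe[1:50]
  batch[cluster] <- batch[cluster] + 3
  hits <- replicate(10, {
    pt <- stats::setNames(rnorm(500), universe)
    pt[cluster] <- pt[cluster] + 3
    r <- retention_fraction(cluster, batch, pt, n_shuffles = 199,
                            seed = sample.int(1e6, 1))
    r$p < 0.025
  })
  expect_gte(mean(hits), 0.9)
  # random clusters look like the null
  zs <- replicate(30, {
    pt <- stats::setNames(rnorm(500), universe)
    r <- retention_fraction(sample(universe, 50), batch, pt,
                            n_shuffles = 199, seed = sample.int(1e6, 1))
    abs(r$z)
  })
  expect_gte(mean(zs <= 2.5), 0.9)
  expect_error(retention_fraction(character(0), batch, batch), "empty")
})
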