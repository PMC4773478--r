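# TSS-window quantification, target calling, de novo logic, spatial
# pattern classification, and the Mann-Whitney machinery behind the
# expression-consequence comparison.

test_that("profile geometry contracts hold", {
  m <- matrix(5, 10, 60, dimnames = list(sprintf("g%04d", 1:10), NULL))
  pr <- chip_profile(m)
  expect_equal(ncol(pr$mat), 60)
  expect_error(chip_profile(m, window_half = 3000, bin_size = 70),
               "divide")
  expect_error(chip_profile(m[, 1:50]), "expected 60 bins")
  # flip involution
  expect_identical(flip_profile(flip_profile(pr))$mat, pr$mat)
})

test_that("bedGraph round trip preserves profiles and strand handling", {
  d <- tiny_design(n_genes = 30, seed = 13)
  ids <- sprintf("g%04d", 1:30)
  cls <- stats::setNames(rep("UP", 10), ids[1:10])
  d$chip_class <- list(tumour = cls)
  ch <- simulate_chip(d)
  genome <- simulate_genome(d)
  bg <- tempfile(fileext = ".bedGraph")
  write_profile_bedgraph(ch$samples[["tumour_1"]], genome$genes, bg)
  pr <- tss_profile(bg, genome$genes, sample = "tumour_1")
  # strand-corrected matrices agree bin by bin for both strands
  expect_equal(pr$mat, ch$samples[["tumour_1"]]$mat, tolerance = 1e-9)
  expect_true(any(genome$genes$strand == "-"))
  # UP enrichment lands in the upstream (negative) bins after correction
  up_mean <- rowMeans(pr$mat[1:10, 1:30])
  down_mean <- rowMeans(pr$mat[1:10, 31:60])
  expect_true(all(up_mean > 2 * down_mean))
  # annotation BED round trip
  bed <- tempfile(fileext = ".bed")
  write_genome_bed(genome, bed)
  ann <- read_annotation_bed(bed)
  expect_equal(ann$tss, genome$genes$tss)
  expect_equal(ann$strand, genome$genes$strand)
})

test_that("windows exiting the coordinate space are trimmed to NA", {
  ann <- data.frame(gene_id = c("edge", "inner"), chrom = "chrS",
                    tss = c(1000, 50000), strand = "+")
  gr <- GenomicRanges::GRanges("chrS",
                               IRanges::IRanges(1, 60000), score = 2)
  pr <- tss_profile(gr, ann)
  expect_true("edge" %in% attr(pr, "trimmed"))
  expect_true(anyNA(pr$mat["edge", ]))
  expect_equal(unname(pr$mat["inner", ]), rep(2, 60))
})

test_that("target caller recovers planted marks and stays null-calibrated", {
  set.seed(61)
  ids <- sprintf("g%04d", 1:1000)
  cls <- stats::setNames(rep("TSS", 200), ids[1:200])
  stats_over_seeds <- replicate(3, {
    d <- simulation_design(n_genes = 1000, seed = sample.int(1e6, 1),
                           chip_class = list(tumour = cls),
                           enrichment_factor = 8)
    ch <- simulate_chip(d)
    calls <- call_targets(ch$samples[["tumour_1"]], ch$control)
    hit <- calls$gene_id[calls$is_target]
    c(tp = length(intersect(hit, ids[1:200])),
      fp = length(setdiff(hit, ids[1:200])))
  })
  expect_gte(mean(stats_over_seeds["tp", ]), 190)
  expect_lte(mean(stats_over_seeds["fp", ]), 60)
  # enrichment_factor 1: expected target fraction bounded by the fdr
  frac <- replicate(3, {
    d <- simulation_design(n_genes = 500, seed = sample.int(1e6, 1),
                           enrichment_factor = 1)
    ch <- simulate_chip(d)
    mean(call_targets(ch$samples[[1]], ch$control)$is_target)
  })
  expect_lte(mean(frac), 0.05 + 0.03)
  # zero control -> error
  m0 <- chip_profile(matrix(0, 500, 60,
                            dimnames = list(sprintf("g%04d", 1:500), NULL)))
  d <- simulation_design(n_genes = 500, seed = 1)
  ch <- simulate_chip(d)
  expect_error(call_targets(ch$samples[[1]], m0), "control")
})

test_that("de novo rule is the strict intersection-minus-union", {
  mk <- function(genes, universe) {
    data.frame(gene_id = universe, is_target = universe %in% genes)
  }
  u <- sprintf("g%02d", 1:20)
  t1 <- mk(u[1:10], u); t2 <- mk(u[3:12], u); o1 <- mk(u[9:10], u)
  expect_equal(de_novo_targets(list(o1), list(t1, t2)), sort(u[3:8]))
  # identical tumour and origin calls -> empty
  expect_length(de_novo_targets(list(t1), list(t1)), 0)
  # adding a tumour sample can only shrink the set
  before <- de_novo_targets(list(o1), list(t1))
  after <- de_novo_targets(list(o1), list(t1, t2))
  expect_true(all(after %in% before))
  expect_error(de_novo_targets(list(), list(t1)), "at least one")
})

test_that("pattern classification follows the flank log-ratio rule", {
  # hand computation: U = 80, D = 15 -> log2(80/15) = 2.415 -> UP
  v <- c(rep(80, 30), rep(15, 30))
  expect_equal(unname(classify_pattern(v)), "UP")
  expect_equal(unname(classify_pattern(rev(v))), "DOWN")
  # perfectly symmetric flank enrichment -> TSS
  sym <- c(rep(50, 29), 5, 5, rep(50, 29))
  expect_equal(unname(classify_pattern(sym)), "TSS")
  # reversal swaps UP/DOWN and fixes TSS on random profiles
  set.seed(99)
  m <- matrix(rexp(200 * 60, 1 / 20) + 0.1, 200, 60,
              dimnames = list(sprintf("g%04d", 1:200), NULL))
  pr <- chip_profile(m)
  cls <- classify_pattern(pr)
  cls_rev <- classify_pattern(flip_profile(pr))
  swap <- c(UP = "DOWN", DOWN = "UP", TSS = "TSS")
  expect_identical(unname(cls_rev), unname(swap[cls]))
  # both flanks zero for a called target is inconsistent
  z <- matrix(0, 1, 60, dimnames = list("g1", NULL))
  expect_error(classify_pattern(chip_profile(z)), "inconsistent")
})

test_that("mann-whitney exact p matches full enumeration and wilcox", {
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 2/20
  t <- mw_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$statistic, 0)
  expect_equal(t$p, 0.1)
  expect_equal(t$method, "exact")
  # identical tied samples -> p = 1 under the exact midrank null
  expect_equal(mw_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # random instances (with ties) vs full-permutation enumeration
  set.seed(7)
  for (i in 1:20) {
    x <- sample(1:6, sample(3:8, 1), replace = TRUE)
    y <- sample(1:6, sample(3:8, 1), replace = TRUE)
    expect_equal(mw_test(x, y)$p, mw_p_enum(x, y), tolerance = 1e-12)
  }
  # untied instances agree with wilcox.test exact p
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(mw_test(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample normal approximation agrees with wilcox.test
  x <- rnorm(30); y <- rnorm(25) + 0.5
  expect_equal(mw_test(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("expression consequence of patterns is detected", {
  classes <- c(rep("TSS", 100), rep("UP", 100))
  names(classes) <- sprintf("g%04d", 1:200)
  rej <- replicate(20, {
    expr <- c(rnorm(100, -1), rnorm(100, 0))
    names(expr) <- names(classes)
    res <- expression_by_pattern(classes, expr)
    res$pairwise$p < 0.05
  })
  expect_gte(mean(rej), 0.95)
  # small classes excluded with a warning; < 2 classes left -> error
  cl2 <- c(a = "TSS", b = "UP", c = "UP")
  expect_error(
    expect_warning(expression_by_pattern(cl2, c(a = 1, b = 2, c = 3)),
                   "excluded"),
    "2 non-empty"
  )
})
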