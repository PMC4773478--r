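# Synthetic-data generator: determinism, planted-effect fidelity, and
# degenerate-input handling.

test_that("degenerate designs are rejected", {
  expect_error(simulation_design(n_genes = 0), "configuration error")
  expect_error(simulation_design(dispersion = -1), "dispersion")
  expect_error(simulation_design(enrichment_factor = 0.5), "enrichment")
  expect_error(simulation_design(deg_lfc = c(g0001 = Inf)), "finite")
  expect_error(simulation_design(bin_size = 70), "divide")
})

test_that("identical designs give byte-identical outputs", {
  d <- tiny_design(n_genes = 50, seed = 7)
  b1 <- simulate_genome(d)
  b2 <- simulate_genome(d)
  expect_identical(b1, b2)
  expect_identical(simulate_counts(d), simulate_counts(d))
  c1 <- simulate_chip(d)
  c2 <- simulate_chip(d)
  expect_identical(c1$samples[[1]]$mat, c2$samples[[1]]$mat)
  # byte-identical files
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_promoters_fasta(b1, f1); write_promoters_fasta(b2, f2)
  expect_identical(readLines(f1), readLines(f2))
  p1 <- tempfile(fileext = ".bed"); p2 <- tempfile(fileext = ".bed")
  write_genome_bed(b1, p1); write_genome_bed(b2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("promoter base composition matches the uniform model", {
  d <- simulation_design(n_genes = 500, promoter_len = 500, seed = 1)
  b <- simulate_genome(d)
  expect_length(b$promoters, 500)
  expect_true(all(nchar(b$promoters) == 500))
  expect_false(any(grepl("[^ACGT]", b$promoters)))
  gc <- vapply(strsplit(b$promoters, ""), function(s) {
    mean(s %in% c("G", "C"))
  }, numeric(1))
  # binomial sd at 500 bp is ~0.022; 3.6 sd bounds every promoter whp,
  # and the grand mean is far tighter
  expect_true(all(gc > 0.42 & gc < 0.58))
  expect_lt(abs(mean(gc) - 0.5), 0.01)
  expect_gte(mean(gc > 0.45 & gc < 0.55), 0.9)
  # TSS windows are non-overlapping
  expect_true(all(diff(sort(b$genes$tss)) > 2 * d$window_half))
})

test_that("plant_motifs writes sites into targets only", {
  d <- tiny_design(n_genes = 20, seed = 3)
  b <- simulate_genome(d)
  cons <- pwm(matrix(c(100, 0, 0, 0,  0, 0, 0, 100, 100, 0, 0, 0,
                       0, 100, 0, 0, 0, 0, 100, 0, 0, 0, 0, 100), 4),
              id = "CONS")
  expect_identical(plant_motifs(b, cons, "g0001", 0, seed = 1), b)
  planted <- plant_motifs(b, cons, c("g0001", "g0002"), 1, seed = 1)
  for (g in c("g0001", "g0002")) {
    expect_true(grepl(cons$consensus, planted$promoters[[g]]))
    expect_equal(unname(best_site_score(planted$promoters[[g]], cons)), 1.0)
  }
  untouched <- setdiff(names(b$promoters), c("g0001", "g0002"))
  expect_identical(planted$promoters[untouched], b$promoters[untouched])
  expect_error(plant_motifs(b, cons, "gXXXX", 1), "not in bundle")
  wide <- pwm(matrix(1, 4, 200), id = "WIDE")
  expect_error(plant_motifs(b, wide, "g0001", 3, seed = 1), "non-overlapping")
})

test_that("planted fold changes are recovered in the simulated counts", {
  d <- planted_deg_design(n_genes = 1000, n_down = 100, n_up = 0,
                          lfc = 2, seed = 11)
  cm <- simulate_counts(d)
  expect_equal(dim(cm), c(1000L, 6L))
  sf <- size_factors(cm)
  qn <- sweep(cm$counts, 2, sf, "/")
  obs_lfc <- log2(rowMeans(qn[1:100, 4:6]) / rowMeans(qn[1:100, 1:3]))
  expect_lt(abs(mean(obs_lfc) - (-2)), 0.3)
})

test_that("a scaled library is recovered by the size factors", {
  d <- tiny_design(n_genes = 500, seed = 5, dispersion = 0.01)
  cm <- simulate_counts(d, sample_scale = c(tumour_1 = 2))
  sf <- size_factors(cm)
  others <- setdiff(colnames(cm$counts), "tumour_1")
  expect_lt(abs(sf[["tumour_1"]] / median(sf[others]) - 2), 0.15)
})

test_that("spatial chip classes produce the planted geometry", {
  ids <- sprintf("g%04d", 1:300)
  cls <- c(stats::setNames(rep("UP", 100), ids[1:100]),
           stats::setNames(rep("TSS", 100), ids[101:200]))
  d <- simulation_design(n_genes = 300, seed = 9,
                         chip_class = list(tumour = cls),
                         enrichment_factor = 8)
  ch <- simulate_chip(d)
  expect_length(ch$samples, 6)
  m <- ch$samples[["tumour_1"]]$mat
  expect_equal(dim(m), c(300L, 60L))
  # UP genes: upstream/downstream density ratio >= 4 in >= 95% of genes
  ratio <- rowMeans(m[1:100, 1:30]) / rowMeans(m[1:100, 31:60])
  expect_gte(mean(ratio >= 4), 0.95)
  # TSS genes: central dip at background, flanks enriched
  dip <- rowMeans(m[101:200, 30:31])
  flank <- rowMeans(m[101:200, c(1:29, 32:60)])
  expect_gt(mean(flank) / mean(dip), 4)
  # origin samples carry no planted signal
  expect_lt(mean(ch$samples[["origin_1"]]$mat), 1.5 * d$chip_background)
  # mirror image of an UP gene classifies as DOWN
  pr <- ch$samples[["tumour_1"]]
  expect_equal(unname(classify_pattern(pr, genes = "g0001")), "UP")
  expect_equal(unname(classify_pattern(flip_profile(pr), genes = "g0001")),
               "DOWN")
})

test_that("survival generator honours censoring and hazards", {
  expect_error(simulate_survival(c(A = 0), c(A = 1)), "empty group")
  expect_error(simulate_survival(c(A = 5), c(A = -1)), "positive")
  expect_error(simulate_survival(c(A = 5), c(A = 1), censoring_rate = 1),
               "censoring_rate")
  tbl <- simulate_survival(c(A = 4), c(A = 0.1), censoring_rate = 0,
                           seed = 2)
  km <- km_estimator(tbl)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  # censoring fraction approximates the requested rate
  tbl2 <- simulate_survival(c(A = 2000), c(A = 0.2), censoring_rate = 0.3,
                            seed = 3)
  expect_lt(abs(mean(tbl2$event == 0) - 0.3), 0.05)
  # expression levels reproduce the intended strata
  tbl3 <- simulate_survival(c(HIGH = 20, MID = 60, LOW = 20),
                            c(HIGH = 0.1, MID = 0.2, LOW = 0.4), seed = 4)
  strata <- stratify_by_expression(tbl3)
  expect_equal(as.character(strata), tbl3$group)
})

test_that("planted master-regulator bundle has the advertised structure", {
  d <- simulation_design(n_genes = 300, n_motifs = 10, seed = 21)
  b <- plant_master_regulator(d, n_deg = 40, n_denovo = 20, n_stable = 10)
  expect_s3_class(b$counts, "count_matrix")
  expect_equal(b$truth$master_tf, "g0001")
  expect_true(b$truth$master_tf %in% b$truth$down)
  expect_true(b$truth$master_tf %in% b$truth$denovo)
  expect_true(all(b$truth$denovo %in% b$truth$down))
  expect_length(b$pwms, 10)
  expect_equal(nrow(b$tf_map), 10)
  # master chip class: marked in tumour, not in origin
  expect_equal(unname(b$chip$classes[b$truth$master_tf, ]),
               c("NONE", "TSS"))
  expect_error(
    plant_master_regulator(simulation_design(n_genes = 50, seed = 1,
                                             master_tf = "nope")),
    "master_tf"
  )
  b2 <- plant_master_regulator(d, n_deg = 40, n_denovo = 20, n_stable = 10)
  expect_identical(b$genome, b2$genome)
  expect_identical(b$counts, b2$counts)
})
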