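#' Simulation design for the synthetic input generator
#'
#' Collects every parameter the generator needs: gene universe size,
#' replicate numbers per condition, planted log2 fold changes, NB
#' dispersion, spatial ChIP enrichment classes per condition, the coverage
#' enrichment factor, planted motif sites, the planted master regulator and
#' the seed that fully determines all outputs.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_per_group Named integer vector of replicates per condition
#'   (default `c(origin = 3, tumour = 3)`).
#' @param promoter_len Promoter length in bp.
#' @param deg_lfc Named numeric vector: planted log2 fold changes
#'   (tumour vs origin) per gene id; unnamed genes are null.
#' @param dispersion NB dispersion (scalar or per-gene).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression means.
#' @param baseline_override Named numeric vector fixing the baseline mean
#'   of specific genes (used for the planted regulator, which as an
#'   expressed TF must not draw a near-zero baseline).
#' @param chip_class Named list per condition of named character vectors
#'   with values in `NONE`, `TSS`, `UP`, `DOWN`; unnamed genes are `NONE`.
#' @param enrichment_factor Coverage multiplier in marked bins (> 1).
#' @param chip_background Poisson background rate per bin (reads/bin).
#' @param window_half,bin_size Window geometry in bp.
#' @param base_comp Promoter background base composition (A, C, G, T).
#' @param master_tf Gene id of the planted master regulator, or `NULL`.
#' @param n_motifs Number of PWMs generated by [plant_master_regulator()].
#' @param motif_length Length of the generated PWMs.
#' @param seed Integer seed; identical designs give byte-identical outputs.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 1000,
                              n_per_group = c(origin = 3, tumour = 3),
                              promoter_len = 500,
                              deg_lfc = numeric(0),
                              dispersion = 0.05,
                              baseline_meanlog = log(100),
                              baseline_sdlog = 1,
                              baseline_override = numeric(0),
                              chip_class = list(),
                              enrichment_factor = 8,
                              chip_background = 10,
                              window_half = 3000, bin_size = 100,
                              base_comp = rep(0.25, 4),
                              master_tf = NULL,
                              n_motifs = 50, motif_length = 8,
                              seed = 1) {
  if (n_genes < 1) stop("configuration error: n_genes must be >= 1")
  if (is.null(names(n_per_group)) || length(n_per_group) < 1) {
    stop("n_per_group must be a named vector of conditions")
  }
  if (any(dispersion < 0)) stop("dispersion must be non-negative")
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (length(deg_lfc) && any(!is.finite(deg_lfc))) {
    stop("planted log2 fold changes must be finite")
  }
  if ((2 * window_half) %% bin_size != 0) {
    stop("bin size must divide the window")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_per_group = n_per_group,
    promoter_len = as.integer(promoter_len), deg_lfc = deg_lfc,
    dispersion = dispersion, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    baseline_override = baseline_override, chip_class = chip_class,
    enrichment_factor = enrichment_factor,
    chip_background = chip_background, window_half = window_half,
    bin_size = bin_size, base_comp = base_comp / sum(base_comp),
    master_tf = master_tf, n_motifs = as.integer(n_motifs),
    motif_length = as.integer(motif_length), seed = as.integer(seed)
  ), class = "simulation_design")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate the gene annotation and promoter sequences
#'
#' Genes are laid out on one synthetic chromosome with non-overlapping
#' TSS-centred windows; promoter sequences are drawn i.i.d. from the design's
#' base composition (uniform ACGT by default).
#'
#' @param design A [simulation_design()].
#' @return An object of class `genome_bundle`: `genes` (data.frame with
#'   `gene_id`, `chrom`, `tss`, `strand`) and `promoters` (named character
#'   vector).
#' @export
simulate_genome <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  n <- design$n_genes
  ids <- gene_ids(n)
  spacing <- 2 * design$window_half + 2000
  with_seed(sub_seed(design$seed, 1), {
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss <- 10000 + spacing * (seq_len(n) - 1L)
    prom <- vapply(seq_len(n), function(i) {
      paste0(sample(DNA_BASES, design$promoter_len, replace = TRUE,
                    prob = design$base_comp), collapse = "")
    }, character(1))
  })
  names(prom) <- ids
  structure(list(
    genes = data.frame(gene_id = ids, chrom = "chrS", tss = tss,
                       strand = strand, stringsAsFactors = FALSE),
    promoters = prom
  ), class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("genome_bundle: %d genes, %d bp promoters\n",
              nrow(x$genes), unique(nchar(x$promoters))))
  invisible(x)
}

#' Plant motif occurrences into target promoters
#'
#' For each target gene, samples `sites_per_promoter` sites from the PWM's
#' per-position base distributions and writes them at non-overlapping
#' offsets of the promoter. Non-target promoters are untouched.
#'
#' @param bundle A `genome_bundle`.
#' @param pwm A [pwm()] object.
#' @param targets Character vector of gene ids (subset of the bundle).
#' @param sites_per_promoter Number of sites per target promoter.
#' @param seed Integer seed.
#' @return The modified `genome_bundle`.
#' @export
plant_motifs <- function(bundle, pwm, targets, sites_per_promoter = 1,
                         seed = 1) {
  stopifnot(inherits(bundle, "genome_bundle"), inherits(pwm, "pwm"))
  bad <- setdiff(targets, bundle$genes$gene_id)
  if (length(bad)) stop("target gene(s) not in bundle: ",
                        paste(utils::head(bad, 3), collapse = ", "))
  if (sites_per_promoter == 0) return(bundle)
  L <- pwm_length(pwm)
  plen <- unique(nchar(bundle$promoters))
  if (sites_per_promoter * L > plen) {
    stop("cannot fit ", sites_per_promoter, " non-overlapping sites of ",
         L, " bp in a ", plen, " bp promoter")
  }
  # sites are sampled from the raw count-derived base distribution so that
  # a consensus-only PWM always plants its consensus string
  site_prob <- sweep(pwm$counts, 2, colSums(pwm$counts), "/")
  with_seed(seed, {
    for (g in targets) {
      s <- strsplit(bundle$promoters[[g]], "")[[1]]
      taken <- rep(FALSE, plen)
      placed <- 0
      while (placed < sites_per_promoter) {
        free <- which(!vapply(seq_len(plen - L + 1), function(o) {
          any(taken[o:(o + L - 1)])
        }, logical(1)))
        if (!length(free)) stop("could not place non-overlapping sites")
        o <- if (length(free) == 1) free else sample(free, 1)
        site <- vapply(seq_len(L), function(j) {
          sample(DNA_BASES, 1, prob = site_prob[, j])
        }, character(1))
        s[o:(o + L - 1)] <- site
        taken[o:(o + L - 1)] <- TRUE
        placed <- placed + 1
      }
      bundle$promoters[[g]] <- paste0(s, collapse = "")
    }
  })
  bundle
}

#' Simulate a raw count matrix with planted fold changes
#'
#' Counts are negative binomial with mean
#' `baseline * 2^(lfc * [condition is tumour])` and the design's dispersion;
#' per-gene baselines are log-normal. With dispersion 0 counts are Poisson.
#'
#' @param design A [simulation_design()] with >= 2 conditions, >= 2
#'   replicates each. The last-named condition is the "tumour" side for the
#'   planted fold changes.
#' @param sample_scale Optional named per-sample library scaling factors.
#' @return A [count_matrix()].
#' @export
simulate_counts <- function(design, sample_scale = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  npg <- design$n_per_group
  if (length(npg) < 2 || any(npg < 2)) {
    stop("need >= 2 conditions with >= 2 replicates each")
  }
  n <- design$n_genes
  ids <- gene_ids(n)
  conds <- names(npg)
  tumour <- conds[length(conds)]
  groups <- rep(conds, npg)
  sample_ids <- unlist(lapply(conds, function(g) {
    sprintf("%s_%d", g, seq_len(npg[[g]]))
  }))
  lfc <- stats::setNames(rep(0, n), ids)
  if (length(design$deg_lfc)) {
    lfc[intersect(names(design$deg_lfc), ids)] <-
      design$deg_lfc[intersect(names(design$deg_lfc), ids)]
  }
  disp <- rep(design$dispersion, length.out = n)
  scl <- rep(1, length(sample_ids))
  names(scl) <- sample_ids
  if (!is.null(sample_scale)) scl[names(sample_scale)] <- sample_scale
  with_seed(sub_seed(design$seed, 4), {
    base <- stats::rlnorm(n, design$baseline_meanlog, design$baseline_sdlog)
    names(base) <- ids
    ov <- design$baseline_override
    if (length(ov)) base[intersect(names(ov), ids)] <-
      ov[intersect(names(ov), ids)]
    counts <- matrix(0L, n, length(sample_ids),
                     dimnames = list(ids, sample_ids))
    for (j in seq_along(sample_ids)) {
      mu <- base * 2^(lfc * (groups[j] == tumour)) * scl[j]
      counts[, j] <- if (all(disp == 0)) {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, mu = mu, size = 1 / pmax(disp, 1e-12))
      }
    }
  })
  count_matrix(counts, stats::setNames(groups, sample_ids))
}

# Expected per-bin Poisson rates for one gene given its spatial class.
chip_class_rates <- function(class, nb, lambda, factor) {
  r <- rep(lambda, nb)
  half <- nb / 2
  dip <- c(half, half + 1)
  switch(class,
    NONE = r,
    UP = { r[seq_len(half)] <- lambda * factor; r },
    DOWN = { r[(half + 1):nb] <- lambda * factor; r },
    TSS = { r[] <- lambda * factor; r[dip] <- lambda; r },
    stop("unknown chip class: ", class)
  )
}

#' Simulate TSS-window ChIP profiles
#'
#' Per condition and replicate, per-gene per-bin tag counts are independent
#' Poisson draws: background rate everywhere except the bins dictated by the
#' gene's spatial class (`UP`: upstream flank, `DOWN`: downstream flank,
#' `TSS`: both flanks enriched with the central bins held at background —
#' the dip at the TSS itself). The control track is pure background.
#'
#' @param design A [simulation_design()]; `design$chip_class` maps
#'   condition -> named vector of classes.
#' @return List with `samples` (named list of [chip_profile()], one per
#'   condition replicate), `control` (a [chip_profile()]), and `classes`
#'   (the class matrix used).
#' @export
simulate_chip <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  n <- design$n_genes
  ids <- gene_ids(n)
  nb <- as.integer(2 * design$window_half / design$bin_size)
  conds <- names(design$n_per_group)
  class_mat <- matrix("NONE", n, length(conds),
                      dimnames = list(ids, conds))
  for (g in conds) {
    spec <- design$chip_class[[g]]
    if (!is.null(spec)) {
      class_mat[intersect(names(spec), ids), g] <-
        spec[intersect(names(spec), ids)]
    }
  }
  lam <- design$chip_background
  fac <- design$enrichment_factor
  samples <- list()
  with_seed(sub_seed(design$seed, 5), {
    for (g in conds) {
      rates <- t(vapply(class_mat[, g], chip_class_rates, numeric(nb),
                        nb = nb, lambda = lam, factor = fac))
      for (r in seq_len(design$n_per_group[[g]])) {
        nm <- sprintf("%s_%d", g, r)
        m <- matrix(stats::rpois(n * nb, as.vector(rates)), n, nb,
                    dimnames = list(ids, NULL))
        samples[[nm]] <- chip_profile(m, design$window_half,
                                      design$bin_size, sample = nm)
      }
    }
    ctrl <- matrix(stats::rpois(n * nb, lam), n, nb,
                   dimnames = list(ids, NULL))
  })
  list(samples = samples,
       control = chip_profile(ctrl, design$window_half, design$bin_size,
                              sample = "control"),
       classes = class_mat)
}

#' Simulate a survival cohort with group-specific hazards
#'
#' Event times are exponential with the group's hazard; censoring times are
#' independent uniform on `[0, b]` with `b` chosen numerically so the
#' expected censoring fraction matches `censoring_rate`. Expression values
#' are drawn around group-specific levels so that
#' [stratify_by_expression()] reproduces the intended groups.
#'
#' @param n_per_group Named integer vector of patients per group.
#' @param hazards Named numeric vector of hazard rates (> 0), same names.
#' @param censoring_rate Expected censored fraction in `[0, 1)`.
#' @param expr_levels Named numeric vector of expression levels per group
#'   (defaults: `HIGH` 4, `LOW` 0.2, others 1).
#' @param seed Integer seed.
#' @return A data.frame (class `survival_table`): `patient_id`, `time`,
#'   `event`, `expr`, `group`.
#' @export
simulate_survival <- function(n_per_group, hazards, censoring_rate = 0,
                              expr_levels = NULL, seed = 1) {
  if (any(n_per_group < 1)) stop("empty group")
  if (!setequal(names(n_per_group), names(hazards))) {
    stop("n_per_group and hazards must name the same groups")
  }
  if (any(hazards <= 0)) stop("hazards must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0, 1)")
  }
  groups <- rep(names(n_per_group), n_per_group)
  ntot <- length(groups)
  lev <- stats::setNames(rep(1, length(n_per_group)), names(n_per_group))
  lev[names(lev) == "HIGH"] <- 4
  lev[names(lev) == "LOW"] <- 0.2
  if (!is.null(expr_levels)) lev[names(expr_levels)] <- expr_levels
  with_seed(seed, {
    t_event <- stats::rexp(ntot, rate = hazards[groups])
    if (censoring_rate > 0) {
      lam_mean <- mean(hazards[groups])
      b <- stats::uniroot(function(b) {
        (1 - exp(-lam_mean * b)) / (lam_mean * b) - censoring_rate
      }, c(1e-8, 1e8))$root
      cens <- stats::runif(ntot, 0, b)
    } else {
      cens <- rep(Inf, ntot)
    }
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
    expr <- lev[groups] * exp(stats::rnorm(ntot, 0, 0.1))
  })
  res <- data.frame(patient_id = sprintf("p%04d", seq_len(ntot)),
                    time = time, event = event, expr = as.numeric(expr),
                    group = groups, stringsAsFactors = FALSE)
  class(res) <- c("survival_table", "data.frame")
  res
}

# Random information-rich PWM: one dominant base per column.
random_pwm <- function(id, length = 8, dominant_weight = 0.85, seed = 1,
                       name = id) {
  with_seed(seed, {
    dom <- sample(4, length, replace = TRUE)
  })
  counts <- matrix((1 - dominant_weight) / 3 * 100, 4, length)
  counts[cbind(dom, seq_len(length))] <- dominant_weight * 100
  rownames(counts) <- DNA_BASES
  pwm(counts, id = id, name = name)
}

#' Generate the full planted-master-regulator input bundle
#'
#' Builds every input the integrative pipeline consumes, with a known
#' ground truth: a genome with promoters, a PWM collection with one motif
#' per candidate TF, planted down- and upregulated DEGs, the planted
#' regulator's motif written into the majority of downregulated-DEG
#' promoters, de novo H3K27me3 marking (tumour-only) on a subset of the
#' downregulated genes including the regulator's own gene, and stable
#' (both-condition) marks on unrelated genes. With `master_tf = NULL`
#' (a null bundle) no motif is planted and the regulator gene keeps null
#' expression and no mark.
#'
#' @param design A [simulation_design()]; `design$master_tf` defaults to the
#'   first gene when the argument `null_bundle` is `FALSE`.
#' @param n_deg Number of planted DEGs per direction.
#' @param deg_lfc Absolute planted log2 fold change.
#' @param frac_motif Fraction of downregulated-DEG promoters receiving the
#'   planted motif.
#' @param n_denovo Number of downregulated genes given tumour-only marks.
#' @param n_stable Number of genes marked in both conditions.
#' @param sites_per_promoter Planted sites per target promoter.
#' @param null_bundle If `TRUE`, generate the same universe with no planted
#'   effects at all.
#' @return List (class `regulator_bundle`) with `genome`, `pwms`, `tf_map`,
#'   `counts`, `chip`, `design`, and `truth` (planted gene sets).
#' @export
plant_master_regulator <- function(design, n_deg = 100, deg_lfc = 2,
                                   frac_motif = 0.7, n_denovo = 60,
                                   n_stable = 40, sites_per_promoter = 2,
                                   null_bundle = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  n <- design$n_genes
  ids <- gene_ids(n)
  master <- design$master_tf %||% ids[1]
  if (!master %in% ids) stop("master_tf not in gene list: ", master)
  conds <- names(design$n_per_group)
  tumour <- conds[length(conds)]
  origin <- conds[1]

  # candidate TF universe: one PWM per TF gene (master = first)
  tf_genes <- c(master, setdiff(ids, master)[seq_len(design$n_motifs - 1)])
  pwms <- lapply(seq_along(tf_genes), function(i) {
    random_pwm(id = sprintf("PWM_%s", tf_genes[i]),
               name = sprintf("TF_%s", tf_genes[i]),
               length = design$motif_length,
               seed = sub_seed(design$seed, 100 + i))
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")
  tf_map <- data.frame(pwm_id = names(pwms), gene_id = tf_genes,
                       stringsAsFactors = FALSE)

  genome <- simulate_genome(design)

  if (null_bundle) {
    truth <- list(master_tf = NULL, down = character(0), up = character(0),
                  denovo = character(0), stable = character(0))
    counts <- simulate_counts(design)
    chip <- simulate_chip(design)
  } else {
    with_seed(sub_seed(design$seed, 2), {
      pool <- setdiff(ids, master)
      down <- c(master, sample(pool, n_deg - 1))
      up <- sample(setdiff(pool, down), n_deg)
      denovo <- c(master, sample(setdiff(down, master),
                                 min(n_denovo - 1, n_deg - 1)))
      stable <- sample(setdiff(ids, c(down, up)), n_stable)
      motif_targets <- c(master,
                         sample(setdiff(down, master),
                                ceiling(frac_motif * n_deg) - 1))
    })
    lfc <- c(stats::setNames(rep(-deg_lfc, length(down)), down),
             stats::setNames(rep(deg_lfc, length(up)), up))
    design$deg_lfc <- lfc
    # the planted regulator is an expressed TF in the origin cells: give
    # it a defined baseline (+1 sd above the typical gene) so its
    # repression is observable rather than lost in a low-count draw
    design$baseline_override <- c(
      design$baseline_override,
      stats::setNames(exp(design$baseline_meanlog + design$baseline_sdlog),
                      master))
    design$chip_class <- list()
    design$chip_class[[origin]] <-
      stats::setNames(rep("TSS", length(stable)), stable)
    design$chip_class[[tumour]] <-
      c(stats::setNames(rep("TSS", length(denovo)), denovo),
        stats::setNames(rep("TSS", length(stable)), stable))
    genome <- plant_motifs(genome, pwms[[1]], motif_targets,
                           sites_per_promoter = sites_per_promoter,
                           seed = sub_seed(design$seed, 3))
    truth <- list(master_tf = master, down = sort(down), up = sort(up),
                  denovo = sort(denovo), stable = sort(stable),
                  motif_targets = sort(motif_targets))
    counts <- simulate_counts(design)
    chip <- simulate_chip(design)
  }
  structure(list(genome = genome, pwms = pwms, tf_map = tf_map,
                 counts = counts, chip = chip, design = design,
                 truth = truth),
            class = "regulator_bundle")
}
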