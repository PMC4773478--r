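# Run configuration and the end-to-end pipeline: simulate (or load) ->
# differential expression -> ChIP target calling and de novo logic ->
# promoter motif enrichment -> master-regulator ranking, with a
# machine-readable manifest of every stage.

config_keys <- c(
  "seed", "outdir", "alpha", "fdr", "lfc_min", "pattern_lfc_threshold",
  "min_abs_r", "n_perm", "n_shuffles", "high_fc", "low_fc",
  "simulate", "inputs"
)
simulate_keys <- c(
  "n_genes", "n_per_group", "promoter_len", "dispersion",
  "enrichment_factor", "chip_background", "window_half", "bin_size",
  "n_motifs", "motif_length", "planted", "n_deg", "deg_lfc", "frac_motif",
  "n_denovo", "n_stable", "sites_per_promoter"
)
input_keys <- c(
  "counts", "groups", "annotation", "promoters", "pwms", "tf_map",
  "signal_tracks", "control_track", "origin_group", "tumour_group"
)

#' Read and validate a run configuration (YAML)
#'
#' Plain YAML with a flat top level (thresholds, seed, outdir) plus a
#' `simulate:` block (synthetic mode) or an `inputs:` block (file mode).
#' Unknown keys are rejected.
#'
#' @param path YAML file path, or an already-parsed list.
#' @return Validated configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(cfg$simulate)) {
    unknown <- setdiff(names(cfg$simulate), simulate_keys)
    if (length(unknown)) stop("unknown simulate key(s): ",
                              paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$inputs)) {
    unknown <- setdiff(names(cfg$inputs), input_keys)
    if (length(unknown)) stop("unknown inputs key(s): ",
                              paste(unknown, collapse = ", "))
  }
  defaults <- list(seed = 1, alpha = 0.05, fdr = 0.05, lfc_min = 0,
                   pattern_lfc_threshold = 1)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  structure(cfg, class = c("run_config", "list"))
}

#' Write a run configuration as YAML
#' @param cfg A configuration list.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

design_from_config <- function(cfg) {
  s <- cfg$simulate %||% list()
  npg <- s$n_per_group %||% list(origin = 3, tumour = 3)
  simulation_design(
    n_genes = s$n_genes %||% 1000,
    n_per_group = unlist(npg),
    promoter_len = s$promoter_len %||% 500,
    dispersion = s$dispersion %||% 0.05,
    enrichment_factor = s$enrichment_factor %||% 8,
    chip_background = s$chip_background %||% 10,
    window_half = s$window_half %||% 3000,
    bin_size = s$bin_size %||% 100,
    n_motifs = s$n_motifs %||% 50,
    motif_length = s$motif_length %||% 8,
    seed = cfg$seed
  )
}

bundle_from_config <- function(cfg) {
  s <- cfg$simulate %||% list()
  design <- design_from_config(cfg)
  plant_master_regulator(
    design,
    n_deg = s$n_deg %||% 100,
    deg_lfc = s$deg_lfc %||% 2,
    frac_motif = s$frac_motif %||% 0.7,
    n_denovo = s$n_denovo %||% 60,
    n_stable = s$n_stable %||% 40,
    sites_per_promoter = s$sites_per_promoter %||% 2,
    null_bundle = !(s$planted %||% TRUE)
  )
}

load_bundle_files <- function(inp) {
  annotation <- read_annotation_bed(inp$annotation)
  promoters <- read_promoters_fasta(inp$promoters)
  pwms <- read_jaspar(inp$pwms)
  tf_map <- utils::read.delim(inp$tf_map, stringsAsFactors = FALSE)
  counts <- read_counts_tsv(inp$counts, inp$groups)
  samples <- lapply(names(inp$signal_tracks), function(nm) {
    tss_profile(inp$signal_tracks[[nm]], annotation, sample = nm)
  })
  names(samples) <- names(inp$signal_tracks)
  control <- tss_profile(inp$control_track, annotation,
                         sample = "control")
  list(genome = list(genes = annotation, promoters = promoters),
       pwms = pwms, tf_map = tf_map, counts = counts,
       chip = list(samples = samples, control = control),
       truth = NULL)
}

#' Run the integrative master-regulator pipeline
#'
#' Chains the stages in dependency order: (1) differential expression of
#' tumour vs origin; (2) per-sample ChIP target calling against the control
#' track; (3) de novo target extraction (marked in every tumour sample, no
#' origin sample) and spatial pattern classification; (4) promoter motif
#' enrichment of the DEGs; (5) intersection of downregulated DEGs with de
#' novo targets; (6) master-regulator ranking and shortlisting. Writes each
#' stage's table to `outdir` and records file MD5 hashes in a JSON
#' manifest; re-running an identical configuration reproduces identical
#' hashes.
#'
#' @param config A [read_run_config()] result, a path to a YAML config, or
#'   a plain list.
#' @param outdir Output directory (overrides the config's `outdir`).
#' @return List with `deg`, `calls`, `denovo`, `patterns`, `enrichment`,
#'   `core`, `regulators`, `shortlist`, `truth` (synthetic mode only) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- read_run_config(config)
  outdir <- outdir %||% cfg$outdir %||% tempfile("epimr_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  message("run_pipeline: alpha=", cfg$alpha, " fdr=", cfg$fdr,
          " lfc_min=", cfg$lfc_min,
          " pattern_lfc_threshold=", cfg$pattern_lfc_threshold,
          " seed=", cfg$seed)

  if (!is.null(cfg$inputs)) {
    bundle <- load_bundle_files(cfg$inputs)
    origin <- cfg$inputs$origin_group %||% "origin"
    tumour <- cfg$inputs$tumour_group %||% "tumour"
  } else {
    bundle <- bundle_from_config(cfg)
    conds <- names(bundle$design$n_per_group)
    origin <- conds[1]
    tumour <- conds[length(conds)]
  }
  sample_groups <- sub("_[0-9]+$", "", names(bundle$chip$samples))

  deg <- call_degs(bundle$counts, origin, tumour, alpha = cfg$alpha,
                   lfc_min = cfg$lfc_min)
  calls <- lapply(bundle$chip$samples, call_targets,
                  control = bundle$chip$control, fdr = cfg$fdr)
  denovo <- de_novo_targets(calls[sample_groups == origin],
                            calls[sample_groups == tumour])
  tum_mats <- lapply(bundle$chip$samples[sample_groups == tumour],
                     function(p) p$mat)
  mean_tum <- Reduce(`+`, tum_mats) / length(tum_mats)
  tum_profile <- chip_profile(mean_tum,
                              bundle$chip$control$window_half,
                              bundle$chip$control$bin_size,
                              sample = "tumour_mean")
  patterns <- if (length(denovo)) {
    classify_pattern(tum_profile, genes = denovo,
                     lfc_threshold = cfg$pattern_lfc_threshold)
  } else character(0)

  fg <- deg$gene_id[deg$direction != "NS"]
  enrichment <- if (length(fg)) {
    motif_enrichment(fg, bundle$genome$promoters, bundle$pwms)
  } else {
    structure(data.frame(pwm_id = character(), name = character(),
                         fg_mean = numeric(), bg_mean = numeric(),
                         bg_sd = numeric(), z = numeric(), p = numeric(),
                         n_fg = integer(), n_bg = integer(),
                         p_bonferroni = numeric()),
              class = c("motif_enrichment", "data.frame"))
  }
  core <- intersect_down_denovo(deg, denovo)
  regulators <- rank_master_regulators(enrichment, deg, denovo,
                                       bundle$tf_map, alpha = cfg$alpha)

  files <- c(deg = "deg.tsv", calls = "target_calls.tsv",
             denovo = "denovo_targets.txt", patterns = "patterns.tsv",
             enrichment = "motif_enrichment.tsv", core = "core_set.tsv",
             regulators = "regulators.tsv")
  files <- stats::setNames(file.path(outdir, files), names(files))
  wt <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(deg, files["deg"])
  wt(do.call(rbind, calls), files["calls"])
  write_gene_list(denovo, files["denovo"])
  wt(data.frame(gene_id = names(patterns), pattern = unname(patterns)),
     files["patterns"])
  wt(enrichment, files["enrichment"])
  wt(core, files["core"])
  wt(regulators, files["regulators"])

  manifest <- list(
    config = unclass(cfg),
    stages = lapply(names(files), function(nm) {
      list(stage = nm, file = basename(files[[nm]]),
           md5 = unname(tools::md5sum(files[[nm]])))
    }),
    shortlist = regulators$gene_id[regulators$shortlisted]
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  list(deg = deg, calls = calls, denovo = denovo, patterns = patterns,
       enrichment = enrichment, core = core, regulators = regulators,
       shortlist = regulators$gene_id[regulators$shortlisted],
       truth = bundle$truth, manifest = manifest,
       manifest_path = manifest_path, outdir = outdir)
}
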