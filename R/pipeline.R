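#' Default pipeline configuration
#'
#' The named parameter profile of the analysis: FDR 0.05, fold gate
#' 1.5, equivalence margin 0.3, outlier threshold r^2 0.8, minimum 2
#' quantifying peptides, cluster cut height 100 with minimum size 20,
#' and translation-model rates k_deg 0.1 per hour, k_syn 4. The
#' `simspec` block parameterizes the synthetic inputs of the demo run.
#'
#' @param seed Integer seed used for every stochastic step.
#' @return A nested list of configuration values.
#' @export
default_config <- function(seed = 1L) {
  list(
    profile = "diel-defaults",
    seed = as.integer(seed),
    thresholds = list(fdr = 0.05, fold = 1.5, tost_epsilon = 0.3,
                      outlier_r2 = 0.8, min_peptides = 2,
                      cut_height = 100, min_cluster_size = 20),
    translation = list(k_deg = 0.1, k_syn = 4, photoperiod = 12,
                       settle = 240, phi_step = 0.1),
    turnover = list(efficiency_offset = 0.01,
                    da_from_zt = 24, da_to_zt = 96),
    simspec = list(n_proteins = 200, n_motifs = 300, frac_rhythmic = 0.5,
                   fold = 3, cv = 0.1, loading_spread = 0.05,
                   n_labeled = 40, label_cv = 0.05)
  )
}

read_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config(seed = if (!is.null(config$seed)) config$seed else 1L)
  modifyList(base, config)
}

#' Run the full pipeline on synthetic data
#'
#' End-to-end demonstration run: generates a synthetic diel study
#' (motif table, technical variants, protein table, labelling courses,
#' dark-adaptation series), then executes merging, preprocessing and
#' outlier removal, rhythm and equivalence statistics, pattern
#' analyses, the translation-model simulation, turnover fitting and
#' motif enrichment, writing each stage's outputs under `out_dir`
#' (`qc/`, `merge/`, `rhythm/`, `patterns/`, `translation/`,
#' `turnover/`, `motifs/`) plus a run manifest with the configuration
#' hash and seed, enabling identical re-runs.
#'
#' @param config `NULL` for defaults, a YAML file path, or a list
#'   overriding parts of [default_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the principal in-memory results.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("dielprot_run_")) {
  cfg <- read_config(config)
  th <- cfg$thresholds
  dirs <- file.path(out_dir, c("qc", "merge", "rhythm", "patterns",
                               "translation", "turnover", "motifs"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed

  # --- synthetic study ---------------------------------------------------
  ss <- cfg$simspec
  prot_sim <- generate_ld_dataset(sim_spec(
    n_features = ss$n_proteins, frac_rhythmic = ss$frac_rhythmic,
    fold = ss$fold, cv = ss$cv, loading_spread = ss$loading_spread,
    seed = seed))
  motif_sim <- generate_ld_dataset(sim_spec(
    n_features = ss$n_motifs, frac_rhythmic = ss$frac_rhythmic,
    fold = ss$fold, cv = ss$cv, loading_spread = ss$loading_spread,
    n_loci = ss$n_proteins, seed = seed + 1L))
  motif_sim$table$features$locus <- prot_sim$truth$locus[
    match(motif_sim$truth$locus, prot_sim$truth$locus)]
  var_sim <- generate_phospho_variants(motif_sim$table, ambiguous_frac = 0.1,
                                       seed = seed + 2L)

  # --- merge -------------------------------------------------------------
  resolved <- resolve_ambiguous_sites(var_sim$variants, var_sim$predictions)
  merged <- merge_variants(resolved)
  write_quant_table(merged$motifs, file.path(out_dir, "merge", "motifs.tsv"))
  jsonlite::write_json(merged$report[c("n_in", "n_motifs",
                                       "n_ambiguous_resolved", "n_discarded")],
                       file.path(out_dir, "merge", "merge_report.json"),
                       auto_unbox = TRUE)

  # --- preprocess + QC ---------------------------------------------------
  outlier_key <- format_sample_keys("LD", 16, "E")
  motif_out <- inject_outlier_replicate(merged$motifs, outlier_key,
                                        severity = 1, seed = seed + 3L)
  norm_motif <- mean_normalize(motif_out)
  flags <- detect_outlier_replicates(arcsinh_transform(norm_motif),
                                     r2_threshold = th$outlier_r2)
  norm_motif <- remove_outlier_replicates(norm_motif, flags)
  norm_prot <- mean_normalize(prot_sim$table)
  qc <- list(scale_factors = as.list(attr(norm_prot, "scale_factors")),
             flagged_replicates = flags$key[flags$flagged])
  jsonlite::write_json(qc, file.path(out_dir, "qc", "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  write_results(flags, file.path(out_dir, "qc", "replicate_correlations.tsv"))

  # --- rhythm + equivalence ---------------------------------------------
  rhythm_prot <- rhythm_analysis(norm_prot, fdr = th$fdr,
                                 fold_threshold = th$fold)
  rhythm_motif <- rhythm_analysis(norm_motif, fdr = th$fdr,
                                  fold_threshold = th$fold)
  equiv_prot <- tost_equivalence(arcsinh_transform(norm_prot),
                                 eps = th$tost_epsilon)
  write_results(rhythm_prot, file.path(out_dir, "rhythm", "proteins.tsv"))
  write_results(rhythm_motif, file.path(out_dir, "rhythm", "motifs.tsv"))
  write_results(equiv_prot, file.path(out_dir, "rhythm",
                                      "protein_equivalence.tsv"))

  # --- patterns ----------------------------------------------------------
  prof <- mean_profiles(norm_prot, condition = "LD")
  pca <- pca_profiles(prof)
  clus <- cluster_profiles(prof, cut_height = th$cut_height,
                           min_cluster_size = th$min_cluster_size,
                           prefix = "P")
  peaks_prot <- if (any(rhythm_prot$rhythmic)) {
    peak_phase_distribution(rhythm_prot)
  } else NULL
  peaks_motif <- if (any(rhythm_motif$rhythmic)) {
    peak_phase_distribution(rhythm_motif)
  } else NULL
  pairing <- pair_protein_phospho(rhythm_prot, rhythm_motif)
  write_results(as.data.frame(pca$scores), file.path(out_dir, "patterns",
                                                     "pca_scores.tsv"))
  write_results(as.data.frame(pca$loadings), file.path(out_dir, "patterns",
                                                       "pca_loadings.tsv"))
  write_results(clus, file.path(out_dir, "patterns", "clusters.tsv"))
  if (!is.null(peaks_prot)) {
    write_results(peaks_prot, file.path(out_dir, "patterns",
                                        "peak_distribution_proteins.tsv"))
  }
  if (!is.null(peaks_motif)) {
    write_results(peaks_motif, file.path(out_dir, "patterns",
                                         "peak_distribution_motifs.tsv"))
  }
  write_results(pairing, file.path(out_dir, "patterns", "pairing.tsv"))

  # --- translation model -------------------------------------------------
  tp <- translation_params(k_deg = cfg$translation$k_deg,
                           k_syn = cfg$translation$k_syn,
                           photoperiod = cfg$translation$photoperiod,
                           settle = cfg$translation$settle,
                           phi_step = cfg$translation$phi_step)
  sim <- peak_time_distribution(tp)
  write_results(sim$per_phi, file.path(out_dir, "translation",
                                       "per_phi_peaks.tsv"))
  jsonlite::write_json(list(histogram = sim$histogram,
                            daytime_fraction = sim$daytime_fraction),
                       file.path(out_dir, "translation", "histogram.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  # --- turnover ----------------------------------------------------------
  k_true <- withr::with_seed(seed + 4L,
    stats::setNames(stats::rlnorm(ss$n_labeled, log(0.01), 0.5),
                    sprintf("p%03d", seq_len(ss$n_labeled))))
  courses <- generate_labeling_course(k_true, efficiency = 0.93,
                                      times = c(0, 6, 12, 24, 48, 72),
                                      cv = ss$label_cv, seed = seed + 5L)
  fits <- fit_degradation_all(courses)
  da <- generate_da_dataset(k_true, cv = ss$cv, seed = seed + 6L)
  folds <- classify_da_change(da_fold_change(mean_normalize(da),
                                             from_zt = cfg$turnover$da_from_zt,
                                             to_zt = cfg$turnover$da_to_zt))
  corr <- correlate_kdeg_fold(fits, folds)
  write_results(fits, file.path(out_dir, "turnover", "degradation_fits.tsv"))
  write_results(folds, file.path(out_dir, "turnover", "da_folds.tsv"))
  jsonlite::write_json(list(full = corr$full, excluded = corr$excluded,
                            exclusions = corr$exclusions),
                       file.path(out_dir, "turnover", "correlation.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- motif enrichment --------------------------------------------------
  seqgen <- generate_protein_sequences(ss$n_proteins, plant_sp = 0.3,
                                       seed = seed + 7L)
  site_tab <- seqgen$sites
  # attach each merged motif's first phospho-site to a generated protein
  first_site <- site_tab[!duplicated(site_tab$locus), ]
  mi <- seq_len(nrow(rhythm_motif)) %% nrow(first_site) + 1L
  sites <- data.frame(feature = rhythm_motif$feature,
                      locus = first_site$locus[mi],
                      position = first_site$position[mi],
                      stringsAsFactors = FALSE)
  wins <- extract_windows(sites, seqgen$sequences)
  if (any(rhythm_motif$rhythmic)) {
    logo <- binomial_logo(wins$window[rhythm_motif$rhythmic], wins$window)
    enr <- phase_motif_enrichment(rhythm_motif, wins, wins$window)
    write_results(logo$heights, file.path(out_dir, "motifs", "logo.tsv"))
    write_results(enr, file.path(out_dir, "motifs", "phase_enrichment.tsv"))
  } else {
    logo <- NULL
    enr <- NULL
  }

  # --- manifest ----------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "dielprot",
    version = as.character(utils::packageVersion("dielprot")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    profile = cfg$profile,
    n_proteins = nrow(prot_sim$table$abundance),
    n_motifs = merged$report$n_motifs,
    daytime_fraction = sim$daytime_fraction,
    fraction_differing = attr(pairing, "fraction_differing")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = cfg, out_dir = out_dir,
                 merge = merged, qc = flags,
                 rhythm_protein = rhythm_prot, rhythm_motif = rhythm_motif,
                 equivalence = equiv_prot, pca = pca, clusters = clus,
                 pairing = pairing, translation = sim, turnover = corr,
                 logo = logo, enrichment = enr, manifest = manifest))
}
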