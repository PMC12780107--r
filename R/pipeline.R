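#' Reproducible end-to-end pipeline runs
#'
#' `run_pipeline()` orchestrates the analysis stages — simulate (or load),
#' decontaminate, depth/prevalence filtering, diversity + PERMANOVA, paired
#' differential abundance, survival scan, and power summaries — into a
#' single immutable run directory with a manifest recording the
#' configuration, seed, and an MD5 hash of every output file, so a rerun
#' with the same configuration is byte-identical.
#'
#' @name cli_pipeline
NULL

#' Default pipeline configuration
#'
#' Thresholds default to the study conventions: per-platform minimum
#' sample depth 500 (RNA) / 250 (16S) / 100 (WGS), prevalence filters 1%
#' (pre batch correction) and 5% (pre differential abundance), survival
#' abundance rule 50 reads in 10% of samples for RNA relaxed to 10 reads
#' for 16S/WGS, CLR pseudo-count 0.05, rarefaction draws 100 (alpha) / 50
#' (beta), 999 PERMANOVA permutations.
#'
#' @param platform `"RNA"`, `"16S"`, or `"WGS"`.
#' @param seed master seed.
#' @return a nested list of stage settings.
#' @export
default_run_config <- function(platform = "RNA", seed = 1L) {
  depth_cutoffs <- c(RNA = 500, `16S` = 250, WGS = 100)
  surv_reads <- c(RNA = 50, `16S` = 10, WGS = 10)
  list(
    platform = platform,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, decontam = TRUE, diversity = TRUE,
                  da = TRUE, survival = TRUE, power = TRUE),
    simulate = list(n_subjects = 60, n_genera = 40,
                    contaminants = c("Contam_A", "Contam_B"),
                    contaminant_intensity = c(0, 0.5),
                    tumor_effect = c(g01 = 0.8),
                    survival = list(mu = 1.0, sigma = 1.1,
                                    censor_fraction = 0.4,
                                    log_hr = c(g02 = 0.4))),
    thresholds = list(min_depth = unname(depth_cutoffs[platform]),
                      icc_common_depth = 250,
                      prevalence_batch = 0.01,
                      prevalence_da = 0.05,
                      survival_min_reads = unname(surv_reads[platform]),
                      survival_min_fraction = 0.10,
                      min_genus_reads = if (platform == "RNA") 5 else 2),
    diversity = list(depth = 200, n_alpha_draws = 100, n_beta_draws = 50,
                     n_perm = 999),
    clr_pseudo = 0.05,
    power = list(alpha = 0.01, power_target = 0.80)
  )
}

#' Run the pipeline into a run directory
#'
#' @param config list as from [default_run_config()] (or read from YAML
#'   with [yaml::read_yaml()]).
#' @param out_dir run directory; must not already contain a manifest
#'   (one run = one immutable directory).
#' @param cohort optional pre-built cohort (as from [generate_cohort()]);
#'   otherwise the simulate stage must be enabled.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  if (file.exists(file.path(out_dir, "manifest.json")))
    stop_lowbiome("run directory already contains a manifest: ", out_dir,
                  class = "lowbiome_validation_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ..., "\n",
                            sep = "", file = log_path, append = TRUE)
  stages <- config$stages

  if (is.null(cohort)) {
    if (!isTRUE(stages$simulate))
      stop_lowbiome("no input cohort and simulate stage disabled",
                    class = "lowbiome_validation_error")
    sim <- config$simulate
    cc <- cohort_config(
      n_subjects = sim$n_subjects, platform = config$platform,
      n_genera = sim$n_genera,
      tumor_effect = unlist(sim$tumor_effect) %||% numeric(0),
      contaminants = sim$contaminants %||% character(0),
      contaminant_intensity = sim$contaminant_intensity,
      survival = if (!is.null(sim$survival))
        modifyList(sim$survival, list(log_hr = unlist(sim$survival$log_hr))),
      seed = config$seed)
    cohort <- generate_cohort(cc)
    logf("simulate: ", ncol(cohort$table$counts), " samples, ",
         nrow(cohort$table$counts), " genera")
  }
  write_cohort(cohort, file.path(out_dir, "cohort"))

  tab <- cohort$table
  if (isTRUE(stages$decontam)) {
    policy <- contaminant_policy(
      contaminant_genera = cohort$truth$contaminants %||% character(0),
      min_genus_reads = config$thresholds$min_genus_reads)
    dec <- decontaminate_table(tab, policy)
    tab <- dec$table
    logf("decontam: removed ", length(dec$removal), " genera")
    write_count_table(tab, file.path(out_dir, "counts_decontaminated.tsv"))
  } else {
    logf("decontam: skipped; raw tables propagated")
  }

  tab <- filter_min_depth(tab, config$thresholds$min_depth)
  logf("depth filter: ", ncol(tab$counts), " samples retained at ",
       config$thresholds$min_depth, " reads")

  results <- list()
  if (isTRUE(stages$diversity)) {
    proto <- rarefaction_protocol(config$diversity$depth,
                                  config$diversity$n_alpha_draws,
                                  config$diversity$n_beta_draws,
                                  seed = config$seed)
    keep <- sample_depths(tab) >= proto$depth
    tab_div <- tab; tab_div$counts <- tab$counts[, keep, drop = FALSE]
    alpha <- alpha_diversity(tab_div, proto)
    utils::write.table(alpha, file.path(out_dir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bc <- suppressWarnings(braycurtis_rarefied(tab_div, proto))
    utils::write.table(round(bc, 8), file.path(out_dir, "braycurtis.tsv"),
                       sep = "\t", quote = FALSE)
    perm <- permanova_marginal(bc, cohort$metadata,
                               terms = c("tissue", "batch"),
                               n_perm = config$diversity$n_perm,
                               seed = config$seed)
    utils::write.table(perm, file.path(out_dir, "permanova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$permanova <- perm
    logf("diversity: ", nrow(alpha), " samples")
  }

  if (isTRUE(stages$da)) {
    da_tab <- filter_prevalence(tab, config$thresholds$prevalence_da)
    clr <- clr_transform(da_tab, pseudo_count = config$clr_pseudo)
    md <- cohort$metadata
    tum <- md[md$tissue == "tumor", c("subject_id", "sample_id")]
    nor <- md[md$tissue == "normal", c("subject_id", "sample_id")]
    pairs <- merge(tum, nor, by = "subject_id", suffixes = c("_t", "_n"))
    pairs <- data.frame(tumor = pairs$sample_id_t, normal = pairs$sample_id_n)
    pairs <- pairs[pairs$tumor %in% colnames(clr) &
                     pairs$normal %in% colnames(clr), ]
    da <- paired_da_test(clr, pairs)
    utils::write.table(da, file.path(out_dir, "differential_abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$da <- da
    logf("da: ", nrow(da), " taxa over ", nrow(pairs), " pairs")
  }

  if (isTRUE(stages$survival) &&
      any(!is.na(cohort$metadata$survival_time_years))) {
    surv_tab <- filter_survival_abundance(
      tab, config$thresholds$survival_min_reads,
      config$thresholds$survival_min_fraction)
    if (nrow(surv_tab$counts) > 0) {
      clr <- clr_transform(surv_tab, pseudo_count = config$clr_pseudo)
      md <- cohort$metadata[cohort$metadata$tissue == "tumor", ]
      rec <- prepare_survival(md)
      rec$sample_id <- md$sample_id[match(rec$subject_id, md$subject_id)]
      scan <- taxon_survival_scan(clr, rec)
      utils::write.table(scan, file.path(out_dir, "survival_scan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$survival <- scan
      logf("survival: ", sum(!scan$aliased), " taxa tested")
    }
  }

  if (isTRUE(stages$power)) {
    n_pairs <- sum(cohort$metadata$tissue == "tumor")
    alpha <- config$power$alpha
    pw <- data.frame(
      analysis = c("paired_mde"),
      n = n_pairs, alpha = alpha,
      value = min_detectable_effect(n_pairs, alpha,
                                    config$power$power_target))
    utils::write.table(pw, file.path(out_dir, "power.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$power <- pw
  }

  # run.log carries wall-clock timestamps; keep the manifest deterministic.
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json", "run.log"))
  manifest <- list(
    config = config,
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("lowbiome")),
    files = stats::setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, files)))), files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
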