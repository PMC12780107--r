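#' Synthetic low-biomass multi-platform cohorts with known ground truth
#'
#' The generator emulates the structure of a paired tumor-normal tissue
#' microbiome study across three sequencing platforms: very low per-sample
#' bacterial depth (log-normal depth models parameterized by their medians,
#' anchored to the platform medians reported for this kind of cohort — 344
#' reads for WGS-like, 730 for 16S-like, and 9080 for RNA-like tumor
#' samples), a balanced phylum-family-genus taxonomy, per-subject latent
#' compositions from a Dirichlet base, sparse tumor effects planted on the
#' CLR scale, batch-specific contaminant spiking, and right-censored
#' survival with proportional-hazards taxon effects. Every cohort carries a
#' ground-truth manifest sufficient to recompute expected analysis
#' outcomes.
#'
#' @name synthetic_data
NULL

#' Configuration for a synthetic cohort
#'
#' @param n_subjects paired subjects (each contributes a tumor and a normal
#'   sample).
#' @param platform depth-model preset: `"RNA"` (median 9080 reads),
#'   `"16S"` (730), or `"WGS"` (344); tumor medians from the motivating
#'   study design. `depth_median` overrides the preset.
#' @param depth_median optional explicit median depth.
#' @param depth_sdlog log-scale standard deviation of the depth model
#'   (default 0.6, giving the order-of-magnitude spread seen in tissue
#'   data).
#' @param n_genera number of genera (default 50).
#' @param n_phyla,families_per_phylum taxonomy shape; genera are nested
#'   evenly (default 4 phyla, 3 families each).
#' @param base_concentration Dirichlet concentration of the base
#'   composition (default 0.5: realistic dominance of a few genera).
#' @param subject_concentration total Dirichlet concentration of
#'   per-subject compositions around the base (default 20: strong
#'   inter-subject variation with sparse rare genera, the regime seen in
#'   tissue microbiome data, giving CLR spreads on the order of 1-2 units).
#' @param tumor_effect named numeric vector of CLR-scale shifts applied to
#'   tumor samples (default none).
#' @param contaminants character vector of contaminant genus names added on
#'   top of the taxonomy (default none; see [spike_contamination()]).
#' @param contaminant_intensity per-batch relative intensity: a numeric
#'   vector of length `n_batches`; contaminant reads are added at
#'   `intensity * depth` per sample (default all 0).
#' @param n_sites study sites (default 2), assigned round-robin.
#' @param n_batches processing batches (default 2).
#' @param survival list with elements `mu`, `sigma` (log-normal baseline of
#'   survival time in years), `censor_fraction`, and `log_hr`: named vector
#'   of per-genus log hazard ratios applied to true CLR abundance
#'   (default NULL: no survival generation).
#' @param seed master seed; all randomness flows from it.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 100,
                          platform = c("RNA", "16S", "WGS"),
                          depth_median = NULL,
                          depth_sdlog = 0.6,
                          n_genera = 50,
                          n_phyla = 4,
                          families_per_phylum = 3,
                          base_concentration = 0.5,
                          subject_concentration = 20,
                          tumor_effect = numeric(0),
                          contaminants = character(0),
                          contaminant_intensity = NULL,
                          n_sites = 2,
                          n_batches = 2,
                          survival = NULL,
                          seed = 1L) {
  platform <- match.arg(platform)
  if (n_subjects < 1 || n_genera < 2)
    stop_lowbiome("need at least 1 subject and 2 genera",
                  class = "lowbiome_validation_error")
  presets <- c(RNA = 9080, `16S` = 730, WGS = 344)
  depth_median <- depth_median %||% unname(presets[platform])
  contaminant_intensity <- contaminant_intensity %||% rep(0, n_batches)
  stopifnot(length(contaminant_intensity) == n_batches)
  if (length(tumor_effect) && is.null(names(tumor_effect)))
    stop_lowbiome("tumor_effect must be named by genus",
                  class = "lowbiome_validation_error")
  structure(list(
    n_subjects = as.integer(n_subjects), platform = platform,
    depth_median = depth_median, depth_sdlog = depth_sdlog,
    n_genera = as.integer(n_genera), n_phyla = as.integer(n_phyla),
    families_per_phylum = as.integer(families_per_phylum),
    base_concentration = base_concentration,
    subject_concentration = subject_concentration,
    tumor_effect = tumor_effect,
    contaminants = contaminants,
    contaminant_intensity = contaminant_intensity,
    n_sites = as.integer(n_sites), n_batches = as.integer(n_batches),
    survival = survival, seed = as.integer(seed)
  ), class = "cohort_config")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  g / rowSums(g)
}

# Balanced genus taxonomy: genus names g01..gNN nested in families/phyla.
synthetic_taxonomy <- function(config) {
  g <- sprintf("g%02d", seq_len(config$n_genera))
  n_fam <- config$n_phyla * config$families_per_phylum
  fam <- sprintf("f%02d", ((seq_len(config$n_genera) - 1) %% n_fam) + 1)
  phy <- sprintf("p%02d", ((match(fam, sort(unique(fam))) - 1) %/%
                             config$families_per_phylum) + 1)
  data.frame(genus = g, family = fam, phylum = phy, stringsAsFactors = FALSE)
}

#' Generate a synthetic paired tumor-normal cohort
#'
#' Per subject: a latent composition is drawn from a Dirichlet around a
#' cohort-level base composition; the tumor sample's composition shifts the
#' planted genera on the CLR scale by `tumor_effect` (adding the effect to
#' log-abundance and renormalizing, which shifts the genus CLR by the
#' effect minus the mean shift); counts are drawn multinomially at a depth
#' sampled from the platform's log-normal depth model. Contamination and
#' survival are added by [spike_contamination()] and [generate_survival()],
#' which are invoked automatically when configured.
#'
#' @param config a [cohort_config()].
#' @return list: `table` (genus [count_table()], tumor and normal columns),
#'   `metadata` (data.frame, one row per sample), `truth`
#'   (ground-truth manifest: taxonomy, base and per-sample true
#'   compositions, planted effects, contaminant set, batch intensities,
#'   hazard ratios, realized depths).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    taxo <- synthetic_taxonomy(config)
    genera <- taxo$genus
    unknown_fx <- setdiff(names(config$tumor_effect), genera)
    if (length(unknown_fx))
      stop_lowbiome("tumor_effect names not in taxonomy: ",
                    paste(unknown_fx, collapse = ", "),
                    class = "lowbiome_validation_error")
    n <- config$n_subjects
    base <- as.numeric(rdirichlet(1, rep(config$base_concentration,
                                         config$n_genera)))
    base <- pmax(base, 1e-6)
    base <- base / sum(base)
    subj_comp <- rdirichlet(n, config$subject_concentration * base)
    colnames(subj_comp) <- genera

    effect <- stats::setNames(rep(0, config$n_genera), genera)
    effect[names(config$tumor_effect)] <- config$tumor_effect
    tumor_comp <- sweep(log(pmax(subj_comp, 1e-12)), 2, effect, "+")
    tumor_comp <- exp(tumor_comp)
    tumor_comp <- tumor_comp / rowSums(tumor_comp)

    subjects <- sprintf("S%04d", seq_len(n))
    sample_tumor <- paste0(subjects, "_T")
    sample_normal <- paste0(subjects, "_N")
    meanlog <- log(config$depth_median)
    depths_t <- pmax(2, round(stats::rlnorm(n, meanlog, config$depth_sdlog)))
    depths_n <- pmax(2, round(stats::rlnorm(n, meanlog, config$depth_sdlog)))

    draw <- function(comp, depths) {
      vapply(seq_len(n), function(i)
        as.numeric(stats::rmultinom(1, depths[i], comp[i, ])),
        numeric(config$n_genera))
    }
    counts <- cbind(draw(tumor_comp, depths_t), draw(subj_comp, depths_n))
    dimnames(counts) <- list(genera, c(sample_tumor, sample_normal))

    site <- rep(sprintf("site%d", ((seq_len(n) - 1) %% config$n_sites) + 1), 2)
    batch <- rep(sprintf("batch%d", ((seq_len(n) - 1) %% config$n_batches) + 1), 2)
    metadata <- data.frame(
      sample_id = c(sample_tumor, sample_normal),
      subject_id = rep(subjects, 2),
      tissue = rep(c("tumor", "normal"), each = n),
      platform = config$platform,
      study_site = site,
      batch = batch,
      sex = rep(sample(c("female", "male"), n, replace = TRUE, prob = c(0.8, 0.2)), 2),
      age_years = rep(round(stats::rnorm(n, 65, 8), 1), 2),
      ancestry = rep(sample(c("EUR", "EAS", "AMR"), n, replace = TRUE,
                            prob = c(0.45, 0.45, 0.10)), 2),
      stage = rep(sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                         prob = c(0.6, 0.17, 0.17, 0.06)), 2),
      histology = rep(sample(c("adenocarcinoma", "carcinoid", "squamous"),
                             n, replace = TRUE, prob = c(0.88, 0.07, 0.05)), 2),
      survival_time_years = NA_real_,
      vital_status = NA_integer_,
      stringsAsFactors = FALSE
    )

    truth <- list(
      taxonomy = taxo,
      base_composition = stats::setNames(base, genera),
      true_composition_normal = subj_comp,
      true_composition_tumor = tumor_comp,
      tumor_effect = config$tumor_effect,
      contaminants = config$contaminants,
      contaminant_intensity = config$contaminant_intensity,
      log_hr = if (!is.null(config$survival)) config$survival$log_hr else NULL,
      depths = c(stats::setNames(depths_t, sample_tumor),
                 stats::setNames(depths_n, sample_normal)),
      seed = config$seed
    )
    out <- list(table = count_table(counts, rank = "G"),
                metadata = metadata, truth = truth)
    if (length(config$contaminants))
      out <- spike_contamination(out, config)
    if (!is.null(config$survival))
      out <- generate_survival(out, config)
    out
  })
}

#' Spike batch-specific contaminant reads into a cohort
#'
#' Contaminant genera (disjoint from the planted-effect genera by contract)
#' are appended to the count table; each sample receives Poisson
#' contaminant reads with mean `intensity[batch] * sample_depth`, split
#' evenly across the contaminant genera, so some batches can be left
#' clean. The spiked set and intensities are recorded in the truth
#' manifest.
#'
#' @param cohort list from [generate_cohort()].
#' @param config the same [cohort_config()].
#' @return the cohort with contaminated `table` and updated `truth`.
#' @export
spike_contamination <- function(cohort, config) {
  cont <- config$contaminants
  if (!length(cont)) return(cohort)
  overlap <- intersect(cont, names(config$tumor_effect))
  if (length(overlap))
    stop_lowbiome("contaminants overlap planted-effect genera: ",
                  paste(overlap, collapse = ", "),
                  class = "lowbiome_validation_error")
  m <- cohort$table$counts
  md <- cohort$metadata
  batch_idx <- as.integer(sub("batch", "", md$batch))
  intens <- config$contaminant_intensity[batch_idx]
  depths <- colSums(m)
  add <- matrix(0, length(cont), ncol(m), dimnames = list(cont, colnames(m)))
  with_seed(derive_seed(config$seed, 999983L), {
    for (j in seq_len(ncol(m))) {
      lambda <- intens[j] * depths[j] / length(cont)
      if (lambda > 0) add[, j] <- stats::rpois(length(cont), lambda)
    }
  })
  cohort$table <- count_table(rbind(m, add), rank = cohort$table$rank)
  cohort$truth$contaminants <- cont
  cohort$truth$contaminant_reads <- sum(add)
  cohort
}

#' Fill in survival outcomes from planted proportional-hazards effects
#'
#' Subject-level event times are generated from the PH model over the
#' configured log-normal baseline. The linear predictor is
#' `sum_k log_hr[k] * z_k`, where `z_k` is the taxon's true-composition CLR
#' abundance standardized across subjects (mean 0, SD 1), so each planted
#' log hazard ratio is per standard deviation of the feature — the same
#' convention as the standard-normal feature in [survival_power_sim()].
#' The configured fraction of subjects is censored at uniform times on
#' `(0, T_i)`. The realized event count is recorded in the truth manifest.
#'
#' @param cohort list from [generate_cohort()].
#' @param config the same [cohort_config()]; `config$survival` must hold
#'   `mu`, `sigma`, `censor_fraction`, and optionally `log_hr`.
#' @return the cohort with survival fields filled in `metadata`.
#' @export
generate_survival <- function(cohort, config) {
  sv <- config$survival
  if (is.null(sv)) return(cohort)
  stopifnot(!is.null(sv$mu), !is.null(sv$sigma))
  cf <- sv$censor_fraction %||% 0
  log_hr <- sv$log_hr %||% numeric(0)
  n <- config$n_subjects
  comp <- cohort$truth$true_composition_tumor
  lp <- rep(0, n)
  if (length(log_hr)) {
    bad <- setdiff(names(log_hr), colnames(comp))
    if (length(bad))
      stop_lowbiome("log_hr names not in taxonomy: ", paste(bad, collapse = ", "),
                    class = "lowbiome_validation_error")
    clr_true <- t(clr_transform(t(comp), pseudo_count = 1e-6))
    z <- scale(clr_true[, names(log_hr), drop = FALSE])
    lp <- as.numeric(z %*% log_hr)
  }
  with_seed(derive_seed(config$seed, 424243L), {
    t_event <- simulate_event_times(n, z = lp, beta = 1,
                                    mu = sv$mu, sigma = sv$sigma)
    time <- t_event
    event <- rep(1L, n)
    if (cf > 0) {
      idx <- sample.int(n, round(cf * n))
      time[idx] <- stats::runif(length(idx), 0, t_event[idx])
      event[idx] <- 0L
    }
    subj <- sprintf("S%04d", seq_len(n))
    i <- match(cohort$metadata$subject_id, subj)
    cohort$metadata$survival_time_years <- round(time[i], 4)
    cohort$metadata$vital_status <- event[i]
    cohort$truth$realized_events <- sum(event)
    cohort$truth$linear_predictor <- stats::setNames(lp, subj)
  })
  cohort
}

#' Write a cohort to a run directory
#'
#' Writes the genus count table and metadata as TSV and the truth manifest
#' as JSON.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(cohort$table, file.path(dir, "counts_genus.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$true_composition_normal <- NULL  # large; regenerate from seed
  truth$true_composition_tumor <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
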