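#' Ten-year overall survival and per-taxon Cox scans
#'
#' Survival associations use overall survival censored at ten years, with
#' baseline hazards stratified by study site, tumor stage (I vs II-IV
#' combined, for robust inference with few late-stage subjects), and age at
#' diagnosis (<= 65 vs > 65), further adjusted for age in ten-year
#' categories and histology. Each taxon is tested in its own model with its
#' CLR abundance as the covariate of interest.
#'
#' @name survival_assoc
NULL

#' Prepare per-subject survival records
#'
#' Truncates follow-up at `horizon_years` (deaths after the horizon become
#' censored at the horizon), combines stages II-IV into one stratum, bins
#' age at 65 for stratification and into decades for adjustment. Subjects
#' with unknown stage are dropped with a warning (listwise deletion).
#'
#' @param metadata data.frame with columns subject_id, survival_time_years,
#'   vital_status (1 death, 0 censored), study_site, stage, age_years, and
#'   optionally histology.
#' @param horizon_years censoring horizon (default 10).
#' @return data.frame: subject_id, time_years, event, site, stage_group,
#'   age_group, age_decade, histology.
#' @export
prepare_survival <- function(metadata, horizon_years = 10) {
  need <- c("subject_id", "survival_time_years", "vital_status",
            "study_site", "stage", "age_years")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop_lowbiome("metadata lacks column(s): ", paste(miss, collapse = ", "),
                  class = "lowbiome_validation_error")
  md <- metadata[!is.na(metadata$survival_time_years) &
                   !is.na(metadata$vital_status), , drop = FALSE]
  md <- md[!duplicated(md$subject_id), , drop = FALSE]
  unknown <- is.na(md$stage) | md$stage %in% c("unknown", "")
  if (any(unknown)) {
    warning(sum(unknown), " subject(s) with unknown stage dropped")
    md <- md[!unknown, , drop = FALSE]
  }
  over <- md$survival_time_years > horizon_years
  time <- pmin(md$survival_time_years, horizon_years)
  event <- ifelse(over, 0L, as.integer(md$vital_status))
  data.frame(
    subject_id = md$subject_id,
    time_years = time,
    event = event,
    site = as.character(md$study_site),
    stage_group = ifelse(md$stage == "I", "I", "II-IV"),
    age_group = ifelse(md$age_years <= 65, "<=65", ">65"),
    age_decade = paste0("[", 10 * floor(md$age_years / 10), ",",
                        10 * floor(md$age_years / 10) + 10, ")"),
    histology = if ("histology" %in% names(md)) as.character(md$histology) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Fit a stratified Cox proportional-hazards model
#'
#' Maximizes the stratified partial likelihood (Breslow tie handling by
#' default, Efron via `ties`). Aliased (constant or collinear) covariates
#' raise an error; non-convergence and monotone-likelihood (perfect
#' separation) fits are flagged rather than silently returned.
#'
#' @param records data.frame from [prepare_survival()], optionally with
#'   extra covariate columns bound on.
#' @param covariates character vector of covariate column names.
#' @param strata character vector of stratification column names
#'   (default none).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list: coefficients data.frame (term, coef, se, wald, p_value),
#'   loglik, converged, flagged, n, n_events, fit (the underlying
#'   `survival::coxph` object).
#' @export
cox_fit <- function(records, covariates, strata = character(0),
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  for (v in covariates) {
    x <- records[[v]]
    if (is.null(x))
      stop_lowbiome("covariate '", v, "' absent", class = "lowbiome_validation_error")
    if (length(unique(x[!is.na(x)])) < 2)
      stop_lowbiome("covariate '", v, "' is constant (aliased)",
                    class = "lowbiome_validation_error")
  }
  rhs <- paste(covariates, collapse = " + ")
  if (length(strata))
    rhs <- paste(rhs, "+", paste(sprintf("strata(%s)", strata), collapse = " + "))
  fml <- stats::as.formula(paste("survival::Surv(time_years, event) ~", rhs))
  fit <- survival::coxph(fml, data = records, ties = ties)
  co <- summary(fit)$coefficients
  flagged <- !is.null(fit$info) || any(is.na(stats::coef(fit))) ||
    any(abs(stats::coef(fit)) > 15)
  converged <- is.null(fit$info)
  list(
    coefficients = data.frame(
      term = rownames(co),
      coef = co[, "coef"],
      se = co[, "se(coef)"],
      wald = (co[, "coef"] / co[, "se(coef)"])^2,
      p_value = co[, "Pr(>|z|)"],
      row.names = NULL),
    loglik = fit$loglik[length(fit$loglik)],
    converged = converged,
    flagged = flagged,
    n = fit$n,
    n_events = fit$nevent,
    fit = fit
  )
}

#' Per-taxon stratified Cox survival scan
#'
#' Fits one Cox model per taxon with the taxon's CLR abundance as the
#' covariate of interest, plus adjustment covariates and strata, and
#' adjusts the per-taxon Wald p-values across taxa (BH by default). The
#' count table should be pre-filtered with [filter_survival_abundance()]
#' and CLR-transformed with pseudo-count 0.05. Taxa whose CLR abundance is
#' constant across analyzed subjects are reported as aliased and excluded
#' from testing; strata without events contribute nothing to the partial
#' likelihood (they are retained and simply carry no information).
#'
#' @param clr taxa x samples CLR matrix; columns must match
#'   `records$sample_id`.
#' @param records output of [prepare_survival()] plus a `sample_id` column
#'   linking subjects to CLR columns.
#' @param adjust_covariates extra covariate columns (default
#'   `c("histology", "age_decade")` where present).
#' @param strata stratification columns (default
#'   `c("site", "stage_group", "age_group")` where present).
#' @param adjust p-value adjustment method across taxa.
#' @return data.frame per taxon: taxon, log_hr, se, wald, p_value, fdr,
#'   aliased.
#' @export
taxon_survival_scan <- function(clr, records,
                                adjust_covariates = NULL,
                                strata = NULL,
                                adjust = c("BH", "holm")) {
  adjust <- match.arg(adjust)
  if (is.null(records$sample_id))
    stop_lowbiome("records need a sample_id column matching CLR columns",
                  class = "lowbiome_validation_error")
  keep <- records$sample_id %in% colnames(clr)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < 10)
    stop_lowbiome("too few subjects with abundance data",
                  class = "lowbiome_validation_error")
  strata <- strata %||% intersect(c("site", "stage_group", "age_group"), names(rec))
  adjust_covariates <- adjust_covariates %||%
    intersect(c("histology", "age_decade"), names(rec))
  adjust_covariates <- adjust_covariates[vapply(adjust_covariates, function(v)
    length(unique(rec[[v]][!is.na(rec[[v]])])) > 1, logical(1))]
  taxa <- rownames(clr)
  res <- lapply(taxa, function(tx) {
    rec$taxon_clr <- as.numeric(clr[tx, rec$sample_id])
    if (length(unique(rec$taxon_clr)) < 2)
      return(data.frame(taxon = tx, log_hr = NA_real_, se = NA_real_,
                        wald = NA_real_, p_value = NA_real_, aliased = TRUE))
    f <- tryCatch(
      cox_fit(rec, covariates = c("taxon_clr", adjust_covariates),
              strata = strata),
      error = function(e) NULL)
    if (is.null(f))
      return(data.frame(taxon = tx, log_hr = NA_real_, se = NA_real_,
                        wald = NA_real_, p_value = NA_real_, aliased = TRUE))
    row <- f$coefficients[f$coefficients$term == "taxon_clr", ]
    data.frame(taxon = tx, log_hr = row$coef, se = row$se, wald = row$wald,
               p_value = row$p_value, aliased = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  tested <- !out$aliased
  out$fdr[tested] <- adjust_pvalues(out$p_value[tested], method = adjust)
  rownames(out) <- NULL
  out
}
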