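#' Compositional statistics: CLR, paired differential abundance, meta-analysis
#'
#' Read counts are compositional; analyses operate on the centered log-ratio
#' (CLR) scale with a small pseudo-count (0.05 by default) added to the raw
#' count matrix. The package's differential-abundance primitive is the
#' paired t-test on per-subject tumor-minus-normal CLR differences, which is
#' also the test whose power the analytic framework in
#' [paired_power()] describes. Cross-platform results are pooled with an
#' inverse-variance fixed-effect model and Fisher's combined probability
#' test.
#'
#' @name composition_stats
NULL

#' Centered log-ratio transform
#'
#' Per sample: `y_i = ln(x_i + c) - mean_j ln(x_j + c)`. Every output
#' column sums to zero by construction.
#'
#' @param x a [count_table()] or taxa-by-samples matrix.
#' @param pseudo_count positive pseudo-count added to every cell
#'   (default 0.05).
#' @return a `clr_matrix`: taxa x samples matrix of reals with attribute
#'   `pseudo_count`.
#' @export
clr_transform <- function(x, pseudo_count = 0.05) {
  stopifnot(pseudo_count > 0)
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  lg <- log(m + pseudo_count)
  out <- sweep(lg, 2, colMeans(lg))
  attr(out, "pseudo_count") <- pseudo_count
  class(out) <- c("clr_matrix", class(out))
  out
}

#' Paired tumor-normal differential abundance on the CLR scale
#'
#' For each taxon, tests the per-subject difference
#' `delta_i = CLR_tumor - CLR_normal` against zero with a paired t-test
#' (t distribution, n-1 degrees of freedom). Zero-variance differences
#' (e.g. a taxon absent from every sample) are reported with p = 1 and
#' flagged degenerate rather than dropped, so the output covers all taxa.
#'
#' @param clr a `clr_matrix` (or plain matrix) of taxa x samples.
#' @param pairs data.frame with columns `tumor` and `normal` giving matched
#'   sample ids (one row per subject).
#' @param adjust multiple-testing method, `"BH"` (default) or `"holm"`.
#' @return data.frame per taxon: mean_delta, sd_delta, t, df, p_value,
#'   p_adjusted, degenerate.
#' @export
paired_da_test <- function(clr, pairs, adjust = c("BH", "holm")) {
  adjust <- match.arg(adjust)
  if (!all(c("tumor", "normal") %in% names(pairs)))
    stop_lowbiome("pairs needs 'tumor' and 'normal' columns",
                  class = "lowbiome_validation_error")
  miss <- setdiff(c(pairs$tumor, pairs$normal), colnames(clr))
  if (length(miss))
    stop_lowbiome("paired samples absent from CLR matrix: ",
                  paste(utils::head(miss, 5), collapse = ", "),
                  class = "lowbiome_validation_error")
  n <- nrow(pairs)
  if (n < 3)
    stop_lowbiome("need at least 3 complete pairs",
                  class = "lowbiome_validation_error")
  delta <- clr[, pairs$tumor, drop = FALSE] - clr[, pairs$normal, drop = FALSE]
  mean_d <- rowMeans(delta)
  sd_d <- apply(delta, 1, stats::sd)
  degenerate <- sd_d == 0
  tstat <- ifelse(degenerate, NA_real_, mean_d / (sd_d / sqrt(n)))
  p <- ifelse(degenerate, 1, 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE))
  data.frame(
    taxon = rownames(delta) %||% as.character(seq_len(nrow(delta))),
    mean_delta = mean_d,
    sd_delta = sd_d,
    t = tstat,
    df = n - 1,
    p_value = p,
    p_adjusted = adjust_pvalues(p, method = adjust),
    degenerate = degenerate,
    row.names = NULL
  )
}

#' Multiple-testing adjustment (BH step-up or Holm step-down)
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (false discovery rate, the package default) or
#'   `"holm"` (family-wise error).
#' @return adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_lowbiome("p-values must lie in [0, 1]",
                  class = "lowbiome_validation_error")
  stats::p.adjust(p, method = method)
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools estimates across data subsets (e.g. platforms) with weights
#' `1/se^2`: pooled estimate `sum(w b)/sum(w)`, pooled standard error
#' `1/sqrt(sum(w))`.
#'
#' @param b numeric vector of per-subset estimates.
#' @param se positive standard errors, same length.
#' @return list: estimate, se, z, p_value (two-sided normal), inputs.
#' @export
fixed_effect_meta <- function(b, se) {
  stopifnot(length(b) == length(se))
  if (any(se <= 0))
    stop_lowbiome("standard errors must be positive",
                  class = "lowbiome_validation_error")
  if (length(b) == 1) {
    z <- b / se
    return(list(estimate = b, se = se, z = z,
                p_value = 2 * stats::pnorm(-abs(z)),
                inputs = data.frame(b = b, se = se)))
  }
  w <- 1 / se^2
  est <- sum(w * b) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- est / pse
  list(estimate = est, se = pse, z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       inputs = data.frame(b = b, se = se))
}

#' Fisher's combined probability test
#'
#' `X^2 = -2 sum(ln p_i)` referred to a chi-square distribution with `2k`
#' degrees of freedom. Zero p-values are clipped to the smallest positive
#' double and flagged.
#'
#' @param p vector of p-values in (0, 1].
#' @return list: statistic, df, p_value, clipped (logical).
#' @export
fisher_combine <- function(p) {
  if (any(p < 0 | p > 1))
    stop_lowbiome("p-values must lie in [0, 1]",
                  class = "lowbiome_validation_error")
  clipped <- any(p == 0)
  if (clipped) {
    warning("zero p-value(s) clipped to .Machine$double.xmin")
    p <- pmax(p, .Machine$double.xmin)
  }
  x2 <- -2 * sum(log(p))
  k <- length(p)
  list(statistic = x2, df = 2 * k,
       p_value = stats::pchisq(x2, df = 2 * k, lower.tail = FALSE),
       clipped = clipped)
}

#' Meta-analysis of beta-diversity across data subsets
#'
#' Averages the per-subset PERMANOVA R^2 values and combines their
#' p-values with Fisher's test.
#'
#' @param r2 vector of R^2 values in \[0, 1\].
#' @param p vector of p-values, same length.
#' @return list: mean_r2, statistic, df, p_value.
#' @export
meta_beta_r2 <- function(r2, p) {
  if (length(r2) != length(p))
    stop_lowbiome("r2 and p must have equal length",
                  class = "lowbiome_validation_error")
  stopifnot(all(r2 >= 0 & r2 <= 1))
  fc <- fisher_combine(p)
  list(mean_r2 = mean(r2), statistic = fc$statistic, df = fc$df,
       p_value = fc$p_value)
}

#' Cross-platform concordance of CLR abundances
#'
#' Pearson correlations of matched entries between two CLR matrices over
#' their shared samples: one correlation per shared taxon (across samples)
#' and one per shared sample (across taxa). Zero-variance vectors yield NA.
#'
#' @param clr_a,clr_b CLR matrices (taxa x samples) from two platforms.
#' @return list of data.frames `per_taxon` (taxon, r, n) and `per_sample`
#'   (sample, r, n).
#' @export
platform_concordance <- function(clr_a, clr_b) {
  samples <- intersect(colnames(clr_a), colnames(clr_b))
  if (length(samples) < 3)
    stop_lowbiome("need at least 3 shared samples",
                  class = "lowbiome_validation_error")
  taxa <- intersect(rownames(clr_a), rownames(clr_b))
  a <- clr_a[taxa, samples, drop = FALSE]
  b <- clr_b[taxa, samples, drop = FALSE]
  safe_cor <- function(x, y) {
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (is.na(sx) || is.na(sy) || sx == 0 || sy == 0) return(NA_real_)
    stats::cor(x, y)
  }
  list(
    per_taxon = data.frame(
      taxon = taxa,
      r = vapply(seq_along(taxa), function(i) safe_cor(a[i, ], b[i, ]), numeric(1)),
      n = length(samples), row.names = NULL),
    per_sample = data.frame(
      sample = samples,
      r = vapply(seq_along(samples), function(j) safe_cor(a[, j], b[, j]), numeric(1)),
      n = length(taxa), row.names = NULL)
  )
}

#' Marker-based cell-type scores from expression counts
#'
#' Scores each cell type as the median `log2(CPM + 1)` across its marker
#' genes, per sample, where CPM is counts per million of the sample's
#' library. Marker genes absent from the expression table are skipped with
#' a message; a cell type with no matched markers scores NA.
#'
#' @param expression gene x sample count matrix.
#' @param marker_sets named list of character vectors of marker genes.
#' @return cell type x sample matrix of scores.
#' @export
celltype_scores <- function(expression, marker_sets) {
  m <- if (inherits(expression, "count_table")) expression$counts else as.matrix(expression)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  logcpm <- log2(cpm + 1)
  out <- matrix(NA_real_, length(marker_sets), ncol(m),
                dimnames = list(names(marker_sets), colnames(m)))
  for (ct in names(marker_sets)) {
    genes <- intersect(marker_sets[[ct]], rownames(m))
    missing <- setdiff(marker_sets[[ct]], rownames(m))
    if (length(missing))
      message("celltype_scores: ", ct, ": ", length(missing),
              " marker gene(s) not in expression table, skipped")
    if (length(genes))
      out[ct, ] <- apply(logcpm[genes, , drop = FALSE], 2, stats::median)
  }
  out
}

#' Read marker gene sets from GMT or two-column TSV
#'
#' GMT: one set per line, tab-separated (name, description, genes...).
#' TSV: header plus two columns (cell type, gene).
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_marker_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) > 2 || tolower(first[1]) %in% c("cell_type", "celltype")) {
    if (length(first) > 2) {  # GMT
      sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f)
        f[-(1:2)])
      names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
      return(sets)
    }
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    return(split(df[[2]], df[[1]]))
  }
  stop_lowbiome("unrecognized marker set format",
                class = "lowbiome_format_error")
}
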