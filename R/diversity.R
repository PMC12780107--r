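#' Rarefaction-based diversity and PERMANOVA
#'
#' Samples in low-biomass studies differ in depth by orders of magnitude,
#' so all diversity comparisons are made at a common rarefaction depth.
#' Richness uses the exact hypergeometric expectation; Shannon alpha
#' diversity is the median over repeated random subsamples; Bray-Curtis
#' beta diversity is the mean distance matrix over repeated subsamples;
#' group structure is tested by marginal-term PERMANOVA.
#'
#' @name diversity
NULL

#' Rarefaction protocol
#'
#' @param depth rarefaction depth in reads (>= 1).
#' @param n_alpha_draws subsample draws for alpha diversity (default 100;
#'   the per-sample median over draws is reported).
#' @param n_beta_draws subsample draws for Bray-Curtis (default 50; the
#'   mean distance matrix is reported).
#' @param seed master seed; per-sample streams are derived from it so
#'   results do not depend on sample order.
#' @return a `rarefaction_protocol`.
#' @export
rarefaction_protocol <- function(depth, n_alpha_draws = 100, n_beta_draws = 50,
                                 seed = 1L) {
  stopifnot(depth >= 1, n_alpha_draws >= 1, n_beta_draws >= 1)
  structure(list(depth = as.integer(depth),
                 n_alpha_draws = as.integer(n_alpha_draws),
                 n_beta_draws = as.integer(n_beta_draws),
                 seed = as.integer(seed)),
            class = "rarefaction_protocol")
}

#' Expected genus richness under subsampling without replacement
#'
#' The expected number of distinct taxa observed when `depth` reads are
#' drawn without replacement from a sample with counts `counts` is
#' `sum_j 1 - C(N - N_j, d) / C(N, d)` (hypergeometric expectation),
#' evaluated through log-gamma for numerical stability.
#'
#' @param counts non-negative integer counts for one sample.
#' @param depth subsample size; must not exceed the sample total.
#' @return expected richness (real).
#' @export
expected_richness <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (depth > N)
    stop_lowbiome("depth ", depth, " exceeds sample total ", N,
                  class = "lowbiome_validation_error")
  # log C(N - Nj, d) - log C(N, d); taxa with Nj > N - d are always seen.
  log_c <- function(n, k) ifelse(k > n, -Inf, lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1))
  p_missing <- exp(log_c(N - counts, depth) - log_c(N, depth))
  sum(1 - p_missing)
}

# One multivariate-hypergeometric subsample of `depth` reads.
rarefy_once <- function(counts, depth) {
  N <- sum(counts)
  if (depth == N) return(counts)
  idx <- sample.int(N, depth)
  # Map positions in the pooled read vector back to taxa via cumulative bins.
  bins <- findInterval(idx - 1, cumsum(counts), left.open = FALSE) + 1
  out <- tabulate(bins, nbins = length(counts))
  names(out) <- names(counts)
  out
}

shannon_index <- function(counts, base = exp(1)) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Rarefied Shannon diversity for one sample
#'
#' Draws `n_alpha_draws` subsamples of size `depth` without replacement and
#' returns the median Shannon index across draws (natural log by default).
#'
#' @param counts one sample's non-negative integer counts.
#' @param protocol a [rarefaction_protocol()].
#' @param sample_index integer used to derive this sample's RNG stream from
#'   the protocol seed (keeps results order-independent).
#' @param base logarithm base (default natural log; `2` for bits).
#' @return median Shannon index across draws.
#' @export
shannon_rarefied <- function(counts, protocol, sample_index = 1L, base = exp(1)) {
  N <- sum(counts)
  if (N == 0)
    stop_lowbiome("all-zero sample", class = "lowbiome_validation_error")
  if (N < protocol$depth)
    stop_lowbiome("sample total ", N, " below rarefaction depth ",
                  protocol$depth, class = "lowbiome_validation_error")
  with_seed(derive_seed(protocol$seed, sample_index), {
    h <- vapply(seq_len(protocol$n_alpha_draws), function(k)
      shannon_index(rarefy_once(counts, protocol$depth), base = base),
      numeric(1))
    stats::median(h)
  })
}

#' Rarefied alpha diversity for all samples of a count table
#'
#' @param x a [count_table()].
#' @param protocol a [rarefaction_protocol()].
#' @param base logarithm base for Shannon.
#' @return data.frame: sample_id, total_reads, richness (expected at the
#'   protocol depth), shannon (median over draws). Samples below the depth
#'   are excluded with a warning.
#' @export
alpha_diversity <- function(x, protocol, base = exp(1)) {
  stopifnot(inherits(x, "count_table"))
  depths <- sample_depths(x)
  keep <- depths >= protocol$depth
  if (any(!keep))
    warning(sum(!keep), " sample(s) below rarefaction depth excluded")
  idx <- which(keep)
  data.frame(
    sample_id = sample_names(x)[idx],
    total_reads = depths[idx],
    richness = vapply(idx, function(j)
      expected_richness(x$counts[, j], protocol$depth), numeric(1)),
    shannon = vapply(idx, function(j)
      shannon_rarefied(x$counts[, j], protocol, sample_index = j, base = base),
      numeric(1)),
    row.names = NULL
  )
}

#' Bray-Curtis distances averaged over rarefaction draws
#'
#' Per draw, every retained sample is subsampled to the protocol depth and
#' pairwise Bray-Curtis dissimilarities `sum|x-y| / sum(x+y)` are computed;
#' the arithmetic mean of the `n_beta_draws` distance matrices is returned.
#' Samples below the depth are dropped with a warning.
#'
#' @param x a [count_table()].
#' @param protocol a [rarefaction_protocol()].
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
braycurtis_rarefied <- function(x, protocol) {
  stopifnot(inherits(x, "count_table"))
  depths <- sample_depths(x)
  keep <- depths >= protocol$depth
  if (any(!keep))
    warning(sum(!keep), " sample(s) below rarefaction depth dropped")
  m <- x$counts[, keep, drop = FALSE]
  n <- ncol(m)
  if (n < 2)
    stop_lowbiome("need at least two samples at depth for beta diversity",
                  class = "lowbiome_validation_error")
  acc <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (b in seq_len(protocol$n_beta_draws)) {
    rare <- vapply(seq_len(n), function(j)
      with_seed(derive_seed(protocol$seed, b * 100003L + j),
                rarefy_once(m[, j], protocol$depth)),
      numeric(nrow(m)))
    acc <- acc + as.matrix(vegan::vegdist(t(rare), method = "bray"))
  }
  acc / protocol$n_beta_draws
}

#' Marginal-term PERMANOVA on a distance matrix
#'
#' Partitions the variance of a distance matrix by metadata terms and
#' reports, per term, the marginal sum of squares (the drop in explained SS
#' when the term is removed from the full model), pseudo-F, R^2 (share of
#' total SS), and a permutation p-value over `n_perm` random permutations
#' of sample identities, computed with `vegan::adonis2(by = "margin")`.
#' The p-value includes the observed statistic:
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param dist square symmetric distance matrix or `dist`, with sample
#'   names matching `metadata$sample_id` (or metadata rownames).
#' @param metadata data.frame of per-sample covariates.
#' @param terms character vector of metadata column names to test.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame with rows per term plus `Residual` and `Total`:
#'   columns term, df, ss, pseudo_f, r2, p_value, n_perm.
#' @export
permanova_marginal <- function(dist, metadata, terms, n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  ids <- rownames(d)
  if (!is.null(metadata$sample_id)) {
    rownames(metadata) <- metadata$sample_id
  }
  if (is.null(ids) || !all(ids %in% rownames(metadata)))
    stop_lowbiome("every sample in the distance matrix needs metadata",
                  class = "lowbiome_validation_error")
  md <- metadata[ids, , drop = FALSE]
  missing <- setdiff(terms, names(md))
  if (length(missing))
    stop_lowbiome("metadata lacks term(s): ", paste(missing, collapse = ", "),
                  class = "lowbiome_validation_error")
  for (tm in terms) {
    v <- md[[tm]]
    if (length(unique(v)) < 2)
      stop_lowbiome("term '", tm, "' is constant across samples (no df)",
                    class = "lowbiome_validation_error")
  }
  # Aliased-term check on the full model matrix.
  mm <- stats::model.matrix(stats::reformulate(terms), data = md)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop_lowbiome("collinear/aliased model columns: ",
                  paste(aliased, collapse = ", "),
                  class = "lowbiome_validation_error")
  }
  fml <- stats::as.formula(paste("as.dist(d) ~", paste(terms, collapse = " + ")))
  res <- with_seed(seed,
    vegan::adonis2(fml, data = md, permutations = n_perm, by = "margin"))
  out <- data.frame(
    term = rownames(res),
    df = res$Df,
    ss = res$SumOfSqs,
    pseudo_f = res$F,
    r2 = res$R2,
    p_value = res$`Pr(>F)`,
    n_perm = n_perm,
    row.names = NULL
  )
  out
}
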