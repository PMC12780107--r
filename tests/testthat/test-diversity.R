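test_that("expected richness matches enumeration and subsampling", {
  # single taxon: always exactly 1
  expect_equal(expected_richness(c(A = 5), 5), 1.0)
  # {A:2, B:2} at depth 2: enumeration over C(4,2)=6 subsamples gives 5/3
  expect_equal(expected_richness(c(A = 2, B = 2), 2), 5 / 3)
  # depth = total reads: observed richness
  expect_equal(expected_richness(c(A = 3, B = 1, C = 9), 13), 3)
  # depth beyond the sample total is an error
  expect_error(expected_richness(c(A = 2), 5),
               class = "lowbiome_validation_error")

  # Monte-Carlo agreement within 3 standard errors
  counts <- c(10, 4, 1, 25, 2)
  depth <- 8
  set.seed(42)
  pool <- rep(seq_along(counts), counts)
  obs <- replicate(10000, length(unique(sample(pool, depth))))
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(expected_richness(counts, depth) - mean(obs)), 3 * se)

  # agreement with the classic rarefaction expectation in vegan
  expect_equal(expected_richness(counts, depth),
               as.numeric(vegan::rarefy(counts, depth)),
               tolerance = 1e-10)
})

test_that("rarefied Shannon behaves on uniform, degenerate, and seeded input", {
  proto <- rarefaction_protocol(400, n_alpha_draws = 100, seed = 11)
  h <- shannon_rarefied(c(1000, 1000, 1000, 1000), proto)
  expect_lt(abs(h - log(4)), 0.05)  # within sampling error of ln 4
  expect_equal(shannon_rarefied(c(only = 500), rarefaction_protocol(100, seed = 2)), 0)
  # determinism: same protocol seed, bit-identical
  expect_identical(h, shannon_rarefied(c(1000, 1000, 1000, 1000), proto))
  # order independence comes from per-sample derived streams
  expect_identical(
    shannon_rarefied(c(5, 10, 20), rarefaction_protocol(10, seed = 3),
                     sample_index = 7),
    shannon_rarefied(c(5, 10, 20), rarefaction_protocol(10, seed = 3),
                     sample_index = 7))
  expect_error(shannon_rarefied(c(0, 0), rarefaction_protocol(1, seed = 1)),
               class = "lowbiome_validation_error")
  # Shannon <= ln(richness), equality only for uniform composition
  set.seed(8)
  for (k in 1:20) {
    x <- stats::rpois(6, 40) + 1
    hh <- shannon_rarefied(x, rarefaction_protocol(sum(x), n_alpha_draws = 1,
                                                   seed = k))
    expect_lte(hh, log(sum(x > 0)) + 1e-12)
  }
})

test_that("Bray-Curtis matches the direct formula and bounds", {
  m <- cbind(s1 = c(2, 2), s2 = c(1, 3))
  rownames(m) <- c("a", "b")
  proto <- rarefaction_protocol(4, n_beta_draws = 5, seed = 1)
  bc <- braycurtis_rarefied(count_table(m), proto)  # depth = totals: no sampling
  expect_equal(bc["s1", "s2"], 0.25)
  expect_equal(diag(bc), c(s1 = 0, s2 = 0))
  expect_equal(bc, t(bc))

  # identical samples at full depth -> 0; disjoint supports -> 1
  m2 <- cbind(x = c(3, 3, 0, 0), y = c(3, 3, 0, 0), z = c(0, 0, 4, 2))
  rownames(m2) <- paste0("t", 1:4)
  bc2 <- braycurtis_rarefied(count_table(m2), rarefaction_protocol(6, n_beta_draws = 3, seed = 2))
  expect_equal(bc2["x", "y"], 0)
  expect_equal(bc2["x", "z"], 1)
  expect_true(all(bc2 >= 0 & bc2 <= 1))
})

test_that("alpha_diversity excludes shallow samples with a warning", {
  m <- cbind(deep = c(300, 300), shallow = c(2, 1))
  rownames(m) <- c("a", "b")
  expect_warning(out <- alpha_diversity(count_table(m),
                                        rarefaction_protocol(100, 10, seed = 1)),
                 "below rarefaction depth")
  expect_equal(out$sample_id, "deep")
})

test_that("marginal PERMANOVA reproduces the hand-worked two-group example", {
  # 4 samples, 2 groups; within-pair distance 1, between 2
  D <- matrix(2, 4, 4) - diag(4) * 2
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  md <- data.frame(sample_id = paste0("s", 1:4),
                   grp = c("a", "a", "b", "b"))
  res <- permanova_marginal(D, md, "grp", n_perm = 99, seed = 1)
  grp <- res[res$term == "grp", ]
  expect_equal(grp$r2, 7 / 9, tolerance = 1e-10)
  expect_equal(grp$pseudo_f, 7, tolerance = 1e-10)
  expect_equal(res$ss[res$term == "Total"], 4.5, tolerance = 1e-10)

  # explicit-projection oracle agrees
  orc <- oracle_permanova(D, factor(c("a", "a", "b", "b")))
  expect_equal(grp$ss, orc$ss_model, tolerance = 1e-10)
  expect_equal(grp$r2, orc$r2, tolerance = 1e-10)
})

test_that("PERMANOVA errors on constant and aliased terms", {
  D <- as.matrix(dist(matrix(rnorm(20), 10)))
  dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
  md <- data.frame(sample_id = paste0("s", 1:10),
                   const = "same",
                   g = rep(c("a", "b"), 5))
  md$alias <- md$g  # perfectly collinear with g
  expect_error(permanova_marginal(D, md, "const"),
               class = "lowbiome_validation_error")
  expect_error(permanova_marginal(D, md, c("g", "alias")),
               class = "lowbiome_validation_error")
})

test_that("null permutation p-values are uniform", {
  set.seed(31)
  pvals <- replicate(200, {
    pts <- matrix(rnorm(24), 12)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("s", 1:12), paste0("s", 1:12))
    md <- data.frame(sample_id = paste0("s", 1:12),
                     g = sample(rep(c("a", "b"), 6)))
    res <- permanova_marginal(D, md, "g", n_perm = 199,
                              seed = sample.int(1e6, 1))
    res$p_value[res$term == "g"]
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # p never exactly 0: the observed statistic is counted
  expect_true(all(pvals >= 1 / 200))
})

test_that("single-term R2 values and residual share sum to one", {
  co <- generate_cohort(cohort_config(n_subjects = 15, n_genera = 20, seed = 6))
  proto <- rarefaction_protocol(200, n_beta_draws = 5, seed = 6)
  tab <- filter_min_depth(co$table, 200)
  bc <- suppressWarnings(braycurtis_rarefied(tab, proto))
  res <- permanova_marginal(bc, co$metadata, c("tissue", "study_site"),
                            n_perm = 49, seed = 2)
  r2 <- res$r2[res$term %in% c("tissue", "study_site", "Residual")]
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_lte(sum(res$r2[!res$term %in% c("Total")]), 1 + 1e-8)
})
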