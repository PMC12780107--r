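test_that("CLR transform centers every sample at zero", {
  m <- cbind(s1 = c(1, 4), s2 = c(7, 7))
  rownames(m) <- c("a", "b")
  clr <- clr_transform(count_table(m), pseudo_count = 0.05)
  half <- (log(4.05) - log(1.05)) / 2
  expect_equal(unname(clr[, "s1"]), c(-half, half), tolerance = 1e-12)
  expect_equal(unname(clr[, "s2"]), c(0, 0))
  # column sums zero for arbitrary input
  set.seed(5)
  r <- matrix(rpois(60, 20), 6, dimnames = list(letters[1:6], paste0("s", 1:10)))
  expect_lt(max(abs(colSums(clr_transform(r)))), 1e-9)
})

test_that("paired DA test is antisymmetric and handles degenerate taxa", {
  set.seed(21)
  clr <- matrix(rnorm(5 * 12), 5,
                dimnames = list(paste0("t", 1:5),
                                c(paste0("T", 1:6), paste0("N", 1:6))))
  clr["t5", ] <- 0   # zero-variance difference
  pairs <- data.frame(tumor = paste0("T", 1:6), normal = paste0("N", 1:6))
  res <- paired_da_test(clr, pairs)
  expect_equal(res$df, rep(5, 5))
  expect_true(res$degenerate[res$taxon == "t5"])
  expect_equal(res$p_value[res$taxon == "t5"], 1)
  # swapping labels flips t, keeps p
  swapped <- paired_da_test(clr, data.frame(tumor = pairs$normal,
                                            normal = pairs$tumor))
  ok <- !res$degenerate
  expect_equal(swapped$t[ok], -res$t[ok])
  expect_equal(swapped$p_value[ok], res$p_value[ok])
  # agreement with stats::t.test as an independent route
  tt <- t.test(clr["t1", pairs$tumor], clr["t1", pairs$normal], paired = TRUE)
  expect_equal(res$p_value[res$taxon == "t1"], tt$p.value, tolerance = 1e-12)
  expect_error(paired_da_test(clr, pairs[1:2, ]),
               class = "lowbiome_validation_error")
})

test_that("p-value adjustment reproduces hand-derived BH and Holm values", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p, "BH"), rep(0.04, 4))
  expect_equal(adjust_pvalues(p, "holm"), c(0.04, 0.06, 0.06, 0.06))
  expect_equal(adjust_pvalues(0.3, "BH"), 0.3)
  expect_equal(adjust_pvalues(0.3, "holm"), 0.3)
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "lowbiome_validation_error")
  # Holm dominates BH componentwise; BH monotone in rank
  set.seed(9)
  q <- runif(20)
  expect_true(all(adjust_pvalues(q, "holm") >= adjust_pvalues(q, "BH") - 1e-12))
  bh <- adjust_pvalues(q, "BH")
  expect_true(all(diff(bh[order(q)]) >= -1e-12))
  expect_true(all(bh >= q))
})

test_that("fixed-effect meta pools by inverse variance", {
  res <- fixed_effect_meta(c(1, 3), c(1, 1))
  expect_equal(res$estimate, 2)
  expect_equal(res$se, 1 / sqrt(2), tolerance = 1e-12)
  one <- fixed_effect_meta(2.5, 0.8)
  expect_equal(one$estimate, 2.5)
  expect_equal(one$se, 0.8)
  # doubling all se leaves the pooled estimate unchanged
  a <- fixed_effect_meta(c(0.2, 0.9, -0.3), c(0.5, 0.2, 0.9))
  b <- fixed_effect_meta(c(0.2, 0.9, -0.3), 2 * c(0.5, 0.2, 0.9))
  expect_equal(a$estimate, b$estimate)
  # pooled se below the smallest input se; estimate within input range
  expect_lt(a$se, 0.2)
  expect_gte(a$estimate, -0.3)
  expect_lte(a$estimate, 0.9)
  expect_error(fixed_effect_meta(1, 0), class = "lowbiome_validation_error")
})

test_that("Fisher's combined test matches the chi-square closed form", {
  res <- fisher_combine(c(0.5, 0.5))
  expect_equal(res$statistic, -2 * 2 * log(0.5), tolerance = 1e-12)
  expect_equal(res$df, 4)
  # survival function of chi2_4: exp(-x/2)(1 + x/2)
  x <- res$statistic
  expect_equal(res$p_value, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  # single p round-trips exactly through -2 ln p on 2 df
  expect_equal(fisher_combine(0.123)$p_value, 0.123, tolerance = 1e-12)
  # p = 1 contributes nothing
  expect_equal(fisher_combine(c(0.2, 1))$statistic,
               fisher_combine(0.2)$statistic + 0)
  expect_warning(z <- fisher_combine(c(0, 0.5)), "clipped")
  expect_true(z$clipped)
})

test_that("beta-diversity meta-analysis averages R2 and combines p", {
  res <- meta_beta_r2(c(0.2, 0.4), c(0.05, 0.2))
  expect_equal(res$mean_r2, 0.3)
  expect_equal(res$p_value, fisher_combine(c(0.05, 0.2))$p_value)
  expect_error(meta_beta_r2(c(0.1), c(0.1, 0.2)),
               class = "lowbiome_validation_error")
})

test_that("platform concordance finds perfect, inverted, and null correlation", {
  set.seed(13)
  a <- matrix(rnorm(5 * 8), 5, dimnames = list(paste0("t", 1:5), paste0("s", 1:8)))
  cc <- platform_concordance(a, a)
  expect_equal(cc$per_taxon$r, rep(1, 5))
  cc2 <- platform_concordance(a, -a)
  expect_equal(cc2$per_taxon$r, rep(-1, 5))
  # independent matrices: null correlation within 3/sqrt(n)
  n <- 1000
  x <- matrix(rnorm(n), 1, dimnames = list("t", paste0("s", 1:n)))
  y <- matrix(rnorm(n), 1, dimnames = list("t", paste0("s", 1:n)))
  expect_lt(abs(platform_concordance(x, y)$per_taxon$r), 3 / sqrt(n))
  # zero-variance taxon reported as NA
  a0 <- a; a0["t1", ] <- 2
  expect_true(is.na(platform_concordance(a0, a)$per_taxon$r[1]))
  expect_error(platform_concordance(a[, 1:2], a[, 1:2]),
               class = "lowbiome_validation_error")
})

test_that("cell-type scores are median logCPM over matched markers", {
  m <- matrix(c(100, 300, 600, 0,
                200, 600, 1200, 0), 4, 2,
              dimnames = list(c("CD3D", "CD3E", "MS4A1", "JUNK2"),
                              c("s1", "s2")))
  sets <- read_marker_sets(fixture_path("celltype_markers_example.tsv"))
  expect_named(sets, c("Bcell", "Tcell"))
  scores <- suppressMessages(celltype_scores(m, sets))
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  expect_equal(scores["Tcell", "s1"],
               stats::median(log2(cpm[c("CD3D", "CD3E"), "s1"] + 1)))
  # CD79A is missing from the expression table -> Bcell uses MS4A1 alone
  expect_equal(scores["Bcell", "s1"], log2(cpm["MS4A1", "s1"] + 1))
  # doubling the library leaves scores unchanged
  scores2 <- suppressMessages(celltype_scores(m * 2, sets))
  expect_equal(scores, scores2)
})

test_that("GMT marker sets parse", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SetA\tdesc\tG1\tG2\tG3", "SetB\tdesc\tG9"), gmt)
  sets <- read_marker_sets(gmt)
  expect_equal(sets$SetA, c("G1", "G2", "G3"))
  expect_equal(sets$SetB, "G9")
})
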