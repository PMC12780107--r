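test_that("count tables round-trip through TSV bit-exactly for integer input", {
  tab <- read_count_table(fixture_path("toy_counts_genus.tsv"))
  expect_equal(unname(sample_depths(tab)), c(4, 6))
  expect_equal(taxa_names(tab), c("Genus_A", "Genus_B"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, tmp)
  back <- read_count_table(tmp)
  expect_identical(back$counts, tab$counts)
  # gzip round-trip too
  tmpgz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_count_table(tab, tmpgz)
  expect_identical(read_count_table(tmpgz)$counts, tab$counts)
})

test_that("malformed count tables are rejected", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_count_table(empty), class = "lowbiome_format_error")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1\ts1", "A\t1\t2"), dup)
  expect_error(read_count_table(dup), class = "lowbiome_format_error")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1", "A\t-3"), neg)
  expect_error(read_count_table(neg), class = "lowbiome_validation_error")

  txt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1", "A\toops"), txt)
  expect_error(read_count_table(txt), class = "lowbiome_format_error")
})

test_that("long-format reader pivots to the same matrix", {
  long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tsample\tcount",
               "Genus_A\ts1\t1", "Genus_A\ts2\t2",
               "Genus_B\ts1\t3", "Genus_B\ts2\t4"), long)
  tab <- read_count_table_long(long)
  wide <- read_count_table(fixture_path("toy_counts_genus.tsv"))
  expect_equal(tab$counts, wide$counts)
})

test_that("Kraken reports parse into a consistent tree", {
  tree <- read_kraken_report(fixture_path("toy_kraken_report.tsv"),
                             sample_id = "s1")
  expect_s3_class(tree, "taxonomy_tree")
  expect_equal(nrow(tree$nodes), 3)
  # root direct = clade - child clade = 100 - 60 = 40
  expect_equal(unname(tree$direct["1", "s1"]), 40)
  expect_true(validate_taxonomy_tree(tree))

  only_uncl <- withr::local_tempfile()
  writeLines("100.00\t500\t500\tU\t0\tunclassified", only_uncl)
  t2 <- read_kraken_report(only_uncl, sample_id = "s")
  expect_equal(nrow(t2$nodes), 1)
  expect_equal(t2$nodes$rank, "R")
  expect_equal(attr(t2, "unclassified_reads"), 500)

  bad <- withr::local_tempfile()
  writeLines(c("100.00\t10\t20\tR\t1\troot"), bad)  # clade < direct
  expect_error(read_kraken_report(bad), class = "lowbiome_validation_error")

  weird <- withr::local_tempfile()
  writeLines(c("100.00\t10\t5\tR\t1\troot",
               "50.00\t5\t5\tZ9\t7\t  oddity"), weird)
  expect_warning(t3 <- read_kraken_report(weird), "unknown rank")
  expect_equal(t3$nodes$rank[2], "no rank")
})

test_that("aggregate_to_rank extracts clade counts and conserves totals", {
  # family with two genera (100, 50) and 30 direct reads
  rep_file <- withr::local_tempfile()
  writeLines(c("100.00\t200\t20\tR\t1\troot",
               "90.00\t180\t30\tF\t10\t  Fam",
               "50.00\t100\t100\tG\t11\t    GenA",
               "25.00\t50\t50\tG\t12\t    GenB"), rep_file)
  tree <- read_kraken_report(rep_file, sample_id = "s1")
  g <- aggregate_to_rank(tree, "G")
  expect_equal(unname(g$counts[, 1]), c(100, 50))
  f <- aggregate_to_rank(tree, "F")
  expect_equal(unname(f$counts[, 1]), 150 + 30)
  expect_warning(s <- aggregate_to_rank(tree, "S"), "absent")
  expect_equal(nrow(s$counts), 0)
  # conservation: genus table total equals sum of genus clade reads
  expect_equal(sum(g$counts), sum(tree$clade[tree$nodes$rank == "G", ]))
})

test_that("depth filter uses a strict less-than rule", {
  m <- matrix(c(499, 500, 501), 1, 3,
              dimnames = list("A", c("s1", "s2", "s3")))
  tab <- count_table(m)
  kept <- filter_min_depth(tab, 500)
  expect_equal(sample_names(kept), c("s2", "s3"))
  expect_equal(filter_min_depth(tab, 0)$counts, tab$counts)
  expect_message(none <- filter_min_depth(tab, 1e6), "all samples below")
  expect_equal(ncol(none$counts), 0)
})

test_that("prevalence filter treats the boundary as retained", {
  n <- 100
  m <- rbind(rare = c(rep(1, 4), rep(0, n - 4)),
             boundary = c(rep(1, 5), rep(0, n - 5)),
             common = rep(1, n))
  colnames(m) <- paste0("s", seq_len(n))
  tab <- count_table(m)
  out <- filter_prevalence(tab, 0.05)
  expect_equal(taxa_names(out), c("boundary", "common"))
  expect_equal(filter_prevalence(tab, 0)$counts, tab$counts)
})

test_that("survival abundance filter keeps >=min_reads in >=fraction of samples", {
  n <- 20
  m <- rbind(good = rep(c(50, 0), c(2, n - 2)),     # 50 reads in 10%
             weak = rep(49, n),                      # never reaches 50
             relaxed = rep(c(10, 0), c(2, n - 2)))   # 10 reads in 10%
  colnames(m) <- paste0("s", seq_len(n))
  tab <- count_table(m)
  expect_equal(taxa_names(filter_survival_abundance(tab, 50, 0.10)), "good")
  expect_equal(taxa_names(filter_survival_abundance(tab, 10, 0.10)),
               c("good", "weak", "relaxed"))
})

test_that("all table filters are idempotent", {
  co <- generate_cohort(cohort_config(n_subjects = 10, n_genera = 20, seed = 4))
  tab <- co$table
  for (f in list(function(t) filter_min_depth(t, 250),
                 function(t) filter_prevalence(t, 0.05),
                 function(t) filter_survival_abundance(t, 10, 0.1))) {
    once <- f(tab)
    expect_identical(f(once)$counts, once$counts)
  }
})

test_that("sample metadata reader enforces the sample_id contract", {
  md_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttissue\tsurvival_time_years",
               "a\ttumor\t2.5", "b\tnormal\t3.1"), md_file)
  md <- read_sample_metadata(md_file)
  expect_equal(nrow(md), 2)
  expect_true(all(c("subject_id", "vital_status") %in% names(md)))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tx", "a\t1", "a\t2"), dup)
  expect_error(read_sample_metadata(dup), class = "lowbiome_format_error")
})
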