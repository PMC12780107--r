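#' Count tables of taxa by samples
#'
#' A `count_table` is the package's basic container for taxonomic read
#' counts at a fixed rank: a numeric matrix with taxa as rows and samples as
#' columns, plus the rank it was tabulated at. Counts may be real-valued:
#' decontamination propagation rescales clade counts multiplicatively and
#' premature rounding would break read-conservation checks. Rounding happens
#' only on explicit export.
#'
#' @param counts numeric matrix (taxa x samples), non-negative; dimnames
#'   give taxon and sample identifiers.
#' @param rank rank code of the rows, one of `"D","P","C","O","F","G","S"`
#'   (Kraken report convention) or `"no rank"`.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, rank = "G") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop_lowbiome("count_table requires taxon rownames",
                  class = "lowbiome_format_error")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop_lowbiome("count_table requires sample colnames",
                  class = "lowbiome_format_error")
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop_lowbiome("duplicate taxon ids: ",
                  paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
                  class = "lowbiome_format_error")
  if (anyDuplicated(colnames(counts)))
    stop_lowbiome("duplicate sample ids: ",
                  paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
                  class = "lowbiome_format_error")
  if (anyNA(counts) || !all(is.finite(counts)))
    stop_lowbiome("counts contain missing or non-finite values",
                  class = "lowbiome_validation_error")
  if (any(counts < 0))
    stop_lowbiome("negative counts are not allowed",
                  class = "lowbiome_validation_error")
  structure(list(counts = counts, rank = rank), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples at rank '%s'\n",
              nrow(x$counts), ncol(x$counts), x$rank))
  cat(sprintf("total reads: %s; per-sample median: %s\n",
              format(sum(x$counts)), format(stats::median(colSums(x$counts)))))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Taxon and sample identifiers of a count table
#' @param x a `count_table`.
#' @return character vector of ids.
#' @export
taxa_names <- function(x) rownames(x$counts)

#' @rdname taxa_names
#' @export
sample_names <- function(x) colnames(x$counts)

#' Per-sample total assigned reads
#' @param x a `count_table`.
#' @return named numeric vector of column sums.
#' @export
sample_depths <- function(x) colSums(x$counts)

#' Read a taxa-by-samples count table from TSV
#'
#' Expects a header row of sample identifiers and one row per taxon, with
#' the taxon identifier in the first column. Gzip-compressed files are read
#' transparently. A long-format reader is available as
#' [read_count_table_long()].
#'
#' @param path path to a tab-delimited file (optionally `.gz`).
#' @param rank rank code to attach to the table (default `"G"`).
#' @return a [count_table()].
#' @export
read_count_table <- function(path, rank = "G") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  df <- tryCatch(
    utils::read.delim(con, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop_lowbiome("malformed count table: ", conditionMessage(e),
                                      class = "lowbiome_format_error")
  )
  if (nrow(df) == 0 || ncol(df) < 2)
    stop_lowbiome("count table must have a taxon column and at least one sample",
                  class = "lowbiome_format_error")
  hdr <- names(df)[-1]
  if (anyDuplicated(hdr))
    stop_lowbiome("duplicate sample ids: ",
                  paste(unique(hdr[duplicated(hdr)]), collapse = ", "),
                  class = "lowbiome_format_error")
  taxa <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  colnames(mat) <- hdr
  if (!is.numeric(mat))
    stop_lowbiome("non-numeric count cells found",
                  class = "lowbiome_format_error")
  rownames(mat) <- taxa
  count_table(mat, rank = rank)
}

#' @rdname read_count_table
#' @details `read_count_table_long()` reads three columns
#'   (`taxon`, `sample`, `count`) and pivots to the wide matrix form.
#' @export
read_count_table_long <- function(path, rank = "G") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE)
  need <- c("taxon", "sample", "count")
  if (!all(need %in% names(df)))
    stop_lowbiome("long count table needs columns: ", paste(need, collapse = ", "),
                  class = "lowbiome_format_error")
  if (anyDuplicated(df[, c("taxon", "sample")]))
    stop_lowbiome("duplicated (taxon, sample) entries in long table",
                  class = "lowbiome_format_error")
  taxa <- sort(unique(df$taxon))
  samp <- sort(unique(df$sample))
  mat <- matrix(0, length(taxa), length(samp), dimnames = list(taxa, samp))
  mat[cbind(match(df$taxon, taxa), match(df$sample, samp))] <- df$count
  count_table(mat, rank = rank)
}

#' Write a count table to TSV
#'
#' @param x a `count_table`.
#' @param path output path (gzip if it ends in `.gz`).
#' @param round_counts round to integers on export (default FALSE: adjusted
#'   counts are real-valued by design).
#' @export
write_count_table <- function(x, path, round_counts = FALSE) {
  stopifnot(inherits(x, "count_table"))
  m <- x$counts
  if (round_counts) m <- round(m)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop samples below a minimum sequencing depth
#'
#' Samples whose total assigned reads fall below `min_reads` are removed
#' (strictly fewer than the threshold; a sample at exactly `min_reads` is
#' kept). The study-design defaults are 500 reads for RNA-seq, relaxed to
#' 250 for 16S and 100 for WGS given their lower bacterial depth.
#'
#' @param x a `count_table`.
#' @param min_reads non-negative integer depth cutoff.
#' @return filtered `count_table`; taxa unchanged.
#' @export
filter_min_depth <- function(x, min_reads) {
  stopifnot(inherits(x, "count_table"), min_reads >= 0)
  keep <- colSums(x$counts) >= min_reads
  if (!any(keep))
    message("filter_min_depth: all samples below ", min_reads, " reads")
  out <- x
  out$counts <- x$counts[, keep, drop = FALSE]
  out
}

#' Drop taxa below a prevalence threshold
#'
#' Presence is defined as count strictly greater than zero. Taxa present in
#' fewer than `min_prevalence` of samples are discarded (strict "less
#' than", so a taxon at exactly the threshold is retained). Conventional
#' settings: 5% before differential abundance, 1% before batch correction.
#'
#' @param x a `count_table`.
#' @param min_prevalence fraction in \[0, 1\].
#' @return filtered `count_table`; samples unchanged.
#' @export
filter_prevalence <- function(x, min_prevalence) {
  stopifnot(inherits(x, "count_table"),
            min_prevalence >= 0, min_prevalence <= 1)
  n <- ncol(x$counts)
  prev <- if (n == 0) numeric(nrow(x$counts)) else rowMeans(x$counts > 0)
  out <- x
  out$counts <- x$counts[prev >= min_prevalence, , drop = FALSE]
  out
}

#' Abundance filter used before survival scans
#'
#' Keeps taxa having at least `min_reads` reads in at least
#' `min_sample_fraction` of samples. Defaults follow the survival-analysis
#' rule: 50 reads in 10% of samples for RNA-seq, with the read cutoff
#' relaxed to 10 for 16S and WGS.
#'
#' @param x a `count_table`.
#' @param min_reads positive read cutoff per cell.
#' @param min_sample_fraction fraction of samples that must meet it.
#' @return filtered `count_table`.
#' @export
filter_survival_abundance <- function(x, min_reads = 50, min_sample_fraction = 0.10) {
  stopifnot(inherits(x, "count_table"), min_reads > 0, min_sample_fraction > 0)
  frac <- rowMeans(x$counts >= min_reads)
  out <- x
  out$counts <- x$counts[frac >= min_sample_fraction, , drop = FALSE]
  out
}

#' Read a sample metadata table
#'
#' Tab-delimited with exact header names: `sample_id`, `subject_id`,
#' `tissue` (tumor/normal/blood), `platform` (16S/RNA/WGS), `study_site`,
#' `batch`, `sex`, `age_years`, `ancestry`, `stage` (I/II/III/IV/unknown),
#' `histology`, `survival_time_years`, `vital_status` (0 censored, 1 dead).
#' Only `sample_id` is mandatory; missing optional columns are filled with
#' NA so partial cohorts (e.g. diversity-only runs) still load.
#'
#' @param path TSV path (optionally gzip).
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop_lowbiome("metadata must contain a sample_id column",
                  class = "lowbiome_format_error")
  if (anyDuplicated(df$sample_id))
    stop_lowbiome("duplicate sample_id in metadata",
                  class = "lowbiome_format_error")
  optional <- c("subject_id", "tissue", "platform", "study_site", "batch",
                "sex", "age_years", "ancestry", "stage", "histology",
                "survival_time_years", "vital_status")
  for (col in setdiff(optional, names(df))) df[[col]] <- NA
  if (any(!is.na(df$survival_time_years) & df$survival_time_years < 0))
    stop_lowbiome("negative survival_time_years",
                  class = "lowbiome_validation_error")
  df
}
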