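#' Rank-coded taxonomy trees with clade and direct read counts
#'
#' A `taxonomy_tree` mirrors the structure of a Kraken-style report: each
#' node carries a taxon id, name, rank code, parent pointer, and two count
#' matrices over samples — `clade` (reads assigned to the node or any
#' descendant) and `direct` (reads assigned to exactly that node). The root
#' satisfies, per sample and per node,
#' `clade = direct + sum(clade of children)`; adjusted (post-
#' decontamination) counts are real-valued so this identity is checked to a
#' small tolerance.
#'
#' @name taxonomy_tree
NULL

# Standard rank codes, highest first. "R" is the Kraken root pseudo-rank,
# "U" unclassified. Ranks along any root-to-leaf path strictly decrease.
RANK_ORDER <- c("R", "D", "P", "C", "O", "F", "G", "S")

rank_level <- function(rank) match(rank, RANK_ORDER)

new_taxonomy_tree <- function(nodes, clade, direct) {
  stopifnot(is.data.frame(nodes),
            all(c("taxid", "name", "rank", "parent") %in% names(nodes)))
  structure(list(nodes = nodes, clade = clade, direct = direct),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  tab <- table(factor(x$nodes$rank, levels = c(RANK_ORDER, "no rank")))
  cat(sprintf("taxonomy_tree: %d nodes, %d sample(s)\n",
              nrow(x$nodes), ncol(x$clade)))
  cat("nodes per rank:", paste(names(tab)[tab > 0], tab[tab > 0],
                               sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Validate the clade-sum identity of a taxonomy tree
#'
#' Checks that every node's clade count equals its direct count plus the
#' clade counts of its children, per sample, within `tol` (adjusted counts
#' are real-valued). Also checks `clade >= direct`.
#'
#' @param tree a `taxonomy_tree`.
#' @param tol numeric tolerance (default 1e-9 per read).
#' @return invisibly TRUE, or an error naming the offending taxid.
#' @export
validate_taxonomy_tree <- function(tree, tol = 1e-9) {
  nodes <- tree$nodes
  if (any(tree$clade - tree$direct < -tol)) {
    bad <- nodes$taxid[which(rowSums(tree$clade - tree$direct < -tol) > 0)]
    stop_lowbiome("clade < direct reads at taxid ", paste(bad, collapse = ", "),
                  class = "lowbiome_validation_error")
  }
  child_sum <- matrix(0, nrow(nodes), ncol(tree$clade))
  has_parent <- !is.na(nodes$parent)
  if (any(has_parent)) {
    for (i in which(has_parent)) {
      p <- nodes$parent[i]
      child_sum[p, ] <- child_sum[p, ] + tree$clade[i, ]
    }
  }
  resid <- tree$clade - tree$direct - child_sum
  bad <- which(rowSums(abs(resid) > tol * pmax(1, tree$clade)) > 0)
  if (length(bad))
    stop_lowbiome("clade-sum identity violated at taxid ",
                  paste(nodes$taxid[bad], collapse = ", "),
                  class = "lowbiome_validation_error")
  invisible(TRUE)
}

#' Read a Kraken-style taxonomic report
#'
#' Parses the standard six-column report dialect: percent of reads, clade
#' read count, direct read count, rank code, taxon id, and a name indented
#' by two spaces per taxonomy level. The indentation encodes the tree.
#' An `unclassified` line (rank `U`) is recorded in the
#' `unclassified_reads` attribute rather than as a tree node. Rank codes
#' outside the standard set are retained with rank `"no rank"`; fully
#' unknown codes additionally raise a warning (Kraken sub-rank codes such
#' as `G1` are downgraded silently since they are routine).
#'
#' @param path report path (optionally gzip); `sample_id` names the single
#'   sample column (defaults to the file base name).
#' @param sample_id sample identifier for the counts.
#' @return a `taxonomy_tree` with one sample column.
#' @export
read_kraken_report <- function(path, sample_id = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop_lowbiome("empty Kraken report: ", path, class = "lowbiome_format_error")
  sample_id <- sample_id %||% sub("\\.gz$", "", basename(path))

  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6))
    stop_lowbiome("Kraken report lines must have 6 tab-separated fields",
                  class = "lowbiome_format_error")
  clade  <- as.numeric(vapply(parts, `[[`, "", 2))
  direct <- as.numeric(vapply(parts, `[[`, "", 3))
  rank   <- vapply(parts, `[[`, "", 4)
  taxid  <- vapply(parts, `[[`, "", 5)
  rawname <- vapply(parts, `[[`, "", 6)
  if (anyNA(clade) || anyNA(direct))
    stop_lowbiome("non-numeric read counts in Kraken report",
                  class = "lowbiome_format_error")
  if (any(clade < direct))
    stop_lowbiome("clade reads < direct reads at taxid ",
                  paste(taxid[clade < direct], collapse = ", "),
                  class = "lowbiome_validation_error")

  depth <- nchar(rawname) - nchar(sub("^ *", "", rawname))
  if (any(depth %% 2 != 0))
    stop_lowbiome("indentation must be two spaces per level",
                  class = "lowbiome_format_error")
  depth <- depth / 2
  name <- trimws(rawname)

  unknown <- !(rank %in% c(RANK_ORDER, "U")) &
    !grepl("^[RDKPCOFGS][0-9]+$", rank) & rank != "K"
  if (any(unknown))
    warning("unknown rank code(s) ", paste(unique(rank[unknown]), collapse = ", "),
            "; node(s) retained with rank 'no rank'")
  rank[!(rank %in% c(RANK_ORDER, "U"))] <- "no rank"

  uncl <- rank == "U"
  unclassified_reads <- sum(clade[uncl])
  keep <- !uncl
  clade <- clade[keep]; direct <- direct[keep]; rank <- rank[keep]
  taxid <- taxid[keep]; name <- name[keep]; depth <- depth[keep]

  if (!length(clade)) {
    # Only an unclassified line: return a bare root.
    nodes <- data.frame(taxid = "1", name = "root", rank = "R",
                        parent = NA_integer_, stringsAsFactors = FALSE)
    cl <- matrix(0, 1, 1, dimnames = list("1", sample_id))
    tree <- new_taxonomy_tree(nodes, cl, cl)
    attr(tree, "unclassified_reads") <- unclassified_reads
    return(tree)
  }
  if (anyDuplicated(taxid))
    stop_lowbiome("duplicated taxid in report",
                  class = "lowbiome_format_error")

  # Reconstruct parents from the indentation stack.
  parent <- rep(NA_integer_, length(name))
  stack <- integer(0)  # node index per depth level
  for (i in seq_along(name)) {
    d <- depth[i]
    if (d > length(stack))
      stop_lowbiome("indentation jump at line for taxid ", taxid[i],
                    class = "lowbiome_format_error")
    stack <- stack[seq_len(d)]
    if (d > 0) parent[i] <- stack[d]
    stack <- c(stack, i)
  }

  nodes <- data.frame(taxid = taxid, name = name, rank = rank,
                      parent = parent, stringsAsFactors = FALSE)
  cl <- matrix(clade, ncol = 1, dimnames = list(taxid, sample_id))
  dr <- matrix(direct, ncol = 1, dimnames = list(taxid, sample_id))
  tree <- new_taxonomy_tree(nodes, cl, dr)
  validate_taxonomy_tree(tree)
  attr(tree, "unclassified_reads") <- unclassified_reads
  tree
}

# All descendant node indices of node i (excluding i).
descendant_indices <- function(tree, i) {
  children <- split(seq_len(nrow(tree$nodes)), tree$nodes$parent)
  out <- integer(0)
  frontier <- i
  while (length(frontier)) {
    kids <- unlist(children[as.character(frontier)], use.names = FALSE)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Tabulate a taxonomy tree at a single rank
#'
#' Extracts one row per node at the requested rank; counts are clade reads
#' by default (`counts = "direct"` for reads assigned to the exact node).
#'
#' @param tree a `taxonomy_tree`.
#' @param rank rank code, e.g. `"G"` or `"P"`.
#' @param counts `"clade"` (default) or `"direct"`.
#' @return a [count_table()] (possibly with zero rows, with a warning, if
#'   the rank is absent from the tree).
#' @export
aggregate_to_rank <- function(tree, rank, counts = c("clade", "direct")) {
  counts <- match.arg(counts)
  sel <- which(tree$nodes$rank == rank)
  if (!length(sel)) {
    warning("rank '", rank, "' absent from tree; returning empty table")
    m <- matrix(0, 0, ncol(tree$clade),
                dimnames = list(character(0), colnames(tree$clade)))
    return(count_table(m, rank = rank))
  }
  m <- tree[[counts]][sel, , drop = FALSE]
  rownames(m) <- tree$nodes$name[sel]
  count_table(m, rank = rank)
}
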