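#' Curated-list decontamination with rescue and recursive propagation
#'
#' Low-biomass tissue sequencing is dominated by reagent and handling
#' contamination, and frequency-based decontamination algorithms are
#' unreliable at these read depths. The approach implemented here removes
#' genera from a curated list of frequent NGS contaminants, rescues listed
#' genera that encompass two or more known human-associated species (to
#' avoid discarding plausibly real signal), force-removes genera flagged on
#' review (by default *Cutibacterium*, a ubiquitous skin commensal), and
#' then propagates the genus-level removal recursively up the taxonomy:
#' each ancestor's reads are multiplied by the retained (non-contaminant)
#' fraction of its descendants at the next lower standard rank, applied
#' rank by rank from family to the root.
#'
#' @name decontamination
NULL

#' Build a contaminant-handling policy
#'
#' @param contaminant_genera character vector of genus names flagged as
#'   frequent NGS contaminants (Salter-style list).
#' @param human_associated_species_counts named integer vector: for each
#'   genus, the number of known human-associated species it encompasses.
#'   Genera absent from this vector count as 0.
#' @param rescue_min_species a listed contaminant with at least this many
#'   human-associated species is rescued (default 2).
#' @param forced_removals genera removed regardless of rescue (default
#'   `"Cutibacterium"`).
#' @param min_genus_reads per-cell floor applied before removal: genus
#'   cells with fewer reads are zeroed (2 for Bracken-adjusted DNA counts,
#'   5 for RNA-seq).
#' @return a `contaminant_policy` object.
#' @export
contaminant_policy <- function(contaminant_genera,
                               human_associated_species_counts = integer(0),
                               rescue_min_species = 2,
                               forced_removals = "Cutibacterium",
                               min_genus_reads = 2) {
  stopifnot(rescue_min_species >= 1, min_genus_reads >= 0)
  structure(list(
    contaminant_genera = unique(as.character(contaminant_genera)),
    human_associated_species_counts = human_associated_species_counts,
    rescue_min_species = rescue_min_species,
    forced_removals = unique(as.character(forced_removals)),
    min_genus_reads = min_genus_reads
  ), class = "contaminant_policy")
}

#' Load a contaminant policy from plain-text files
#'
#' @param contaminants_path one genus name per line.
#' @param rescue_counts_path optional two-column TSV
#'   (`genus`, `n_human_species`).
#' @param ... passed to [contaminant_policy()].
#' @return a `contaminant_policy`.
#' @export
read_contaminant_policy <- function(contaminants_path, rescue_counts_path = NULL, ...) {
  genera <- trimws(readLines(contaminants_path, warn = FALSE))
  genera <- genera[nzchar(genera) & !startsWith(genera, "#")]
  counts <- integer(0)
  if (!is.null(rescue_counts_path)) {
    df <- utils::read.delim(rescue_counts_path, header = TRUE,
                            stringsAsFactors = FALSE)
    counts <- stats::setNames(as.integer(df[[2]]), df[[1]])
  }
  contaminant_policy(genera, human_associated_species_counts = counts, ...)
}

#' Resolve which observed genera to remove and which to rescue
#'
#' Removal = (listed contaminants among the observed genera) minus the
#' rescued set, plus forced removals that are observed. Rescued = listed
#' contaminants encompassing at least `rescue_min_species` human-associated
#' species, unless force-removed.
#'
#' @param policy a [contaminant_policy()].
#' @param observed_genera character vector of genus names present in the data.
#' @return list with elements `removal` and `rescued` (disjoint character
#'   vectors).
#' @export
resolve_removal_set <- function(policy, observed_genera) {
  stopifnot(inherits(policy, "contaminant_policy"))
  observed <- unique(as.character(observed_genera))
  listed <- intersect(policy$contaminant_genera, observed)
  hits <- policy$human_associated_species_counts[listed]
  hits[is.na(hits)] <- 0L
  rescued <- listed[hits >= policy$rescue_min_species]
  rescued <- setdiff(rescued, policy$forced_removals)
  removal <- union(setdiff(listed, rescued),
                   intersect(policy$forced_removals, observed))
  unknown <- setdiff(policy$contaminant_genera, observed)
  if (length(unknown))
    message("resolve_removal_set: ", length(unknown),
            " listed genera not observed; ignored")
  list(removal = removal, rescued = rescued)
}

#' Zero out removed taxa in a count table
#'
#' @param x a genus-rank [count_table()].
#' @param removal character vector of taxa to zero in all samples.
#' @return the table with removed taxa set to 0 (rows retained).
#' @export
zero_out_taxa <- function(x, removal) {
  stopifnot(inherits(x, "count_table"))
  hit <- rownames(x$counts) %in% removal
  missing <- setdiff(removal, rownames(x$counts))
  if (length(missing))
    message("zero_out_taxa: not in table, skipped: ",
            paste(missing, collapse = ", "))
  out <- x
  out$counts[hit, ] <- 0
  out
}

#' Apply a per-cell minimum read floor at genus level
#'
#' Cells with fewer than `min_reads` reads are set to zero (a cell at
#' exactly the floor is kept). Used with 2 reads for Bracken-adjusted DNA
#' counts and 5 reads for RNA-seq assignments, where single- or few-read
#' genus calls are overwhelmingly false positives.
#'
#' @param x a [count_table()].
#' @param min_reads non-negative floor.
#' @return the floored table.
#' @export
apply_min_genus_reads <- function(x, min_reads) {
  stopifnot(inherits(x, "count_table"), min_reads >= 0)
  out <- x
  out$counts[out$counts < min_reads] <- 0
  out
}

# Nearest populated standard rank strictly below `rank` within the subtree
# rooted at node i; integer(0) if the subtree has no standard-rank
# descendants. "no rank" nodes are transparent.
lower_rank_descendants <- function(tree, i, rank) {
  desc <- descendant_indices(tree, i)
  if (!length(desc)) return(integer(0))
  lv <- rank_level(rank)
  dranks <- tree$nodes$rank[desc]
  dlv <- rank_level(dranks)  # NA for "no rank"
  below <- which(!is.na(dlv) & dlv > lv)
  if (!length(below)) return(integer(0))
  target <- min(dlv[below])
  desc[below[dlv[below] == target]]
}

#' Propagate genus-level removals up the taxonomy
#'
#' After genus-level decontamination, each node above genus level is
#' rescaled, per sample: its adjusted clade count is the original clade
#' count times the retained fraction of its descendants at the next lower
#' standard rank (sum of adjusted over sum of original clade counts),
#' processed rank by rank from family to the root so the fractions chain
#' recursively. The resulting counts are real-valued.
#'
#' Two conventions are configurable:
#' * `zero_denominator`: a node whose lower-rank descendants carry zero
#'   original reads has an undefined fraction; `"keep"` (default) retains
#'   its reads (fraction 1) so lineages observed only above genus level are
#'   not silently destroyed, `"drop"` applies the strict formula (fraction
#'   0).
#' * `counts`: the rescaling operates on clade counts (default), matching
#'   the rank tables used downstream; `"direct"` additionally rescales
#'   direct counts by the node's own fraction.
#'
#' For lineages that skip a rank (e.g. genera directly under an order), the
#' nearest populated lower standard rank is used, so removals cannot leak
#' upward through a missing level.
#'
#' @param tree a `taxonomy_tree`.
#' @param removal character vector of genus *names* to remove.
#' @param zero_denominator `"keep"` or `"drop"`.
#' @param counts `"clade"` or `"direct"` (see Details).
#' @return a `taxonomy_tree` with adjusted counts and a `decontam_report`
#'   attribute.
#' @export
propagate_upward <- function(tree, removal,
                             zero_denominator = c("keep", "drop"),
                             counts = c("clade", "direct")) {
  zero_denominator <- match.arg(zero_denominator)
  counts <- match.arg(counts)
  nodes <- tree$nodes
  target <- which(nodes$name %in% removal)
  if (length(target) && any(nodes$rank[target] != "G"))
    stop_lowbiome("removal names must resolve to genus-rank nodes: ",
                  paste(nodes$name[target[nodes$rank[target] != "G"]], collapse = ", "),
                  class = "lowbiome_contract_error")

  orig <- tree$clade
  adj <- orig
  adj[target, ] <- 0
  fraction <- matrix(1, nrow(nodes), ncol(orig))

  # Genus fraction: 0 for removed, 1 otherwise (used when rescaling direct).
  fraction[target, ] <- 0

  above_genus <- which(!is.na(rank_level(nodes$rank)) &
                         rank_level(nodes$rank) < rank_level("G"))
  if (length(above_genus)) {
    # Process in increasing rank order: family first, then order, ... root,
    # so each ancestor sees already-adjusted descendants.
    ord <- above_genus[order(rank_level(nodes$rank[above_genus]), decreasing = TRUE)]
    for (i in ord) {
      low <- lower_rank_descendants(tree, i, nodes$rank[i])
      if (!length(low)) {
        f <- if (zero_denominator == "keep") rep(1, ncol(orig)) else rep(0, ncol(orig))
      } else {
        den <- colSums(orig[low, , drop = FALSE])
        num <- colSums(adj[low, , drop = FALSE])
        f <- ifelse(den > 0, num / den,
                    if (zero_denominator == "keep") 1 else 0)
      }
      fraction[i, ] <- f
      adj[i, ] <- orig[i, ] * f
    }
  }

  out <- tree
  out$clade <- adj
  if (counts == "direct") out$direct <- tree$direct * fraction
  else out$direct <- pmin(tree$direct, adj)
  attr(out, "decontam_report") <- decontam_report(tree, out, removal)
  out
}

#' Summarize a decontamination pass
#'
#' @param before,after taxonomy trees before and after adjustment.
#' @param removal genus names removed.
#' @return a `decontam_report`: removed set and per-rank read totals before
#'   and after with retained fractions.
#' @export
decontam_report <- function(before, after, removal) {
  ranks <- intersect(RANK_ORDER, unique(before$nodes$rank))
  per_rank <- do.call(rbind, lapply(ranks, function(r) {
    sel <- before$nodes$rank == r
    b <- sum(before$clade[sel, ])
    a <- sum(after$clade[sel, ])
    data.frame(rank = r, reads_before = b, reads_after = a,
               retained = ifelse(b > 0, a / b, NA_real_))
  }))
  structure(list(removed_genera = removal, per_rank = per_rank),
            class = "decontam_report")
}

#' @export
print.decontam_report <- function(x, ...) {
  cat("decontamination report:", length(x$removed_genera), "genera removed\n")
  print(x$per_rank, row.names = FALSE)
  invisible(x)
}

#' Full genus-table decontamination convenience wrapper
#'
#' Applies the per-cell read floor, resolves the removal set against the
#' observed genera, and zeroes removed genera. Tree-level propagation is
#' done separately with [propagate_upward()] when a taxonomy is available.
#'
#' @param x genus-rank [count_table()].
#' @param policy a [contaminant_policy()].
#' @return list: `table` (decontaminated), `removal`, `rescued`.
#' @export
decontaminate_table <- function(x, policy) {
  x <- apply_min_genus_reads(x, policy$min_genus_reads)
  sets <- resolve_removal_set(policy, taxa_names(x))
  list(table = zero_out_taxa(x, sets$removal),
       removal = sets$removal, rescued = sets$rescued)
}
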