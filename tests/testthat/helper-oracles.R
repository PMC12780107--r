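# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms (recursion, enumeration,
# grid search, explicit projections) from the code paths they verify.

# ---- random small taxonomy trees (<= 6 nodes beyond the root) -------------

# Builds a random tree with ranks drawn strictly decreasing along paths,
# genus-resolved (no species), with random direct counts; clade counts are
# computed bottom-up so the clade-sum identity holds by construction.
random_tree <- function(n_nodes = 5, n_samples = 1, seed = 1) {
  set.seed(seed)
  ranks_pool <- c("D", "P", "C", "O", "F", "G")
  nodes <- data.frame(taxid = "1", name = "root", rank = "R",
                      parent = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n_nodes)) {
    repeat {
      p <- sample.int(nrow(nodes), 1)
      p_lv <- match(nodes$rank[p], c("R", ranks_pool))
      lower <- ranks_pool[match(ranks_pool, c("R", ranks_pool)) > p_lv]
      if (length(lower)) break
    }
    r <- sample(lower, 1)
    nodes <- rbind(nodes, data.frame(
      taxid = as.character(i + 1),
      name = paste0("n", i + 1, "_", r),
      rank = r, parent = p, stringsAsFactors = FALSE))
  }
  direct <- matrix(sample(0:50, nrow(nodes) * n_samples, replace = TRUE),
                   nrow(nodes), n_samples,
                   dimnames = list(nodes$taxid, paste0("s", seq_len(n_samples))))
  clade <- direct
  for (i in rev(seq_len(nrow(nodes)))) {   # children appear after parents
    if (!is.na(nodes$parent[i]))
      clade[nodes$parent[i], ] <- clade[nodes$parent[i], ] + clade[i, ]
  }
  lowbiome:::new_taxonomy_tree(nodes, clade, direct)
}

# Recursive re-computation of the upward-propagation rule, independent of
# the rank-ordered loop in the package.
oracle_propagate <- function(tree, removal, zero_keep = TRUE) {
  nodes <- tree$nodes
  rank_lv <- function(r) match(r, c("R", "D", "P", "C", "O", "F", "G", "S"))
  kids <- lapply(seq_len(nrow(nodes)), function(i) which(nodes$parent == i))
  subtree <- function(i) {
    out <- integer(0); fr <- kids[[i]]
    while (length(fr)) { out <- c(out, fr); fr <- unlist(kids[fr]) }
    out
  }
  adj <- tree$clade
  adjusted <- function(i) {
    if (nodes$rank[i] == "G")
      return(if (nodes$name[i] %in% removal) 0 * tree$clade[i, ] else tree$clade[i, ])
    desc <- subtree(i)
    lv <- rank_lv(nodes$rank[desc])
    below <- desc[!is.na(lv) & lv > rank_lv(nodes$rank[i])]
    if (!length(below))
      return(tree$clade[i, ] * (if (zero_keep) 1 else 0))
    lvb <- rank_lv(nodes$rank[below])
    sel <- below[lvb == min(lvb)]
    num <- Reduce(`+`, lapply(sel, adjusted))
    den <- colSums(tree$clade[sel, , drop = FALSE])
    f <- ifelse(den > 0, num / den, if (zero_keep) 1 else 0)
    tree$clade[i, ] * f
  }
  for (i in seq_len(nrow(nodes)))
    if (nodes$rank[i] != "G" && !is.na(rank_lv(nodes$rank[i])))
      adj[i, ] <- adjusted(i)
    else if (nodes$rank[i] == "G" && nodes$name[i] %in% removal)
      adj[i, ] <- 0
  adj
}

# ---- Breslow partial-likelihood grid/optimize oracle ----------------------

breslow_loglik <- function(beta, time, event, z) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

oracle_cox_beta <- function(time, event, z, interval = c(-5, 5)) {
  stats::optimize(function(b) breslow_loglik(b, time, event, z),
                  interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# ---- explicit-projection PERMANOVA oracle ---------------------------------

oracle_permanova <- function(D, groups) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  X <- stats::model.matrix(~ groups)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ss_total <- sum(diag(G))
  ss_model <- sum(diag(H %*% G %*% H))
  ss_resid <- ss_total - ss_model
  df_model <- qr(X)$rank - 1
  df_resid <- n - qr(X)$rank
  f <- (ss_model / df_model) / (ss_resid / df_resid)
  list(ss_total = ss_total, ss_model = ss_model, ss_resid = ss_resid,
       f = f, r2 = ss_model / ss_total)
}

# ---- small cohort helpers -------------------------------------------------

tumor_normal_pairs <- function(metadata) {
  data.frame(tumor = metadata$sample_id[metadata$tissue == "tumor"],
             normal = metadata$sample_id[metadata$tissue == "normal"])
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "lowbiome", mustWork = TRUE)
}
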