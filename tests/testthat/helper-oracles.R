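# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, direct set arithmetic, and
# closed-form linear algebra.

# Fan-in of every assembly by a direct graph walk over an edge table:
# N * (#child assemblies) + #direct genes not annotated anywhere below.
oracle_fanin <- function(edges, N) {
  aedges <- edges[edges$type == "default", ]
  gedges <- edges[edges$type == "gene", ]
  ids <- unique(c(aedges$parent, aedges$child, gedges$parent))
  desc_genes <- function(id) {
    kids <- aedges$child[aedges$parent == id]
    out <- character(0)
    for (k in kids) {
      out <- c(out, gedges$child[gedges$parent == k], desc_genes(k))
    }
    unique(out)
  }
  res <- sapply(ids, function(id) {
    kids <- aedges$child[aedges$parent == id]
    own <- gedges$child[gedges$parent == id]
    N * length(kids) + length(setdiff(own, desc_genes(id)))
  })
  stats::setNames(res, ids)
}

# Ridge fitted values by the normal equations on centered data.
oracle_ridge_fitted <- function(P, D, penalty) {
  Pc <- scale(P, center = TRUE, scale = FALSE)
  Dc <- D - mean(D)
  w <- solve(crossprod(Pc) + penalty * diag(ncol(Pc)), crossprod(Pc, Dc))
  drop(Pc %*% w) + mean(D)
}

# Spearman rho as Pearson correlation of mid-ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Weighted KS running-sum enrichment score by an explicit position loop
# (weight exponent 1); returns the maximum-magnitude deviation, signed.
oracle_gsea_es <- function(scores_sorted, in_set) {
  scores_sorted <- unname(scores_sorted)
  nh <- sum(in_set)
  nm <- length(scores_sorted) - nh
  wsum <- sum(abs(scores_sorted[in_set]))
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_along(scores_sorted)) {
    if (in_set[i]) {
      run <- run + if (wsum > 0) abs(scores_sorted[i]) / wsum else 1 / nh
    } else {
      run <- run - 1 / nm
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (hi + lo >= -1e-12) hi else lo
}

# A tiny two-assembly chain fixture: root R (2 direct genes) over leaf L
# (3 direct genes).
toy_chain_edges <- function() {
  tibble::tibble(
    parent = c("R", "R", "R", "L", "L", "L"),
    child = c("L", "gR1", "gR2", "g1", "g2", "g3"),
    type = c("default", "gene", "gene", "gene", "gene", "gene")
  )
}

# Perfect binary tree of 7 assemblies, 2 genes per leaf.
toy_tree_edges <- function() {
  a <- tibble::tibble(
    parent = c("T1", "T1", "T2", "T2", "T3", "T3"),
    child = c("T2", "T3", "T4", "T5", "T6", "T7"),
    type = "default"
  )
  leaves <- c("T4", "T5", "T6", "T7")
  g <- tibble::tibble(
    parent = rep(leaves, each = 2),
    child = paste0("g", 1:8),
    type = "gene"
  )
  dplyr::bind_rows(a, g)
}

# Random hierarchy generator for property tests: random tree over
# n_assemblies, genes scattered over random assemblies (not only leaves).
random_hierarchy_edges <- function(n_assemblies, n_genes, seed) {
  set.seed(seed)
  ids <- paste0("H", seq_len(n_assemblies))
  parent <- c(NA, sapply(2:n_assemblies, function(i) sample(i - 1, 1)))
  a <- tibble::tibble(
    parent = ids[parent[-1]], child = ids[-1], type = "default"
  )
  g <- tibble::tibble(
    parent = ids[sample(n_assemblies, n_genes, replace = TRUE)],
    child = paste0("gg", seq_len(n_genes)),
    type = "gene"
  )
  # guarantee leaves carry at least one gene so fan-in > 0
  leaves <- setdiff(ids, a$parent)
  extra <- tibble::tibble(
    parent = leaves, child = paste0("lf", seq_along(leaves)), type = "gene"
  )
  dplyr::bind_rows(a, g, extra)
}

# Small deterministic genotype tensor for layer-level tests.
toy_genotypes <- function(samples, genes, seed = 1) {
  set.seed(seed)
  n <- length(samples)
  m <- length(genes)
  vnndrug:::new_genotype_tensor(
    samples, genes,
    matrix(rbinom(n * m, 1, 0.3), n, m),
    matrix(rbinom(n * m, 1, 0.2), n, m),
    matrix(rbinom(n * m, 1, 0.1), n, m)
  )
}
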