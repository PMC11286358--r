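#' Configuration for synthetic hierarchy / cohort generation
#'
#' Defaults describe the package's canonical study conditions: a 3-layer
#' binary-tree hierarchy of 7 assemblies with 15 genes per leaf (60 genes),
#' 200 samples, per-channel alteration frequencies of 0.05 (mutation), 0.03
#' (amplification) and 0.02 (deletion) — rare events of clinical-panel
#' magnitude — two causal leaf assemblies each adding 0.3 AUC when hit, a
#' baseline AUC of 0.5 and Gaussian noise with sd 0.1.
#'
#' @param n_layers Tree depth (default 3).
#' @param branching Children per internal assembly (default 2).
#' @param genes_per_leaf Genes annotated to each leaf (default 15).
#' @param n_samples Number of samples (default 200).
#' @param freq_mutation,freq_amplification,freq_deletion Per-gene,
#'   per-sample Bernoulli alteration frequencies.
#' @param causal_assemblies Ids of assemblies that drive the response
#'   (default the first and third leaves, `"S4"` and `"S6"`).
#' @param effect_size Per-assembly AUC shift when the assembly is hit; a
#'   scalar is recycled over the causal assemblies (default 0.3).
#' @param baseline_auc Response with no causal hits (default 0.5).
#' @param noise_sd Gaussian response noise (default 0.1).
#' @param saturating If `TRUE` (default) a causal assembly contributes its
#'   full effect once any of its genes is altered (convergence of rare
#'   alterations); if `FALSE` the contribution is linear in the altered-gene
#'   count.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_layers = 3, branching = 2, genes_per_leaf = 15,
                         n_samples = 200,
                         freq_mutation = 0.05, freq_amplification = 0.03,
                         freq_deletion = 0.02,
                         causal_assemblies = c("S4", "S6"),
                         effect_size = 0.3, baseline_auc = 0.5,
                         noise_sd = 0.1, saturating = TRUE, seed = 1L) {
  stopifnot(
    n_layers >= 1, branching >= 1, genes_per_leaf >= 1, n_samples >= 1,
    all(c(freq_mutation, freq_amplification, freq_deletion) >= 0),
    all(c(freq_mutation, freq_amplification, freq_deletion) <= 1),
    noise_sd >= 0
  )
  effect_size <- rep_len(effect_size, length(causal_assemblies))
  structure(
    list(
      n_layers = as.integer(n_layers), branching = as.integer(branching),
      genes_per_leaf = as.integer(genes_per_leaf),
      n_samples = as.integer(n_samples),
      freq_mutation = freq_mutation,
      freq_amplification = freq_amplification,
      freq_deletion = freq_deletion,
      causal_assemblies = causal_assemblies,
      effect_size = effect_size,
      baseline_auc = baseline_auc, noise_sd = noise_sd,
      saturating = isTRUE(saturating),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Simulate a balanced assembly hierarchy
#'
#' Builds a complete `branching`-ary tree of depth `n_layers` with assemblies
#' `S1` (root), `S2`, ... in breadth-first order, and annotates
#' `genes_per_leaf` genes (`G001`, `G002`, ...) to each leaf. The structure
#' is a deterministic function of the configuration.
#'
#' @param cfg A [synth_config()].
#' @return An annotated `assembly_hierarchy`.
#' @export
simulate_hierarchy <- function(cfg = synth_config()) {
  b <- cfg$branching
  L <- cfg$n_layers
  n_assemblies <- if (b == 1) L else (b^L - 1L) / (b - 1L)
  ids <- paste0("S", seq_len(n_assemblies))
  n_internal <- if (b == 1) L - 1L else (b^(L - 1L) - 1L) / (b - 1L)

  edges <- list()
  for (i in seq_len(n_internal)) {
    kids <- ids[(b * (i - 1L) + 2L):(b * i + 1L)]
    edges[[i]] <- tibble::tibble(parent = ids[i], child = kids, type = "default")
  }
  leaves <- ids[(n_internal + 1L):n_assemblies]
  n_genes <- length(leaves) * cfg$genes_per_leaf
  genes <- sprintf("G%03d", seq_len(n_genes))
  gene_edges <- tibble::tibble(
    parent = rep(leaves, each = cfg$genes_per_leaf),
    child = genes,
    type = "gene"
  )
  hierarchy_from_edges(dplyr::bind_rows(edges, list(gene_edges)))
}

#' Simulate binary genotype calls
#'
#' Independent Bernoulli draws per sample, gene and channel at the configured
#' frequencies; deterministic given the config seed.
#'
#' @param h An `assembly_hierarchy` supplying the gene universe/order.
#' @param cfg A [synth_config()].
#' @return A `genotype_tensor`.
#' @export
simulate_genotypes <- function(h, cfg = synth_config()) {
  h <- ensure_annotated(h)
  genes <- h$gene_universe
  n <- cfg$n_samples
  m <- length(genes)
  samples <- sprintf("SAMP%04d", seq_len(n))
  set.seed(cfg$seed)
  draw <- function(f) {
    matrix(as.numeric(stats::runif(n * m) < f), n, m)
  }
  new_genotype_tensor(
    samples, genes,
    draw(cfg$freq_mutation),
    draw(cfg$freq_amplification),
    draw(cfg$freq_deletion)
  )
}

causal_burden <- function(G, h, cfg) {
  altered <- (G$mutation + G$amplification + G$deletion) > 0
  sets <- assembly_gene_sets(h)
  burden <- purrr::map(cfg$causal_assemblies, function(id) {
    if (is.null(sets[[id]])) {
      stop("unknown causal assembly: ", id, call. = FALSE)
    }
    hits <- rowSums(altered[, G$genes %in% sets[[id]], drop = FALSE])
    if (cfg$saturating) pmin(1, hits) else hits
  })
  names(burden) <- cfg$causal_assemblies
  burden
}

#' Simulate drug responses with planted causal assemblies
#'
#' Each causal assembly contributes `effect_size` times its per-sample
#' burden — by default `min(1, number of altered genes in the assembly's
#' total gene set)`, so the response saturates once the assembly is hit at
#' all — on top of `baseline_auc`, plus Gaussian noise. The truth block
#' (per-sample burdens, effects, noise-free response) is attached so
#' recovery tests can recompute the noiseless signal exactly.
#'
#' @param G A `genotype_tensor` (from [simulate_genotypes()]).
#' @param h The `assembly_hierarchy` the genotypes were simulated on.
#' @param cfg A [synth_config()].
#' @return A response tibble (`sample`, `drug`, `auc`) with attribute
#'   `truth`: list of `causal_assemblies`, `signal_free_assemblies`
#'   (assemblies sharing no gene with any causal assembly — the valid
#'   negative controls for recovery tests), `effects`, `burden` (samples x
#'   causal matrix), `noise_free` and `baseline`.
#' @export
simulate_responses <- function(G, h, cfg = synth_config()) {
  h <- ensure_annotated(h)
  burden <- causal_burden(G, h, cfg)
  n <- length(G$samples)
  bmat <- if (length(burden) > 0) {
    do.call(cbind, burden)
  } else {
    matrix(0, n, 0)
  }
  noise_free <- cfg$baseline_auc + drop(bmat %*% cfg$effect_size)
  if (length(noise_free) == 0) noise_free <- rep(cfg$baseline_auc, n)
  set.seed(cfg$seed + 1L)
  auc <- noise_free + stats::rnorm(length(noise_free), 0, cfg$noise_sd)
  rt <- tibble::tibble(
    sample = G$samples, drug = "synthetic_drug", auc = pmax(auc, 0)
  )
  sets <- assembly_gene_sets(h)
  causal_genes <- unique(unlist(sets[cfg$causal_assemblies]))
  signal_free <- names(sets)[purrr::map_lgl(
    sets, function(g) length(intersect(g, causal_genes)) == 0
  )]
  attr(rt, "truth") <- list(
    causal_assemblies = cfg$causal_assemblies,
    # assemblies whose total gene sets share no gene with any causal
    # assembly; ancestors of causal assemblies carry the planted signal by
    # construction and are therefore not negative controls
    signal_free_assemblies = signal_free,
    effects = stats::setNames(cfg$effect_size, cfg$causal_assemblies),
    burden = bmat,
    noise_free = noise_free,
    baseline = cfg$baseline_auc
  )
  rt
}

#' Simulate a complete synthetic dataset
#'
#' @param cfg A [synth_config()].
#' @return A `synth_dataset` list: `hierarchy`, `genotypes`, `responses`
#'   (with truth attribute), `truth`, `config`.
#' @export
simulate_dataset <- function(cfg = synth_config()) {
  h <- simulate_hierarchy(cfg)
  G <- simulate_genotypes(h, cfg)
  rt <- simulate_responses(G, h, cfg)
  structure(
    list(
      hierarchy = h, genotypes = G, responses = rt,
      truth = attr(rt, "truth"), config = cfg
    ),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(
    "<synth_dataset> ", length(x$hierarchy$assemblies), " assemblies, ",
    length(x$genotypes$genes), " genes, ", length(x$genotypes$samples),
    " samples; causal: ",
    paste(x$truth$causal_assemblies, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}
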