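#' Sensitivity / resistance thresholds from predicted AUCs
#'
#' `t_low = median - k_sd * sd`, `t_high = median + k_sd * sd` (sample
#' standard deviation). `k_sd = 0` collapses both to the median, the most
#' inclusive single-threshold rule.
#'
#' @param predictions Numeric vector of predicted AUCs (length >= 2).
#' @param k_sd Number of standard deviations around the median (default 1).
#' @return A `class_thresholds` list with `t_low`, `t_high`, `rule`.
#' @export
compute_thresholds <- function(predictions, k_sd = 1) {
  stopifnot(length(predictions) >= 2, k_sd >= 0)
  med <- stats::median(predictions)
  s <- stats::sd(predictions)
  if (s == 0 && k_sd > 0) {
    warning("constant predictions: thresholds degenerate to the median")
  }
  structure(
    list(
      t_low = med - k_sd * s,
      t_high = med + k_sd * s,
      rule = if (k_sd == 0) "median" else sprintf("median+/-%gsd", k_sd)
    ),
    class = "class_thresholds"
  )
}

#' Classify predictions as sensitive / undefined / resistant
#'
#' Predictions at or below `t_low` are "sensitive", at or above `t_high`
#' "resistant", and strictly between the two "undefined". When
#' `t_low == t_high` the boundary value goes to "sensitive" and no sample is
#' undefined.
#'
#' @param predictions Numeric vector.
#' @param th A `class_thresholds` (or list with `t_low`, `t_high`).
#' @return Factor with levels `sensitive`, `undefined`, `resistant`.
#' @export
classify_response <- function(predictions, th) {
  stopifnot(th$t_low <= th$t_high)
  lab <- ifelse(
    predictions <= th$t_low, "sensitive",
    ifelse(predictions >= th$t_high, "resistant", "undefined")
  )
  factor(lab, levels = c("sensitive", "undefined", "resistant"))
}

#' Split a resistant group into partially and strongly resistant
#'
#' Median split of predicted AUC within the resistant class: predictions
#' above the within-class median are "strongly_resistant", the rest
#' (including ties with the median) "partially_resistant".
#'
#' @param predictions Numeric vector.
#' @param labels Classification factor from [classify_response()].
#' @return Character vector refining `labels`.
#' @export
split_resistant <- function(predictions, labels) {
  out <- as.character(labels)
  res <- which(out == "resistant")
  if (length(res) > 0) {
    med <- stats::median(predictions[res])
    out[res] <- ifelse(
      predictions[res] > med, "strongly_resistant", "partially_resistant"
    )
  }
  out
}

or_from_counts <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  if (sum(cells) == 0) {
    stop("all-zero contingency table; odds ratio undefined", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5 # Haldane-Anscombe
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  tibble::tibble(
    or = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    corrected = corrected
  )
}

#' Diagnostic odds ratio of a 2x2 predicted-vs-observed table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` of a table with cells a = predicted
#' sensitive & observed sensitive, b = predicted sensitive & observed
#' resistant, c = predicted resistant & observed sensitive, d = predicted
#' resistant & observed resistant. When any cell is zero, the
#' Haldane-Anscombe +0.5 correction is applied to all cells. The 95% CI is
#' the Wald interval on the log odds ratio.
#'
#' @param ct 2x2 numeric matrix of counts, or a length-4 vector `(a, b, c,
#'   d)`.
#' @return Tibble with `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
diagnostic_odds_ratio <- function(ct) {
  cells <- if (is.matrix(ct)) as.numeric(t(ct)) else as.numeric(ct)
  stopifnot(length(cells) == 4)
  or_from_counts(cells[1], cells[2], cells[3], cells[4])
}

#' Odds ratio of one binary alteration against resistance
#'
#' @param feature Binary vector (1 = alteration present).
#' @param resistant Binary vector (1 = resistant), aligned with `feature`.
#' @return Tibble as in [diagnostic_odds_ratio()].
#' @export
alteration_odds_ratio <- function(feature, resistant) {
  stopifnot(length(feature) == length(resistant))
  or_from_counts(
    sum(feature == 1 & resistant == 1),
    sum(feature == 1 & resistant == 0),
    sum(feature == 0 & resistant == 1),
    sum(feature == 0 & resistant == 0)
  )
}

#' L1-logistic ranking of alterations within an assembly
#'
#' Samples in the top `top_frac` of AUC are encoded 1 (resistant), the bottom
#' `top_frac` encoded 0 (sensitive) and the middle excluded. An L1-penalized
#' logistic regression (inverse regularization `penalty_C` in the
#' scikit-learn convention; internally `lambda = 1/(n * C)`) is fit on the
#' 3 x genes binary alteration features. Nonzero coefficients flag important
#' alterations; positive signs mark resistance-associated alterations,
#' negative signs sensitivity-associated ones.
#'
#' @param G A `genotype_tensor` restricted (or restrictable via `genes`) to
#'   the assembly's genes.
#' @param aucs Numeric AUC vector aligned with `G$samples`.
#' @param genes Optional character vector of genes to use.
#' @param top_frac Fraction defining each encoded class (default 0.3).
#' @param penalty_C Inverse regularization strength (default 0.01).
#' @return Tibble with `feature`, `gene`, `channel`, `coefficient`, sorted by
#'   absolute coefficient.
#' @export
alteration_logistic_importance <- function(G, aucs, genes = NULL,
                                           top_frac = 0.3, penalty_C = 0.01) {
  stopifnot(inherits(G, "genotype_tensor"), length(aucs) == length(G$samples))
  if (!is.null(genes)) {
    idx <- match(genes, G$genes)
    stopifnot(!anyNA(idx))
  } else {
    idx <- seq_along(G$genes)
  }
  lo <- stats::quantile(aucs, top_frac)
  hi <- stats::quantile(aucs, 1 - top_frac)
  cls <- ifelse(aucs >= hi, 1L, ifelse(aucs <= lo, 0L, NA_integer_))
  keep <- !is.na(cls)
  if (sum(cls[keep] == 1) < 10 || sum(cls[keep] == 0) < 10) {
    stop("need at least 10 samples in each encoded class", call. = FALSE)
  }
  gsub_names <- G$genes[idx]
  X <- cbind(
    G$mutation[keep, idx, drop = FALSE],
    G$amplification[keep, idx, drop = FALSE],
    G$deletion[keep, idx, drop = FALSE]
  )
  channel <- rep(c("mutation", "amplification", "deletion"), each = length(idx))
  colnames(X) <- paste(rep(gsub_names, 3), channel, sep = "_")
  n <- sum(keep)
  fit <- glmnet::glmnet(
    X, cls[keep],
    family = "binomial", alpha = 1,
    lambda = 1 / (n * penalty_C), standardize = FALSE
  )
  beta <- as.numeric(fit$beta)
  tibble::tibble(
    feature = colnames(X),
    gene = rep(gsub_names, 3),
    channel = channel,
    coefficient = beta
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$coefficient)))
}

#' Gene-level fitness z-scores from a pooled CRISPR screen
#'
#' Per replicate: guide-level (log) fold enrichments are centered on the
#' median of the nontargeting controls, averaged over each gene's guides and
#' z-scored across genes; the per-gene z is then averaged over replicates
#' (and time points, if encoded in the replicate tag).
#'
#' @param guides Data frame with columns `guide`, `gene`, `fold_change` (log
#'   scale), `replicate`, and logical `is_ntc` flagging nontargeting guides.
#' @return Tibble with `gene`, `z` (mean across replicates), `n_replicates`.
#' @export
screen_gene_scores <- function(guides) {
  stopifnot(is.data.frame(guides))
  need <- c("guide", "gene", "fold_change", "replicate", "is_ntc")
  if (!all(need %in% names(guides))) {
    stop(
      "guide table is missing column(s): ",
      paste(setdiff(need, names(guides)), collapse = ", "), call. = FALSE
    )
  }
  guides <- tibble::as_tibble(guides)
  if (!any(guides$is_ntc)) {
    stop("no nontargeting (NTC) guides; cannot normalize", call. = FALSE)
  }
  per_rep <- guides |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(
      norm_fc = .data$fold_change -
        stats::median(.data$fold_change[.data$is_ntc])
    ) |>
    dplyr::filter(!.data$is_ntc) |>
    dplyr::group_by(.data$replicate, .data$gene) |>
    dplyr::summarise(gene_fc = mean(.data$norm_fc), .groups = "drop_last") |>
    dplyr::mutate(
      z = (.data$gene_fc - mean(.data$gene_fc)) / stats::sd(.data$gene_fc)
    ) |>
    dplyr::ungroup()
  per_rep |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      z = mean(.data$z), n_replicates = dplyr::n(), .groups = "drop"
    )
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score, weight exponent 1.
gsea_es <- function(scores, in_set) {
  w <- abs(scores)
  nh <- sum(in_set)
  nm <- length(scores) - nh
  sum_w <- sum(w[in_set])
  p_hit <- cumsum(ifelse(in_set, if (sum_w > 0) w / sum_w else 1 / nh, 0))
  p_miss <- cumsum(ifelse(in_set, 0, 1 / nm))
  running <- p_hit - p_miss
  mx <- max(running)
  mn <- min(running)
  # signed maximum deviation; exact magnitude ties resolve to the positive
  # side so the score is deterministic
  if (mx + mn >= -1e-12) mx else mn
}

#' Gene-set enrichment of a ranked score list
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment (weight
#' exponent 1) of a gene set within a score-ranked gene list. Significance
#' and normalization come from seeded gene-label permutations: random sets of
#' the same size are drawn from the universe, NES is the enrichment score
#' divided by the mean magnitude of same-signed permutation scores, and the
#' p-value is the (add-one) fraction of same-signed permutation scores at
#' least as extreme.
#'
#' @param scores Named numeric vector (gene-level scores; names are genes).
#' @param gene_set Character vector; must be a nonempty proper subset of the
#'   score universe.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Tibble with `es`, `nes`, `p`, `set_size`.
#' @export
gsea_enrichment <- function(scores, gene_set, n_perm = 1000, seed = 1L) {
  stopifnot(!is.null(names(scores)), n_perm >= 1)
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  if (!all(gene_set %in% names(scores))) {
    stop("gene set contains genes outside the ranked universe", call. = FALSE)
  }
  if (length(gene_set) >= length(scores)) {
    stop("gene set must be a proper subset of the universe", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  in_set <- names(s) %in% gene_set
  es <- gsea_es(s, in_set)

  set.seed(seed)
  nh <- length(gene_set)
  null_es <- vapply(seq_len(n_perm), function(i) {
    hit <- logical(length(s))
    hit[sample.int(length(s), nh)] <- TRUE
    gsea_es(s, hit)
  }, numeric(1))

  same <- null_es[sign(null_es) == sign(es) | null_es == 0]
  nes <- if (length(same) > 0 && mean(abs(same)) > 0) {
    es / mean(abs(same))
  } else {
    NA_real_
  }
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  tibble::tibble(es = es, nes = nes, p = p, set_size = nh)
}

#' Mann-Whitney rank comparison of two score samples
#'
#' Tests whether `b` tends to exceed `a` (or the stated alternative). The
#' exact null distribution is used when both samples have at most 10
#' observations and no ties; otherwise the tie-corrected normal approximation
#' (without continuity correction) is used.
#'
#' @param a,b Numeric vectors.
#' @param alternative `"greater"` (b > a), `"less"`, or `"two.sided"`.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return Tibble with the Mann-Whitney `u` statistic (of `b` versus `a`),
#'   `p`, and the `method` used.
#' @export
rank_compare <- function(a, b, alternative = c("greater", "less", "two.sided"),
                         method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- switch(method,
    exact = TRUE,
    normal = FALSE,
    auto = length(a) <= 10 && length(b) <= 10 && !ties
  )
  if (use_exact && ties) {
    stop("exact Mann-Whitney p is unavailable with ties", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(
    b, a,
    alternative = alternative, exact = use_exact, correct = FALSE
  ))
  tibble::tibble(
    u = unname(wt$statistic),
    p = wt$p.value,
    method = if (use_exact) "exact" else "normal"
  )
}

#' Compare survival between two predicted response groups
#'
#' Applies administrative censoring at `censor_at` (events after the horizon
#' become censored at the horizon), runs the standard two-group log-rank
#' test, and estimates the hazard ratio of `group2` versus `group1` from a
#' Cox proportional-hazards fit.
#'
#' @param records Data frame with columns `sample`, `time`, `event` (0/1) and
#'   `label`.
#' @param group1,group2 Label values to compare (hazard ratio is group2 vs
#'   group1).
#' @param censor_at Optional censoring horizon in the time unit of `records`
#'   (e.g., 120 months).
#' @return Tibble with `statistic` (log-rank chi-square), `p`, `hr`,
#'   `hr_ci_low`, `hr_ci_high`, `n`, `events`.
#' @export
survival_compare <- function(records, group1, group2, censor_at = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("time", "event", "label")
  if (!all(need %in% names(records))) {
    stop(
      "survival records missing column(s): ",
      paste(setdiff(need, names(records)), collapse = ", "), call. = FALSE
    )
  }
  d <- tibble::as_tibble(records) |>
    dplyr::filter(.data$label %in% c(group1, group2))
  if (length(unique(d$label)) < 2) {
    stop("need two nonempty groups to compare", call. = FALSE)
  }
  stopifnot(all(d$time >= 0), all(d$event %in% c(0, 1)))
  if (!is.null(censor_at)) {
    over <- d$time > censor_at
    d$event[over] <- 0
    d$time[over] <- censor_at
  }
  if (sum(d$event) == 0) {
    stop("no events after censoring; survival comparison undefined",
      call. = FALSE
    )
  }
  d$grp <- factor(d$label, levels = c(group1, group2))
  sdiff <- survival::survdiff(survival::Surv(time, event) ~ grp, data = d)
  p <- stats::pchisq(sdiff$chisq, df = 1, lower.tail = FALSE)
  cox <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ grp, data = d)
  )
  ci <- suppressWarnings(stats::confint(cox))
  tibble::tibble(
    statistic = unname(sdiff$chisq),
    p = p,
    hr = unname(exp(stats::coef(cox)))[1],
    hr_ci_low = exp(ci[1, 1]),
    hr_ci_high = exp(ci[1, 2]),
    n = nrow(d),
    events = sum(d$event)
  )
}

#' Performance as a function of the number of assessed genes
#'
#' For each requested gene-set size, draws random gene subsets, masks the
#' complement as unaltered ([mask_unassessed()]), and records the Spearman
#' correlation between the ensemble prediction and the observed response.
#' Size 0 yields `NA` (constant predictions).
#'
#' @param ens A `vnn_ensemble`.
#' @param G A `genotype_tensor`.
#' @param y Observed responses aligned with `G$samples`.
#' @param sizes Integer vector of gene-subset sizes.
#' @param reps Random subsets per size (default 5).
#' @param seed Integer seed.
#' @return Tibble with `size`, `rep`, `rho`.
#' @export
gene_subsampling_curve <- function(ens, G, y, sizes, reps = 5, seed = 1L) {
  stopifnot(all(sizes <= length(G$genes)), all(sizes >= 0))
  set.seed(seed)
  purrr::map_dfr(sizes, function(sz) {
    purrr::map_dfr(seq_len(reps), function(r) {
      rho <- if (sz == 0) {
        NA_real_
      } else {
        keep <- sample(G$genes, sz)
        pred <- predict(ens, mask_unassessed(G, keep))
        suppressWarnings(stats::cor(pred, y, method = "spearman"))
      }
      tibble::tibble(size = sz, rep = r, rho = rho)
    })
  })
}
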