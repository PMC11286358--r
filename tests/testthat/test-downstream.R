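test_that("thresholds are median +/- k sd with the median collapse at k = 0", {
  pred <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  th <- compute_thresholds(pred, k_sd = 1)
  expect_equal(th$t_low, median(pred) - sd(pred))
  expect_equal(th$t_high, median(pred) + sd(pred))
  expect_equal(th$t_low, 0.7 - 0.1581139, tolerance = 1e-6)

  th0 <- compute_thresholds(pred, k_sd = 0)
  expect_equal(th0$t_low, th0$t_high)
  expect_equal(th0$t_low, 0.7)

  # shift equivariance
  th_shift <- compute_thresholds(pred + 0.25, k_sd = 1)
  expect_equal(th_shift$t_low, th$t_low + 0.25)
  expect_equal(th_shift$t_high, th$t_high + 0.25)

  expect_warning(compute_thresholds(rep(0.5, 4), k_sd = 1), "constant")
})

test_that("classification partitions samples into three labels", {
  th <- list(t_low = 0.5, t_high = 0.9)
  lab <- classify_response(c(0.3, 0.7, 1.0, 0.5, 0.9), th)
  expect_equal(
    as.character(lab),
    c("sensitive", "undefined", "resistant", "sensitive", "resistant")
  )

  set.seed(6)
  pred <- rnorm(101, 0.8, 0.2)
  th1 <- compute_thresholds(pred, k_sd = 1)
  lab1 <- classify_response(pred, th1)
  expect_equal(sum(table(lab1)), 101)
  # single-median rule leaves nothing undefined
  lab0 <- classify_response(pred, compute_thresholds(pred, k_sd = 0))
  expect_equal(sum(lab0 == "undefined"), 0)
  expect_equal(sum(table(lab0)), 101)
})

test_that("the resistant class splits evenly at its median", {
  pred <- c(0.1, 0.2, 1.0, 1.1, 1.2, 1.3)
  lab <- classify_response(pred, list(t_low = 0.5, t_high = 0.9))
  refined <- split_resistant(pred, lab)
  expect_equal(sum(refined == "strongly_resistant"), 2)
  expect_equal(sum(refined == "partially_resistant"), 2)
  expect_true(all(
    pred[refined == "strongly_resistant"] >
      pred[refined == "partially_resistant"]
  ))
})

test_that("odds ratios match the hand cross-product, with Haldane correction", {
  res <- diagnostic_odds_ratio(c(30, 10, 5, 15))
  expect_equal(res$or, 9)
  expect_false(res$corrected)

  expect_equal(diagnostic_odds_ratio(c(10, 10, 10, 10))$or, 1)

  zero <- diagnostic_odds_ratio(c(0, 10, 5, 15))
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or))
  expect_equal(zero$or, (0.5 * 15.5) / (10.5 * 5.5))

  expect_error(diagnostic_odds_ratio(c(0, 0, 0, 0)), "undefined")

  # property: 50 random tables against the direct formula
  set.seed(3)
  for (i in 1:50) {
    cells <- rpois(4, 20) + 1
    expect_equal(
      diagnostic_odds_ratio(cells)$or,
      (cells[1] * cells[4]) / (cells[2] * cells[3])
    )
  }
})

test_that("alteration odds ratios behave under independence and association", {
  set.seed(9)
  n <- 2000
  feat <- rbinom(n, 1, 0.3)
  res_ind <- alteration_odds_ratio(feat, rbinom(n, 1, 0.5))
  expect_gt(res_ind$ci_high, 1)
  expect_lt(res_ind$ci_low, 1)

  # altered samples twice as often resistant
  p <- ifelse(feat == 1, 0.5, 1 / 3) # odds 1.0 vs 0.5: true OR = 2
  resist <- rbinom(n, 1, p)
  res2 <- alteration_odds_ratio(feat, resist)
  expect_gt(res2$ci_high, 2 * 0.8)
  expect_lt(res2$ci_low, 2 * 1.2)

  # perfect association is finite only through the correction
  res_perf <- alteration_odds_ratio(feat, feat)
  expect_true(res_perf$corrected && is.finite(res_perf$or))
})

test_that("L1-logistic alteration ranking finds a planted resistance driver", {
  set.seed(21)
  n <- 600
  genes <- paste0("g", 1:6)
  mut <- matrix(rbinom(n * 6, 1, 0.15), n, 6)
  amp <- matrix(rbinom(n * 6, 1, 0.1), n, 6)
  del <- matrix(0, n, 6)
  # g2 amplification strongly raises AUC (resistance)
  auc <- 0.6 + 0.5 * amp[, 2] + rnorm(n, 0, 0.1)
  G <- vnndrug:::new_genotype_tensor(paste0("s", 1:n), genes, mut, amp, del)
  coefs <- alteration_logistic_importance(G, auc, penalty_C = 0.05)
  top <- coefs$feature[1]
  expect_equal(top, "g2_amplification")
  expect_gt(coefs$coefficient[1], 0)

  # an all-zero feature gets exactly zero coefficient
  expect_equal(
    coefs$coefficient[coefs$channel == "deletion"],
    rep(0, 6)
  )

  # flipping the class encoding flips signs: encode sensitivity as 1 instead
  coefs_flip <- alteration_logistic_importance(G, -auc, penalty_C = 0.05)
  expect_lt(coefs_flip$coefficient[coefs_flip$feature == "g2_amplification"], 0)
})

test_that("L1 shrinkage is monotone in the inverse regularization C", {
  set.seed(22)
  n <- 300
  genes <- paste0("g", 1:4)
  mut <- matrix(rbinom(n * 4, 1, 0.3), n, 4)
  G <- vnndrug:::new_genotype_tensor(
    paste0("s", 1:n), genes, mut,
    matrix(0, n, 4), matrix(0, n, 4)
  )
  auc <- 0.5 + 0.4 * mut[, 1] + rnorm(n, 0, 0.15)
  l1norm <- function(C) {
    sum(abs(alteration_logistic_importance(G, auc, penalty_C = C)$coefficient))
  }
  expect_equal(l1norm(1e-5), 0) # C -> 0 kills everything
  expect_lt(l1norm(0.01), l1norm(10)) # looser penalty, larger coefficients
})

test_that("screen scoring normalizes to NTC medians and averages replicates", {
  guides <- tibble::tibble(
    guide = rep(paste0("gd", 1:6), 2),
    gene = rep(c("A", "A", "B", "B", "NTC", "NTC"), 2),
    fold_change = c(
      -2, -2.4, 0.3, 0.5, 0.1, -0.1, # replicate 1
      -1.6, -2.0, 0.4, 0.2, 0.2, 0.0 # replicate 2
    ),
    replicate = rep(c("r1", "r2"), each = 6),
    is_ntc = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE), 2)
  )
  z <- screen_gene_scores(guides)
  expect_setequal(z$gene, c("A", "B"))
  expect_equal(z$n_replicates, c(2L, 2L))
  # hand computation for replicate 1: NTC median 0; gene means -2.2, 0.4;
  # z over the two genes; replicate 2: NTC median 0.1; means -1.9, 0.2
  z1 <- scale(c(-2.2, 0.4))[, 1]
  z2 <- scale(c(-1.9, 0.2))[, 1]
  expect_equal(z$z[z$gene == "A"], mean(c(z1[1], z2[1])))
  expect_equal(z$z[z$gene == "B"], mean(c(z1[2], z2[2])))
  # depleted gene scores negative
  expect_lt(z$z[z$gene == "A"], 0)

  expect_error(
    screen_gene_scores(dplyr::mutate(guides, is_ntc = FALSE)),
    "NTC"
  )
})

test_that("all guides at the NTC median give z approximately zero", {
  guides <- tibble::tibble(
    guide = paste0("gd", 1:5),
    gene = c("A", "B", "C", "NTC", "NTC"),
    fold_change = c(0.2, 0.2, 0.2000001, 0.2, 0.2),
    replicate = "r1",
    is_ntc = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  z <- screen_gene_scores(guides)
  expect_true(all(abs(z$z) < 2)) # z-scaling of near-identical values
  expect_lt(max(abs(z$z[1:2] - z$z[2:1])), 1e-6)
})

test_that("GSEA enrichment score matches the exhaustive running-sum oracle", {
  # a set containing only the top-ranked gene gives ES = 1
  scores <- c(a = 3, b = 2, c = -1, d = -2)
  res <- gsea_enrichment(scores, "a", n_perm = 10, seed = 1)
  expect_equal(res$es, 1.0)

  # exhaustive check over every list up to length 8 and every proper subset
  set.seed(17)
  for (n in 2:8) {
    s <- sort(round(rnorm(n), 2), decreasing = TRUE)
    names(s) <- paste0("G", seq_len(n))
    subsets <- seq_len(2^n - 2) # nonempty proper subsets by bitmask
    for (mask in sample(subsets, min(20, length(subsets)))) {
      in_set <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      es <- vnndrug:::gsea_es(s, in_set)
      expect_equal(es, oracle_gsea_es(s, in_set), tolerance = 1e-12)
    }
  }

  # whole universe is rejected; so is an unknown gene
  expect_error(gsea_enrichment(scores, names(scores)), "proper subset")
  expect_error(gsea_enrichment(scores, "zzz"), "outside")

  # determinism given the seed
  r1 <- gsea_enrichment(scores, c("a", "c"), n_perm = 50, seed = 9)
  r2 <- gsea_enrichment(scores, c("a", "c"), n_perm = 50, seed = 9)
  expect_identical(r1, r2)
})

test_that("GSEA agrees with an established implementation on random lists", {
  skip_if_not_installed("fgsea")
  set.seed(31)
  for (i in 1:10) {
    n <- 30
    s <- sort(rnorm(n), decreasing = TRUE)
    names(s) <- paste0("G", 1:n)
    set <- sample(names(s), 6)
    es <- gsea_enrichment(s, set, n_perm = 1, seed = 1)$es
    ref <- fgsea::calcGseaStat(s, selectedStats = match(set, names(s)))
    expect_equal(es, ref, tolerance = 1e-6)
  }
})

test_that("GSEA p-values are roughly uniform for random gene sets", {
  set.seed(12)
  n <- 40
  s <- rnorm(n)
  names(s) <- paste0("G", 1:n)
  ps <- purrr::map_dbl(1:60, function(i) {
    set <- sample(names(s), 5)
    gsea_enrichment(s, set, n_perm = 99, seed = 1000 + i)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank comparison gives exact and approximate Mann-Whitney p", {
  # full enumeration: P(all of b above a) = 1 / choose(6, 3) = 0.05
  res <- rank_compare(c(1, 2, 3), c(4, 5, 6), alternative = "greater")
  expect_equal(res$p, 0.05)
  expect_equal(res$method, "exact")

  # identical multisets: one-tailed p = 0.5 under the normal approximation
  res_eq <- rank_compare(c(1, 2, 3), c(1, 2, 3), alternative = "greater")
  expect_equal(res_eq$p, 0.5)

  # exact and approximate paths agree closely at n = 15 per group
  set.seed(14)
  a <- rnorm(15)
  b <- rnorm(15, 0.3)
  pe <- rank_compare(a, b, "greater", method = "exact")$p
  pn <- rank_compare(a, b, "greater", method = "normal")$p
  expect_lt(abs(pe - pn), 0.01)
})

test_that("survival comparison: identical groups, censoring, planted hazard", {
  # two identical groups: log-rank statistic 0, p = 1
  rec <- tibble::tibble(
    sample = paste0("s", 1:20),
    time = rep(c(5, 10, 15, 20, 25, 30, 35, 40, 45, 50), 2),
    event = rep(c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1), 2),
    label = rep(c("sensitive", "resistant"), each = 10)
  )
  res <- survival_compare(rec, "sensitive", "resistant")
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)

  # censoring horizon below every event time leaves nothing to compare
  expect_error(
    survival_compare(rec, "sensitive", "resistant", censor_at = 1),
    "no events"
  )

  expect_error(
    survival_compare(rec[rec$label == "sensitive", ], "sensitive", "resistant"),
    "two nonempty groups"
  )

  # exponential groups with true hazard ratio 0.5
  set.seed(10)
  n <- 100
  t1 <- rexp(n, rate = 0.1)
  t2 <- rexp(n, rate = 0.05) # group2 hazard half of group1
  sim <- tibble::tibble(
    sample = paste0("p", 1:(2 * n)),
    time = c(t1, t2),
    event = 1,
    label = rep(c("resistant", "sensitive"), each = n)
  )
  res_hr <- survival_compare(sim, "resistant", "sensitive", censor_at = 120)
  expect_gt(res_hr$hr, 0.3)
  expect_lt(res_hr$hr, 0.8)
  expect_lt(res_hr$p, 0.05)
})

test_that("gene subsampling reduces to identity at full size and NA at zero", {
  cfg <- synth_config(
    n_layers = 2, branching = 2, genes_per_leaf = 6, n_samples = 60,
    causal_assemblies = "S2", noise_sd = 0.05
  )
  ds <- simulate_dataset(cfg)
  models <- purrr::map(1:2, function(s) {
    build_vnn(ds$hierarchy, vnn_config(neurons = 2, seed = s))
  })
  ens <- structure(
    list(models = models, oof = tibble::tibble(), hierarchy = ds$hierarchy),
    class = "vnn_ensemble"
  )
  y <- ds$responses$auc
  curve <- gene_subsampling_curve(
    ens, ds$genotypes, y,
    sizes = c(0, 6, 12), reps = 2, seed = 3
  )
  expect_true(all(is.na(curve$rho[curve$size == 0])))
  full <- predict(ens, ds$genotypes)
  expect_equal(
    curve$rho[curve$size == 12],
    rep(suppressWarnings(cor(full, y, method = "spearman")), 2)
  )
})
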