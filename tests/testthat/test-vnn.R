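chain_model <- function(N = 2, seed = 3, dropout = 0, ...) {
  h <- hierarchy_from_edges(toy_chain_edges())
  build_vnn(h, vnn_config(
    neurons = N, dropout_rate = dropout, seed = seed, ...
  ))
}

test_that("block fan-in equals N*K + M and matches the graph-walk oracle", {
  h <- hierarchy_from_edges(toy_chain_edges())
  for (N in c(1, 4)) {
    m <- build_vnn(h, vnn_config(neurons = N, seed = 1))
    expect_equal(m$meta$L$fanin, 3) # leaf: M = 3
    expect_equal(m$meta$R$fanin, N * 1 + 2)
    oracle <- oracle_fanin(toy_chain_edges(), N)
    for (id in names(m$meta)) {
      expect_equal(m$meta[[id]]$fanin, unname(oracle[id]))
      expect_equal(dim(m$par$assemblies[[id]]$W), c(m$meta[[id]]$fanin, N))
    }
  }
})

test_that("construction is deterministic given the seed", {
  m1 <- chain_model(seed = 42)
  m2 <- chain_model(seed = 42)
  expect_identical(m1$par, m2$par)
  m3 <- chain_model(seed = 43)
  expect_false(identical(m1$par, m3$par))
})

test_that("dropout is placed on the deepest layers only", {
  cfg <- synth_config(n_layers = 4, branching = 2, genes_per_leaf = 3)
  h <- simulate_hierarchy(cfg)
  m <- build_vnn(h, vnn_config(dropout_rate = 0.3, dropout_top_layers = 2))
  layers <- purrr::map_int(h$assemblies, "depth_layer")
  for (id in names(m$meta)) {
    expect_equal(m$meta[[id]]$dropout, layers[[id]] >= 3, info = id)
  }
  # dropout_rate 0 disables it everywhere
  m0 <- build_vnn(h, vnn_config(dropout_rate = 0))
  expect_false(any(purrr::map_lgl(m0$meta, "dropout")))
})

test_that("an assembly with neither children nor genes is rejected", {
  edges <- tibble::tibble(
    parent = c("A", "A", "A"),
    child = c("B", "C", "g1"),
    type = c("default", "default", "gene")
  )
  # B and C are leaves with no genes
  h <- hierarchy_from_edges(edges)
  expect_error(build_vnn(h, vnn_config()), "fan-in 0")
})

test_that("all-zero input with neutral parameters propagates zeros", {
  m <- chain_model(N = 2, seed = 7)
  # neutralize: zero affine parameters, identity normalization
  m$par$gene[c("w1", "w2", "w3", "b")] <- purrr::map(
    m$par$gene[c("w1", "w2", "w3", "b")], function(v) v * 0
  )
  for (id in m$topo) {
    m$par$assemblies[[id]]$W[] <- 0
    m$par$assemblies[[id]]$b[] <- 0
    m$par$assemblies[[id]]$head_w[] <- 0
    m$par$assemblies[[id]]$head_b <- 0
  }
  G <- vnndrug:::new_genotype_tensor(
    c("s1", "s2"), m$gene_order,
    matrix(0, 2, 5), matrix(0, 2, 5), matrix(0, 2, 5)
  )
  out <- vnn_forward(m, G, training = FALSE)
  expect_equal(unname(out$root), c(0, 0))
  expect_true(all(abs(out$gene_repr) < 1e-12))
})

test_that("a hand-set two-assembly model reproduces manual matrix arithmetic", {
  m <- chain_model(N = 1, seed = 5)
  genes <- m$gene_order # g1 g2 g3 (leaf) and gR1 gR2 (root extras), order from hierarchy
  mloc <- function(g) match(g, genes)
  # hand-set every parameter
  m$par$gene$w1 <- rep(0.5, 5)
  m$par$gene$w2 <- rep(-0.25, 5)
  m$par$gene$w3 <- rep(0.1, 5)
  m$par$gene$b <- rep(0.05, 5)
  m$par$gene$gamma <- rep(1.5, 5)
  m$par$gene$beta <- rep(-0.2, 5)
  m$bn$gene$run_mean <- rep(0.1, 5)
  m$bn$gene$run_var <- rep(0.8, 5)
  WL <- matrix(c(0.3, -0.2, 0.6), 3, 1)
  WR <- matrix(c(0.4, -0.5, 0.25), 3, 1) # fan-in: leaf neuron + gR1 + gR2
  m$par$assemblies$L$W <- WL
  m$par$assemblies$L$b <- 0.1
  m$par$assemblies$R$W <- WR
  m$par$assemblies$R$b <- -0.05
  for (id in c("L", "R")) {
    m$par$assemblies[[id]]$gamma <- 1.2
    m$par$assemblies[[id]]$beta <- 0.3
    m$bn$assemblies[[id]]$run_mean <- 0.05
    m$bn$assemblies[[id]]$run_var <- 1.1
    m$par$assemblies[[id]]$head_w <- 0.9
    m$par$assemblies[[id]]$head_b <- 0.7
  }

  mut <- matrix(0, 2, 5)
  amp <- matrix(0, 2, 5)
  del <- matrix(0, 2, 5)
  mut[1, mloc("g1")] <- 1
  amp[2, mloc("g2")] <- 1
  del[2, mloc("gR1")] <- 1
  G <- vnndrug:::new_genotype_tensor(c("s1", "s2"), genes, mut, amp, del)

  out <- vnn_forward(m, G, training = FALSE)

  # manual recomputation, scalar by scalar
  eps <- 1e-5
  grep_manual <- matrix(NA_real_, 2, 5)
  for (s in 1:2) {
    for (g in 1:5) {
      lin <- 0.5 * mut[s, g] - 0.25 * amp[s, g] + 0.1 * del[s, g] + 0.05
      xhat <- (tanh(lin) - 0.1) / sqrt(0.8 + eps)
      grep_manual[s, g] <- 1.5 * xhat - 0.2
    }
  }
  expect_equal(unname(out$gene_repr), grep_manual, tolerance = 1e-6)

  leaf_in <- grep_manual[, mloc(c("g1", "g2", "g3"))]
  oL <- 1.2 * ((tanh(leaf_in %*% WL + 0.1) - 0.05) / sqrt(1.1 + eps)) + 0.3
  root_in <- cbind(oL, grep_manual[, mloc(c("gR1", "gR2"))])
  oR <- 1.2 * ((tanh(root_in %*% WR - 0.05) - 0.05) / sqrt(1.1 + eps)) + 0.3
  expect_equal(unname(out$neuron$L), unname(oL), tolerance = 1e-6)
  expect_equal(unname(out$root), drop(0.9 * oR + 0.7), tolerance = 1e-6)
  expect_equal(out$head$R, out$root) # root prediction is the root head
})

test_that("loss decomposition sums to the total and collapses correctly", {
  m <- chain_model(N = 2, seed = 9)
  G <- toy_genotypes(paste0("s", 1:8), m$gene_order, seed = 4)
  y <- runif(8)
  out <- vnn_forward(m, G, training = FALSE)
  l <- compute_loss(out, y)
  expect_equal(
    l$total, l$root_mse + m$cfg$aux_loss_weight * sum(l$aux_mse) + l$penalty,
    tolerance = 1e-10
  )

  # alpha = 0, beta = 0 collapses to the root MSE
  cfg0 <- vnn_config(neurons = 2, aux_loss_weight = 0, weight_penalty = 0, seed = 9)
  l0 <- compute_loss(out, y, cfg = cfg0, model = m)
  expect_equal(l0$total, l0$root_mse)

  # perfect heads with no penalty give zero loss
  outp <- out
  for (id in names(outp$head)) outp$head[[id]] <- y
  lp <- compute_loss(outp, y, cfg = cfg0, model = m)
  expect_equal(lp$total, 0)

  # hand-checked alpha weighting on the 2-assembly chain
  l_hand <- mean((out$head$R - y)^2) + 0.3 * mean((out$head$L - y)^2)
  expect_equal(l$total, l_hand + l$penalty, tolerance = 1e-12)

  expect_error(compute_loss(out, y[1:3]), "length")
})

test_that("analytic gradients match central finite differences", {
  m <- chain_model(N = 2, seed = 21, dropout = 0, l2_in_loss = TRUE,
                   weight_penalty = 0.01)
  G <- toy_genotypes(paste0("s", 1:12), m$gene_order, seed = 8)
  y <- runif(12)
  lg <- vnndrug:::vnn_loss_grad(m, G, y)
  h <- 1e-5

  check_leaf <- function(get, set) {
    p0 <- get(m$par)
    for (i in seq_len(min(4, length(p0)))) {
      mp <- m
      pm <- m
      v <- p0
      v[i] <- v[i] + h
      mp$par <- set(mp$par, v)
      v <- p0
      v[i] <- v[i] - h
      pm$par <- set(pm$par, v)
      fd <- (vnndrug:::vnn_loss_grad(mp, G, y)$loss$total -
        vnndrug:::vnn_loss_grad(pm, G, y)$loss$total) / (2 * h)
      an <- unname(get(lg$grad)[i])
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
  check_leaf(function(p) p$gene$w1, function(p, v) {
    p$gene$w1 <- v
    p
  })
  check_leaf(function(p) p$gene$beta, function(p, v) {
    p$gene$beta <- v
    p
  })
  check_leaf(function(p) as.numeric(p$assemblies$L$W), function(p, v) {
    p$assemblies$L$W[] <- v
    p
  })
  check_leaf(function(p) as.numeric(p$assemblies$R$W), function(p, v) {
    p$assemblies$R$W[] <- v
    p
  })
  check_leaf(function(p) p$assemblies$R$head_w, function(p, v) {
    p$assemblies$R$head_w <- v
    p
  })
  check_leaf(function(p) p$assemblies$L$gamma, function(p, v) {
    p$assemblies$L$gamma <- v
    p
  })
})

test_that("training and evaluation modes honor the dropout contract", {
  m <- chain_model(N = 3, seed = 2, dropout = 0.3)
  # chain has 2 layers; top-4 window covers both, so dropout is active
  expect_true(any(purrr::map_lgl(m$meta, "dropout")))
  G <- toy_genotypes(paste0("s", 1:16), m$gene_order, seed = 3)

  set.seed(1)
  tr1 <- vnn_forward(m, G, training = TRUE)
  set.seed(2)
  tr2 <- vnn_forward(m, G, training = TRUE)
  expect_false(identical(tr1$root, tr2$root)) # dropout noise

  ev1 <- vnn_forward(m, G, training = FALSE)
  ev2 <- vnn_forward(m, G, training = FALSE)
  expect_identical(ev1$root, ev2$root) # eval is pure
  expect_false(identical(unname(ev1$root), unname(tr1$root)))
})

test_that("eval-mode outputs permute with the sample order", {
  m <- chain_model(N = 2, seed = 13)
  G <- toy_genotypes(paste0("s", 1:10), m$gene_order, seed = 5)
  out <- vnn_forward(m, G, training = FALSE)
  perm <- sample(10)
  Gp <- vnndrug:::subset_genotypes(G, perm)
  outp <- vnn_forward(m, Gp, training = FALSE)
  expect_equal(unname(outp$root), unname(out$root[perm]), tolerance = 1e-12)
  expect_equal(
    unname(outp$neuron$L), unname(out$neuron$L[perm, , drop = FALSE]),
    tolerance = 1e-12
  )
})

test_that("gene-order mismatches are contract errors", {
  m <- chain_model()
  G <- toy_genotypes(paste0("s", 1:4), rev(m$gene_order), seed = 1)
  expect_error(vnn_forward(m, G), "gene order")
})
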