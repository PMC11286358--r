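#' Model configuration for a visible neural network
#'
#' @param neurons Number of neurons N per assembly block (default 24). Wide
#'   banks act as an internal ensemble: the block output averages many
#'   partially independent views of the same fan-in, which stabilizes
#'   held-out rank accuracy markedly at desk-scale cohort sizes.
#' @param dropout_rate Dropout probability applied to assembly-block inputs in
#'   the top `dropout_top_layers` layers during training (default 0.3).
#' @param dropout_top_layers How many of the deepest (closest-to-root) layers
#'   receive dropout (default 4).
#' @param aux_loss_weight Weight `alpha` of the auxiliary per-assembly MSE
#'   terms in the loss (default 0.3; the root term has weight 1).
#' @param weight_penalty Coefficient `beta` of the weight penalty. By default
#'   it acts as decoupled weight decay inside the AdamW update (applied to
#'   affine weights, not biases or normalization parameters); set
#'   `l2_in_loss = TRUE` to instead add `beta * sum(W^2)` to the loss.
#' @param l2_in_loss Logical; include the L2 penalty in the loss itself.
#' @param seed Integer seed for weight initialization.
#' @return A `vnn_config` list.
#' @export
vnn_config <- function(neurons = 24, dropout_rate = 0.3, dropout_top_layers = 4,
                       aux_loss_weight = 0.3, weight_penalty = 0.1,
                       l2_in_loss = FALSE, seed = 1L) {
  stopifnot(
    neurons >= 1, dropout_rate >= 0, dropout_rate < 1,
    aux_loss_weight >= 0, weight_penalty >= 0
  )
  structure(
    list(
      neurons = as.integer(neurons),
      dropout_rate = dropout_rate,
      dropout_top_layers = as.integer(dropout_top_layers),
      aux_loss_weight = aux_loss_weight,
      weight_penalty = weight_penalty,
      l2_in_loss = isTRUE(l2_in_loss),
      seed = as.integer(seed)
    ),
    class = "vnn_config"
  )
}

rowrep <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(x, gamma, beta, run_mean, run_var, training) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - rowrep(mu, n)
    v <- colMeans(xc * xc) # biased batch variance
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * rowrep(invstd, n)
    y <- xhat * rowrep(gamma, n) + rowrep(beta, n)
    list(
      y = y,
      cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
      run_mean = (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu,
      run_var = (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * v
    )
  } else {
    xhat <- (x - rowrep(run_mean, n)) * rowrep(1 / sqrt(run_var + BN_EPS), n)
    list(
      y = xhat * rowrep(gamma, n) + rowrep(beta, n),
      cache = NULL, run_mean = run_mean, run_var = run_var
    )
  }
}

bn_backward <- function(dy, cache) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rowrep(cache$gamma, n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - rowrep(s1 / n, n) - xhat * rowrep(s2 / n, n)) *
    rowrep(cache$invstd, n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Build a visible neural network from an annotated hierarchy
#'
#' Each gene gets an independent affine map from its 3 alteration bits to a
#' single value, followed by tanh and per-gene batch normalization. Each
#' assembly gets an affine block whose fan-in is the concatenation of its K
#' children's N-neuron outputs and the representations of its M additional
#' genes, followed by tanh and batch normalization; every assembly (including
#' the root) also carries an auxiliary scalar head. Weights are initialized
#' uniformly in `(-1/sqrt(fan_in), +1/sqrt(fan_in))` from the config seed, so
#' construction is deterministic.
#'
#' @param h An annotated `assembly_hierarchy` (typically already filtered to
#'   the gene panel).
#' @param cfg A [vnn_config()].
#' @param genes Optional character vector fixing the model's gene order;
#'   defaults to the hierarchy's gene universe.
#' @return A `vnn_model`.
#' @export
build_vnn <- function(h, cfg = vnn_config(), genes = NULL) {
  h <- ensure_annotated(h)
  stopifnot(inherits(cfg, "vnn_config"))
  if (is.null(genes)) genes <- h$gene_universe
  genes <- as.character(genes)
  missing_genes <- setdiff(h$gene_universe, genes)
  if (length(missing_genes) > 0) {
    stop(
      "gene order lacks ", length(missing_genes),
      " hierarchy gene(s), e.g. ", missing_genes[1], call. = FALSE
    )
  }

  topo <- topo_order(h)
  N <- cfg$neurons
  n_layers <- h$n_layers
  dropout_floor <- n_layers - cfg$dropout_top_layers + 1L

  set.seed(cfg$seed)
  m <- length(genes)
  r3 <- 1 / sqrt(3)
  par <- list(
    gene = list(
      w1 = stats::runif(m, -r3, r3),
      w2 = stats::runif(m, -r3, r3),
      w3 = stats::runif(m, -r3, r3),
      b = stats::runif(m, -r3, r3),
      gamma = rep(1, m), beta = rep(0, m)
    ),
    assemblies = list()
  )
  bn <- list(
    gene = list(run_mean = rep(0, m), run_var = rep(1, m)),
    assemblies = list()
  )
  meta <- list()

  for (id in topo) {
    a <- h$assemblies[[id]]
    fanin <- N * a$K + a$M
    if (fanin == 0) {
      stop("assembly ", id, " has fan-in 0 (no children, no genes)",
        call. = FALSE
      )
    }
    rf <- 1 / sqrt(fanin)
    rn <- 1 / sqrt(N)
    par$assemblies[[id]] <- list(
      W = matrix(stats::runif(fanin * N, -rf, rf), fanin, N),
      b = stats::runif(N, -rf, rf),
      gamma = rep(1, N), beta = rep(0, N),
      head_w = stats::runif(N, -rn, rn),
      head_b = stats::runif(1, -rn, rn)
    )
    bn$assemblies[[id]] <- list(run_mean = rep(0, N), run_var = rep(1, N))
    meta[[id]] <- list(
      children = a$children,
      gene_idx = match(a$m_genes, genes),
      fanin = fanin,
      dropout = a$depth_layer >= dropout_floor && cfg$dropout_rate > 0
    )
  }

  structure(
    list(
      hierarchy = h, gene_order = genes, topo = topo, meta = meta,
      par = par, bn = bn, cfg = cfg
    ),
    class = "vnn_model"
  )
}

#' @export
print.vnn_model <- function(x, ...) {
  np <- sum(rapply(x$par, length, how = "unlist"))
  cat(
    "<vnn_model> ", length(x$topo), " assembly blocks (N = ", x$cfg$neurons,
    "), ", length(x$gene_order), " genes, ", np, " parameters\n",
    sep = ""
  )
  invisible(x)
}

check_gene_order <- function(model, G) {
  stopifnot(inherits(model, "vnn_model"), inherits(G, "genotype_tensor"))
  if (!identical(model$gene_order, G$genes)) {
    stop("genotype gene order does not match the model's gene order",
      call. = FALSE
    )
  }
}

#' Forward pass of a visible neural network
#'
#' In training mode, batch normalization uses current-batch statistics (and
#' the returned model carries updated running statistics) and dropout is
#' active on the configured layers; in evaluation mode dropout is disabled
#' and normalization uses the stored running statistics, making the pass a
#' pure function of its inputs.
#'
#' @param model A `vnn_model`.
#' @param G A `genotype_tensor` whose gene order matches the model.
#' @param training Logical; training or evaluation mode.
#' @param keep_cache Logical; retain intermediate values for backpropagation
#'   (internal use).
#' @return A `vnn_forward` list: `gene_repr` (samples x genes), `neuron`
#'   (per-assembly samples x N matrices), `head` (per-assembly prediction
#'   vectors), `root` (the root head's predictions), plus `model` (with
#'   updated running statistics) and, if requested, `cache`.
#' @export
vnn_forward <- function(model, G, training = FALSE, keep_cache = FALSE) {
  check_gene_order(model, G)
  n <- length(G$samples)
  p <- model$cfg$dropout_rate

  lin <- G$mutation * rowrep(model$par$gene$w1, n) +
    G$amplification * rowrep(model$par$gene$w2, n) +
    G$deletion * rowrep(model$par$gene$w3, n) +
    rowrep(model$par$gene$b, n)
  tg <- tanh(lin)
  bng <- bn_forward(
    tg, model$par$gene$gamma, model$par$gene$beta,
    model$bn$gene$run_mean, model$bn$gene$run_var, training
  )
  gene_repr <- bng$y
  if (training) {
    model$bn$gene$run_mean <- bng$run_mean
    model$bn$gene$run_var <- bng$run_var
  }

  neuron <- list()
  head <- list()
  cache <- if (keep_cache) {
    list(gene = list(t = tg, bn = bng$cache), assemblies = list())
  }

  for (id in model$topo) {
    mt <- model$meta[[id]]
    pa <- model$par$assemblies[[id]]
    blocks <- c(
      unname(neuron[mt$children]),
      if (length(mt$gene_idx) > 0) {
        list(gene_repr[, mt$gene_idx, drop = FALSE])
      }
    )
    X <- do.call(cbind, blocks)
    mask <- NULL
    if (training && mt$dropout) {
      mask <- matrix(
        stats::runif(length(X)) >= p,
        nrow(X), ncol(X)
      ) / (1 - p)
      X <- X * mask
    }
    Z <- X %*% pa$W + rowrep(pa$b, n)
    Ta <- tanh(Z)
    bna <- bn_forward(
      Ta, pa$gamma, pa$beta,
      model$bn$assemblies[[id]]$run_mean,
      model$bn$assemblies[[id]]$run_var, training
    )
    O <- bna$y
    if (training) {
      model$bn$assemblies[[id]]$run_mean <- bna$run_mean
      model$bn$assemblies[[id]]$run_var <- bna$run_var
    }
    neuron[[id]] <- O
    head[[id]] <- drop(O %*% pa$head_w) + pa$head_b
    if (keep_cache) {
      cache$assemblies[[id]] <- list(
        X = X, mask = mask, t = Ta, bn = bna$cache, O = O
      )
    }
  }

  structure(
    list(
      gene_repr = gene_repr, neuron = neuron, head = head,
      root = head[[model$hierarchy$root]],
      samples = G$samples, model = model,
      cache = cache
    ),
    class = "vnn_forward"
  )
}

#' Loss of a forward pass against observed responses
#'
#' The loss aggregates mean squared error across every assembly head:
#' `MSE(root head, y) + alpha * sum over non-root assemblies of
#' MSE(aux head, y) + penalty`. The penalty term is `beta * sum(W^2)` over
#' affine weights when the model was configured with `l2_in_loss = TRUE`, and
#' 0 otherwise (the penalty then acts as decoupled weight decay during
#' optimization instead).
#'
#' @param out A `vnn_forward`.
#' @param y Numeric response vector aligned with the forward pass samples.
#' @param cfg A [vnn_config()]; defaults to the one stored in the pass.
#' @param model Optional `vnn_model` used to evaluate the in-loss penalty.
#' @return A list with `total`, `root_mse`, `aux_mse` (named per assembly),
#'   and `penalty`.
#' @export
compute_loss <- function(out, y, cfg = NULL, model = NULL) {
  stopifnot(inherits(out, "vnn_forward"))
  if (is.null(cfg)) cfg <- out$model$cfg
  if (is.null(model)) model <- out$model
  if (length(y) != length(out$root)) {
    stop("response length does not match number of samples", call. = FALSE)
  }
  mse <- function(p) mean((p - y)^2)
  root_id <- model$hierarchy$root
  root_mse <- mse(out$head[[root_id]])
  aux_ids <- setdiff(names(out$head), root_id)
  aux_mse <- purrr::map_dbl(out$head[aux_ids], mse)
  penalty <- if (cfg$l2_in_loss) {
    cfg$weight_penalty * weight_sumsq(model)
  } else {
    0
  }
  list(
    total = root_mse + cfg$aux_loss_weight * sum(aux_mse) + penalty,
    root_mse = root_mse,
    aux_mse = aux_mse,
    penalty = penalty
  )
}

weight_sumsq <- function(model) {
  g <- model$par$gene
  sum(g$w1^2) + sum(g$w2^2) + sum(g$w3^2) +
    sum(purrr::map_dbl(
      model$par$assemblies,
      function(a) sum(a$W^2) + sum(a$head_w^2)
    ))
}

zero_like <- function(x) rapply(x, function(v) v * 0, how = "replace")

# Forward (training mode, with cache) + loss + full analytic gradient.
# Returns the model with updated batch-norm running statistics so the
# training loop can thread them through.
vnn_loss_grad <- function(model, G, y) {
  out <- vnn_forward(model, G, training = TRUE, keep_cache = TRUE)
  model <- out$model
  cfg <- model$cfg
  loss <- compute_loss(out, y, cfg, model)

  n <- length(y)
  root_id <- model$hierarchy$root
  grad <- zero_like(model$par)
  dgene_repr <- matrix(0, n, length(model$gene_order))
  dneuron <- list()

  for (id in rev(model$topo)) {
    ca <- out$cache$assemblies[[id]]
    pa <- model$par$assemblies[[id]]
    mt <- model$meta[[id]]
    w_head <- if (id == root_id) 1 else cfg$aux_loss_weight
    dpred <- w_head * 2 * (out$head[[id]] - y) / n

    dO <- outer(dpred, pa$head_w)
    if (!is.null(dneuron[[id]])) dO <- dO + dneuron[[id]]
    grad$assemblies[[id]]$head_w <- drop(crossprod(ca$O, dpred))
    grad$assemblies[[id]]$head_b <- sum(dpred)

    bnb <- bn_backward(dO, ca$bn)
    grad$assemblies[[id]]$gamma <- bnb$dgamma
    grad$assemblies[[id]]$beta <- bnb$dbeta
    dZ <- bnb$dx * (1 - ca$t^2)
    grad$assemblies[[id]]$W <- crossprod(ca$X, dZ)
    grad$assemblies[[id]]$b <- colSums(dZ)
    dX <- tcrossprod(dZ, pa$W)
    if (!is.null(ca$mask)) dX <- dX * ca$mask

    off <- 0L
    N <- cfg$neurons
    for (ch in mt$children) {
      blk <- dX[, (off + 1):(off + N), drop = FALSE]
      dneuron[[ch]] <- if (is.null(dneuron[[ch]])) blk else dneuron[[ch]] + blk
      off <- off + N
    }
    if (length(mt$gene_idx) > 0) {
      dgene_repr[, mt$gene_idx] <- dgene_repr[, mt$gene_idx] +
        dX[, (off + 1):ncol(dX), drop = FALSE]
    }
  }

  bng <- bn_backward(dgene_repr, out$cache$gene$bn)
  grad$gene$gamma <- bng$dgamma
  grad$gene$beta <- bng$dbeta
  dlin <- bng$dx * (1 - out$cache$gene$t^2)
  grad$gene$w1 <- colSums(dlin * G$mutation)
  grad$gene$w2 <- colSums(dlin * G$amplification)
  grad$gene$w3 <- colSums(dlin * G$deletion)
  grad$gene$b <- colSums(dlin)

  if (cfg$l2_in_loss && cfg$weight_penalty > 0) {
    bp <- cfg$weight_penalty
    grad$gene$w1 <- grad$gene$w1 + 2 * bp * model$par$gene$w1
    grad$gene$w2 <- grad$gene$w2 + 2 * bp * model$par$gene$w2
    grad$gene$w3 <- grad$gene$w3 + 2 * bp * model$par$gene$w3
    for (id in model$topo) {
      grad$assemblies[[id]]$W <- grad$assemblies[[id]]$W +
        2 * bp * model$par$assemblies[[id]]$W
      grad$assemblies[[id]]$head_w <- grad$assemblies[[id]]$head_w +
        2 * bp * model$par$assemblies[[id]]$head_w
    }
  }

  list(loss = loss, grad = grad, model = model)
}

#' Predict drug response with a single model
#'
#' Evaluation-mode forward pass returning the root head's predictions.
#'
#' @param object A `vnn_model`.
#' @param G A `genotype_tensor`.
#' @param ... Unused.
#' @return Named numeric vector of predicted AUCs.
#' @export
predict.vnn_model <- function(object, G, ...) {
  out <- vnn_forward(object, G, training = FALSE)
  stats::setNames(out$root, G$samples)
}
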