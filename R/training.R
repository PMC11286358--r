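#' Training configuration
#'
#' @param epochs Maximum number of epochs (default 600).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate AdamW learning rate (default 5e-3).
#' @param patience Early-stopping patience in epochs on the validation
#'   score. By default effectively infinite — the full schedule always runs,
#'   matching the final-checkpoint philosophy below; set a finite value to
#'   re-enable early stopping.
#' @param warm_start Logical; initialize every head bias at the training-set
#'   mean response before the first step (default `TRUE`). Head outputs start
#'   near zero under random initialization while AUCs sit near 1, so this
#'   removes a long plateau in which the optimizer only learns the offset.
#' @param val_metric Validation criterion for early stopping, candidate
#'   scoring and (optionally) checkpoint selection: `"spearman"` (default;
#'   maximize rank correlation of root predictions with the validation
#'   responses, the unit in which these models are benchmarked) or `"loss"`
#'   (minimize the evaluation-mode data loss).
#' @param checkpoint Which weights to return when a validation set is
#'   supplied: `"final"` (default; the model at the last epoch run) or
#'   `"best"` (the epoch with the best validation score). Small validation
#'   folds make per-epoch scores noisy, so the best-scoring epoch is often a
#'   lucky outlier; the final model after a fixed schedule is the more
#'   reliable estimator at these cohort sizes.
#' @param val_every Evaluate the validation metric every this many epochs
#'   (default 5; the final epoch is always evaluated). Per-epoch validation
#'   forwards dominate runtime on small cohorts and per-epoch resolution
#'   buys nothing at these noise levels.
#' @param lr_decay_at Epoch after which the learning rate is multiplied by
#'   `lr_decay_factor` (default: two thirds of `epochs`); a cooling phase
#'   that settles the weights into a flatter, better-generalizing minimum.
#' @param lr_decay_factor Step-decay multiplier (default 0.2; set to 1 for a
#'   constant learning rate).
#' @param seed Integer seed governing minibatch shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 900, batch_size = 32, learning_rate = 5e-3,
                         patience = .Machine$integer.max, warm_start = TRUE,
                         val_metric = c("spearman", "loss"),
                         checkpoint = c("final", "best"), val_every = 5,
                         lr_decay_at = ceiling(2 * epochs / 3),
                         lr_decay_factor = 0.2, seed = 1L) {
  stopifnot(
    epochs >= 0, batch_size >= 1, learning_rate > 0, patience >= 1,
    lr_decay_factor > 0, lr_decay_factor <= 1
  )
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, patience = as.integer(patience),
      warm_start = isTRUE(warm_start),
      val_metric = match.arg(val_metric),
      checkpoint = match.arg(checkpoint),
      val_every = as.integer(val_every),
      lr_decay_at = as.integer(lr_decay_at),
      lr_decay_factor = lr_decay_factor,
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

# One AdamW step over the nested parameter structure. Decoupled weight decay
# is applied to affine weights (gene w1/w2/w3, assembly W, head_w) only —
# never to biases or batch-norm gamma/beta.
adamw_step <- function(par, grad, state, t, lr, wd,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  decayed <- c("w1", "w2", "w3", "W", "head_w")
  step <- function(p, g, m, v, nm) {
    if (is.list(p)) {
      for (k in names(p)) {
        r <- step(p[[k]], g[[k]], m[[k]], v[[k]], k)
        p[[k]] <- r$p
        m[[k]] <- r$m
        v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (nm %in% decayed && wd > 0) upd <- upd + wd * p
    list(p = p - lr * upd, m = m, v = v)
  }
  r <- step(par, grad, state$m, state$v, "")
  list(par = r$p, state = list(m = r$m, v = r$v))
}

eval_data_loss <- function(model, G, y) {
  out <- vnn_forward(model, G, training = FALSE)
  l <- compute_loss(out, y, model$cfg, model)
  l$root_mse + model$cfg$aux_loss_weight * sum(l$aux_mse)
}

# Evaluation-mode validation summary: data loss plus root-prediction rank
# correlation. The score is "lower is better" under either metric.
eval_val <- function(model, G, y, metric) {
  out <- vnn_forward(model, G, training = FALSE)
  l <- compute_loss(out, y, model$cfg, model)
  loss <- l$root_mse + model$cfg$aux_loss_weight * sum(l$aux_mse)
  rho <- suppressWarnings(stats::cor(out$root, y, method = "spearman"))
  score <- if (metric == "spearman") {
    if (is.na(rho)) Inf else -rho
  } else {
    loss
  }
  list(loss = loss, rho = rho, score = score)
}

#' Train a single visible neural network
#'
#' Minibatch AdamW optimization of the hierarchy-aggregated MSE loss. When a
#' validation set is given, the checkpoint with the best validation score
#' (rank correlation by default, evaluation-mode data loss via
#' `val_metric = "loss"`; see [train_config()]) is returned and training
#' stops early after `patience` epochs without improvement. With
#' `epochs = 0` the model is returned unchanged with an empty history.
#'
#' @param model A `vnn_model` (see [build_vnn()]).
#' @param G,y Training genotypes and responses.
#' @param G_val,y_val Optional validation genotypes and responses.
#' @param tc A [train_config()].
#' @return A `vnn_fit`: list with `model` (best checkpoint), `history`
#'   (tibble of per-epoch train/validation losses, validation rank
#'   correlation and the train-loss decomposition), `best_val_loss` and
#'   `best_val_score` (lower is better under either metric).
#' @export
train_vnn <- function(model, G, y, G_val = NULL, y_val = NULL,
                      tc = train_config()) {
  check_gene_order(model, G)
  stopifnot(length(y) == length(G$samples), length(y) > 0)
  has_val <- !is.null(G_val)
  if (has_val) stopifnot(length(y_val) == length(G_val$samples))

  if (tc$epochs == 0) {
    ev <- if (has_val) eval_val(model, G_val, y_val, tc$val_metric) else NULL
    return(structure(
      list(
        model = model,
        history = tibble::tibble(
          epoch = integer(), train_loss = numeric(), val_loss = numeric(),
          val_rho = numeric(), root_mse = numeric(), aux_mse = numeric(),
          penalty = numeric()
        ),
        best_val_loss = if (has_val) ev$loss else NA_real_,
        best_val_score = if (has_val) ev$score else NA_real_
      ),
      class = "vnn_fit"
    ))
  }

  if (isTRUE(tc$warm_start)) {
    for (id in model$topo) model$par$assemblies[[id]]$head_b <- mean(y)
  }
  wd <- if (model$cfg$l2_in_loss) 0 else model$cfg$weight_penalty
  state <- list(m = zero_like(model$par), v = zero_like(model$par))
  n <- length(y)
  t_step <- 0L
  best <- list(model = model, score = Inf, loss = Inf)
  stale <- 0L
  hist <- vector("list", tc$epochs)

  set.seed(tc$seed)
  for (epoch in seq_len(tc$epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / tc$batch_size))
    ep_loss <- 0
    ep_root <- 0
    ep_aux <- 0
    ep_pen <- 0
    for (b in batches) {
      lg <- vnn_loss_grad(model, subset_genotypes(G, b), y[b])
      model <- lg$model
      t_step <- t_step + 1L
      lr_now <- tc$learning_rate *
        if (epoch > tc$lr_decay_at) tc$lr_decay_factor else 1
      st <- adamw_step(
        model$par, lg$grad, state, t_step,
        lr = lr_now, wd = wd
      )
      model$par <- st$par
      state <- st$state
      w <- length(b) / n
      ep_loss <- ep_loss + w * lg$loss$total
      ep_root <- ep_root + w * lg$loss$root_mse
      ep_aux <- ep_aux + w * sum(lg$loss$aux_mse)
      ep_pen <- ep_pen + w * lg$loss$penalty
    }
    if (!is.finite(ep_loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch,
        call. = FALSE
      )
    }
    eval_now <- has_val &&
      (epoch %% tc$val_every == 0 || epoch == tc$epochs)
    ev <- if (eval_now) eval_val(model, G_val, y_val, tc$val_metric) else NULL
    hist[[epoch]] <- c(
      epoch = epoch, train_loss = ep_loss,
      val_loss = if (eval_now) ev$loss else NA_real_,
      val_rho = if (eval_now) ev$rho else NA_real_,
      root_mse = ep_root, aux_mse = ep_aux, penalty = ep_pen
    )
    if (eval_now) {
      if (ev$score < best$score) {
        best <- list(model = model, score = ev$score, loss = ev$loss)
        stale <- 0L
      } else {
        stale <- stale + tc$val_every
        if (stale >= tc$patience) break
      }
    }
  }

  final_ev <- if (has_val) eval_val(model, G_val, y_val, tc$val_metric) else NULL
  out <- if (!has_val) {
    list(model = model, score = NA_real_, loss = NA_real_)
  } else if (tc$checkpoint == "best") {
    best
  } else {
    # the reported score averages the last few validation evaluations:
    # a single-epoch validation score on a small fold is noisy, and model
    # selection on it is dominated by that noise
    hh <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    rhos <- hh[, "val_rho"]
    losses <- hh[, "val_loss"]
    rhos <- utils::tail(rhos[!is.na(rhos)], 5)
    losses <- utils::tail(losses[!is.na(losses)], 5)
    score <- if (tc$val_metric == "spearman") {
      if (length(rhos) == 0) Inf else -mean(rhos)
    } else {
      if (length(losses) == 0) Inf else mean(losses)
    }
    list(model = model, score = score, loss = final_ev$loss)
  }
  structure(
    list(
      model = out$model,
      history = tibble::as_tibble(as.data.frame(do.call(
        rbind, hist[!vapply(hist, is.null, logical(1))]
      ))),
      best_val_loss = out$loss,
      best_val_score = out$score
    ),
    class = "vnn_fit"
  )
}

#' Grouped 64/16/20 cross-validation splits
#'
#' Builds 5 outer folds at the group level (e.g., cell line, so replicate
#' measurements of one line never straddle a split): the 5 test sets
#' partition the groups; within each fold the non-test groups are divided
#' 80/20 into training and validation, i.e. 64% / 16% / 20% of the whole.
#' Deterministic given the seed.
#'
#' @param samples Character vector of sample ids.
#' @param groups Grouping key per sample (defaults to the sample ids, i.e.
#'   singleton groups).
#' @param seed Integer seed.
#' @param n_folds Number of outer folds (default 5).
#' @return A `split_plan`: list of folds, each with `train`, `val`, `test`
#'   sample-id vectors.
#' @export
make_grouped_splits <- function(samples, groups = samples, seed = 1L,
                                n_folds = 5L) {
  samples <- as.character(samples)
  groups <- as.character(groups)
  stopifnot(length(samples) == length(groups))
  ug <- unique(groups)
  if (length(ug) < n_folds) {
    stop(
      "need at least ", n_folds, " distinct groups; got ", length(ug),
      call. = FALSE
    )
  }
  set.seed(seed)
  ug <- sample(ug)
  fold_of <- rep(seq_len(n_folds), length.out = length(ug))
  expand <- function(gs) samples[groups %in% gs]
  folds <- purrr::map(seq_len(n_folds), function(f) {
    test_g <- ug[fold_of == f]
    rest_g <- ug[fold_of != f]
    n_val <- max(1L, round(0.2 * length(rest_g)))
    val_g <- rest_g[seq_len(n_val)]
    train_g <- rest_g[-seq_len(n_val)]
    list(train = expand(train_g), val = expand(val_g), test = expand(test_g))
  })
  structure(
    list(folds = folds, samples = samples, groups = groups, seed = seed),
    class = "split_plan"
  )
}

#' Select the best hyperparameter candidate on a validation set
#'
#' Trains one model per `(model config, train config)` candidate and returns
#' the candidate minimizing validation loss; ties are broken by candidate
#' order. A seeded list of candidates stands in as the tuning search.
#'
#' @param h Annotated `assembly_hierarchy`.
#' @param G,y Training genotypes and responses.
#' @param G_val,y_val Validation genotypes and responses.
#' @param candidates List of candidates, each
#'   `list(model = vnn_config(), train = train_config())`.
#' @param genes Optional gene order passed to [build_vnn()].
#' @return List with `index`, `candidate`, `fit` (the winning trained
#'   [train_vnn()] result) and `scores` (validation loss per candidate).
#' @export
tune_hyperparameters <- function(h, G, y, G_val, y_val, candidates,
                                 genes = NULL) {
  stopifnot(length(candidates) >= 1)
  fits <- purrr::map(candidates, function(cand) {
    model <- build_vnn(h, cand$model, genes = genes)
    train_vnn(model, G, y, G_val, y_val, cand$train)
  })
  scores <- purrr::map_dbl(fits, "best_val_score")
  best <- which.min(scores) # first minimum wins ties
  list(
    index = best, candidate = candidates[[best]], fit = fits[[best]],
    scores = scores
  )
}

#' Default hyperparameter candidates for nested cross-validation
#'
#' A compact seeded search suitable for desk-scale cohorts (hundreds of
#' samples over a handful of assemblies): wide (N = 24) assembly blocks at
#' two weight-decay strengths. Dropout is left off here — on shallow
#' hierarchies the `dropout_top_layers` window covers every layer and the
#' resulting input noise destabilizes the small-cohort fits; a dropout
#' candidate can always be added by hand via [vnn_config()].
#'
#' @param epochs,learning_rate Training-schedule values shared by all
#'   candidates.
#' @return A list of `list(model =, train =)` candidates for
#'   [tune_hyperparameters()] / [run_nested_cv()].
#' @export
default_candidates <- function(epochs = 900, learning_rate = 5e-3) {
  purrr::map(
    c(0.1, 0.3),
    function(wd) {
      list(
        model = vnn_config(
          neurons = 24, dropout_rate = 0, weight_penalty = wd
        ),
        train = train_config(epochs = epochs, learning_rate = learning_rate)
      )
    }
  )
}

#' Grouped nested cross-validation producing a five-model ensemble
#'
#' For each of the 5 outer folds: candidates are tuned on the fold's
#' train/validation split, and the winning tuned model predicts the untouched
#' test fold. Every sample receives exactly one out-of-fold prediction; the
#' 5 per-fold models form the ensemble used downstream.
#'
#' @param h Annotated `assembly_hierarchy`.
#' @param G A `genotype_tensor` over all samples.
#' @param y Numeric response vector aligned with `G$samples`.
#' @param groups Grouping key per sample (replicates of one biological sample
#'   share a group); defaults to sample ids.
#' @param candidates Hyperparameter candidates as in
#'   [tune_hyperparameters()].
#' @param seed Integer seed for the split plan and per-fold sub-seeds.
#' @return A `vnn_ensemble`: `models` (5 `vnn_model`s), `oof` (tibble of
#'   out-of-fold predictions with columns `sample`, `fold`, `observed`,
#'   `predicted`), `splits`, `chosen` (per-fold winning candidate index),
#'   `val_loss` per fold.
#' @export
run_nested_cv <- function(h, G, y, groups = G$samples, candidates, seed = 1L) {
  stopifnot(length(y) == length(G$samples))
  splits <- make_grouped_splits(G$samples, groups, seed = seed)
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, length(splits$folds))

  models <- list()
  chosen <- integer()
  val_loss <- numeric()
  oof <- vector("list", length(splits$folds))
  for (f in seq_along(splits$folds)) {
    fold <- splits$folds[[f]]
    tr <- match(fold$train, G$samples)
    va <- match(fold$val, G$samples)
    te <- match(fold$test, G$samples)
    cands <- purrr::map(candidates, function(cand) {
      cand$model$seed <- cand$model$seed + fold_seeds[f] %% 1000003L
      cand$train$seed <- cand$train$seed + fold_seeds[f] %% 999983L
      cand
    })
    tuned <- tune_hyperparameters(
      h,
      subset_genotypes(G, tr), y[tr],
      subset_genotypes(G, va), y[va],
      cands,
      genes = G$genes
    )
    # retrain the winning configuration on train + validation for the fold's
    # final model; the test fold stays untouched throughout
    win <- tuned$candidate
    trva <- c(tr, va)
    final <- train_vnn(
      build_vnn(h, win$model, genes = G$genes),
      subset_genotypes(G, trva), y[trva],
      tc = win$train
    )
    models[[f]] <- final$model
    chosen[f] <- tuned$index
    val_loss[f] <- tuned$fit$best_val_loss
    pred <- predict(final$model, subset_genotypes(G, te))
    oof[[f]] <- tibble::tibble(
      sample = fold$test, fold = f, observed = y[te], predicted = unname(pred)
    )
  }

  structure(
    list(
      models = models, oof = dplyr::bind_rows(oof), splits = splits,
      chosen = chosen, val_loss = val_loss, hierarchy = h
    ),
    class = "vnn_ensemble"
  )
}

#' Ensemble prediction: mean of the member models
#'
#' @param object A `vnn_ensemble`.
#' @param G A `genotype_tensor`.
#' @param ... Unused.
#' @return Named numeric vector: the arithmetic mean of the members'
#'   evaluation-mode root predictions.
#' @export
predict.vnn_ensemble <- function(object, G, ...) {
  preds <- purrr::map(object$models, predict, G = G)
  stats::setNames(Reduce(`+`, preds) / length(preds), G$samples)
}

#' @export
print.vnn_ensemble <- function(x, ...) {
  cat(
    "<vnn_ensemble> ", length(x$models), " models, ",
    nrow(x$oof), " out-of-fold predictions\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy an ensemble: out-of-fold predictions
#'
#' @param x A `vnn_ensemble`.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `fold`, `observed`, `predicted`.
#' @method tidy vnn_ensemble
#' @export
tidy.vnn_ensemble <- function(x, ...) x$oof

#' One-row ensemble summary
#'
#' @param x A `vnn_ensemble`.
#' @param ... Unused.
#' @return Tibble with out-of-fold Spearman correlation, RMSE, number of
#'   models and samples.
#' @method glance vnn_ensemble
#' @export
glance.vnn_ensemble <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$models),
    n_samples = nrow(x$oof),
    oof_spearman = stats::cor(
      x$oof$observed, x$oof$predicted,
      method = "spearman"
    ),
    oof_rmse = sqrt(mean((x$oof$observed - x$oof$predicted)^2))
  )
}

#' Persist / restore a trained ensemble
#'
#' @param ens A `vnn_ensemble`.
#' @param path File path.
#' @return `path` invisibly, or the restored ensemble.
#' @export
save_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "vnn_ensemble"))
  saveRDS(ens, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  ens <- readRDS(path)
  stopifnot(inherits(ens, "vnn_ensemble"))
  ens
}
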