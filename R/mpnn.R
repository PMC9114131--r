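#' Configure the message-passing neural network
#'
#' The architecture used by the baseline, the propensity classifier, and
#' both debiasing methods: `n_layers` rounds of bond-type-conditioned
#' linear messages with ReLU activation and GRU node updates (weights
#' shared across rounds), a set2set attention readout over final node
#' states, and two linear layers producing the head output.
#'
#' @param n_layers number of message-passing rounds (default 3).
#' @param hidden_dim node state width D (default 32).
#' @param s2s_steps set2set processing steps (default 3).
#' @param head one of `"regression"` (scalar output),
#'   `"binary_classification"` (probability via the logistic function),
#'   or `"feature_only"` (node states only; used as the CFR feature
#'   extractor, which has no readout).
#' @export
mpnn_config <- function(n_layers = 3L, hidden_dim = 32L, s2s_steps = 3L,
                        head = c("regression", "binary_classification",
                                 "feature_only")) {
  head <- match.arg(head)
  stopifnot(n_layers >= 1L, hidden_dim >= 1L, s2s_steps >= 1L)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 s2s_steps = as.integer(s2s_steps), head = head),
            class = "mpnn_config")
}

#' Configure the optimizer and training loop
#'
#' Adam without weight decay, mini-batches, a reduce-on-plateau learning
#' rate schedule (multiply by `lr_factor` when the validation loss has
#' not improved for `lr_patience` epochs), and selection of the
#' parameters with the lowest validation loss seen.
#'
#' @param initial_lr initial learning rate.
#' @param lr_factor plateau reduction factor (default 0.7).
#' @param lr_patience plateau patience in epochs (default 5).
#' @param batch_size mini-batch size (default 64).
#' @param max_epochs epoch budget.
#' @param val_fraction fraction of the data held out for validation.
#' @param min_lr stop training once the learning rate falls below this.
#' @param seed seed controlling initialization, the validation split and
#'   batch shuffling.
#' @export
train_config <- function(initial_lr = 1e-5, lr_factor = 0.7,
                         lr_patience = 5L, batch_size = 64L,
                         max_epochs = 200L, val_fraction = 0.2,
                         min_lr = 1e-7, seed = 1L) {
  stopifnot(initial_lr > 0, lr_factor > 0, lr_factor < 1,
            lr_patience >= 1L, batch_size >= 1L, max_epochs >= 1L,
            val_fraction >= 0, val_fraction < 1)
  structure(list(initial_lr = initial_lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction, min_lr = min_lr,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize MPNN parameters
#'
#' @param cfg an [mpnn_config].
#' @param atom_vocab atom vocabulary (defines the one-hot input width).
#' @param seed initialization seed.
#' @param bond_vocab bond vocabulary.
#' @return an `mpnn_model` holding parameters, configuration and
#'   vocabularies.
#' @export
mpnn_init <- function(cfg, atom_vocab, seed = 1L, bond_vocab = BOND_TYPES) {
  D <- cfg$hidden_dim
  params <- with_seed(seed, {
    p <- list(trunk = init_trunk(length(atom_vocab), D, length(bond_vocab)))
    if (cfg$head != "feature_only") {
      p$s2s <- init_set2set(D)
      p$head <- init_head(D, 1L)
    }
    p
  })
  structure(list(params = params, config = cfg, atom_vocab = atom_vocab,
                 bond_vocab = bond_vocab), class = "mpnn_model")
}

# full forward pass on a prepared batch; returns head output and caches
mpnn_forward_batch <- function(params, batch, cfg) {
  tf <- trunk_forward(params$trunk, batch, cfg$n_layers)
  if (cfg$head == "feature_only")
    return(list(H = tf$H, trunk = tf))
  sf <- set2set_forward(params$s2s, tf$H, batch, cfg$s2s_steps)
  hf <- head_forward(params$head, sf$qstar)
  out <- hf$out[, 1L]
  if (cfg$head == "binary_classification") out <- sigmoid_(out)
  list(out = out, raw = hf$out[, 1L], H = tf$H,
       trunk = tf, s2s = sf, head = hf)
}

#' Forward pass of an MPNN on a list of graphs
#'
#' @param model an `mpnn_model`.
#' @param graphs list of [mol_graph] objects.
#' @return numeric vector: predictions (regression) or probabilities
#'   (binary classification).
#' @export
mpnn_predict <- function(model, graphs) {
  cfg <- model$config
  out <- numeric(length(graphs))
  idx <- seq_along(graphs)
  for (chunk in split(idx, ceiling(idx / 512))) {
    batch <- build_batch(graphs[chunk], model$atom_vocab, model$bond_vocab)
    out[chunk] <- mpnn_forward_batch(model$params, batch, cfg)$out
  }
  out
}

# loss + gradients for one batch. task "regression": weighted squared
# loss mean(w * (pred - y)^2); task "classification": mean cross-entropy
# against 0/1 labels.
mpnn_loss_grad <- function(params, batch, y, w, cfg, task) {
  fw <- mpnn_forward_batch(params, batch, cfg)
  B <- batch$n_graphs
  if (task == "regression") {
    resid <- fw$out - y
    loss <- mean(w * resid^2)
    dout <- 2 * w * resid / B
  } else {
    p <- pmin(pmax(fw$out, 1e-12), 1 - 1e-12)
    loss <- -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
    dout <- w * (fw$out - y) / B   # d/draw of sigmoid cross-entropy
  }
  if (!is.finite(loss))
    stop("non-finite training loss (batch of ", B, " graphs); ",
         "check learning rate and input scaling")
  hb <- head_backward(params$head, fw$s2s$qstar, fw$head,
                      matrix(dout, ncol = 1L))
  sb <- set2set_backward(params$s2s, fw$H, batch, fw$s2s, hb$dqstar)
  tb <- trunk_backward(params$trunk, batch, fw$trunk, sb$dH)
  list(loss = loss,
       grads = list(trunk = tb, s2s = sb$grads, head = hb$grads))
}

mpnn_eval_loss <- function(params, graphs, y, w, cfg, atom_vocab,
                           bond_vocab, task) {
  tot <- 0; n <- length(graphs)
  idx <- seq_len(n)
  for (chunk in split(idx, ceiling(idx / 512))) {
    batch <- build_batch(graphs[chunk], atom_vocab, bond_vocab)
    out <- mpnn_forward_batch(params, batch, cfg)$out
    if (task == "regression") {
      tot <- tot + sum(w[chunk] * (out - y[chunk])^2)
    } else {
      p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
      tot <- tot - sum(w[chunk] * (y[chunk] * log(p) +
                                   (1 - y[chunk]) * log(1 - p)))
    }
  }
  tot / n
}

#' Train an MPNN with mini-batch Adam and plateau scheduling
#'
#' Splits off a seeded validation set, optimizes the (optionally
#' per-instance weighted) loss with Adam, reduces the learning rate on
#' validation plateaus, and returns the parameters that achieved the
#' lowest validation loss. All-ones weights give the unweighted
#' baseline objective.
#'
#' @param model an `mpnn_model` from [mpnn_init()].
#' @param graphs training graphs.
#' @param y targets (regression) or 0/1 labels (classification).
#' @param tcfg a [train_config].
#' @param weights per-instance loss weights (default all ones).
#' @param task `"regression"` or `"classification"`.
#' @param val_idx optional explicit validation indices; by default a
#'   seeded `val_fraction` subset is held out.
#' @return the model with trained parameters, plus `history` (per-epoch
#'   train/validation loss and learning rate) and `best_val`.
#' @export
mpnn_train <- function(model, graphs, y, tcfg, weights = NULL,
                       task = c("regression", "classification"),
                       val_idx = NULL) {
  task <- match.arg(task)
  cfg <- model$config
  n <- length(graphs)
  stopifnot(n >= 2L, length(y) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(is.finite(weights)), all(weights >= 0))

  if (is.null(val_idx)) {
    val_idx <- with_seed(derive_seed(tcfg$seed, 1L), {
      sample.int(n, max(1L, round(tcfg$val_fraction * n)))
    })
  }
  val <- as.integer(val_idx)
  tr <- setdiff(seq_len(n), val)

  params <- model$params
  state <- adam_state(params)
  lr <- tcfg$initial_lr
  best_val <- Inf; best_params <- params
  since_improve <- 0L
  hist <- vector("list", tcfg$max_epochs)

  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- with_seed(derive_seed(tcfg$seed, 100L + epoch), sample(tr))
    ep_loss <- 0; n_b <- 0L
    for (bidx in split(ord, ceiling(seq_along(ord) / tcfg$batch_size))) {
      batch <- build_batch(graphs[bidx], model$atom_vocab, model$bond_vocab)
      lg <- mpnn_loss_grad(params, batch, y[bidx], weights[bidx], cfg, task)
      st <- adam_step(params, lg$grads, state, lr)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + lg$loss; n_b <- n_b + 1L
    }
    val_loss <- mpnn_eval_loss(params, graphs[val], y[val], weights[val],
                               cfg, model$atom_vocab, model$bond_vocab, task)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n_b,
                                val_loss = val_loss, lr = lr)
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_params <- params; since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= tcfg$lr_patience) {
        lr <- lr * tcfg$lr_factor
        since_improve <- 0L
      }
    }
    if (lr < tcfg$min_lr) break
  }
  model$params <- best_params
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$best_val <- best_val
  model$task <- task
  model
}
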