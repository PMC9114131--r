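#' Closed-form importance weight from the weight-estimator head
#'
#' Given the two domain scores `phi = (phi0, phi1)` of a molecule and
#' its domain `d` (1 = training, 0 = test), the importance weight is the
#' reciprocal of the softmax probability of the observed domain:
#' `w = 1 / Pr(d | G) = 1 + exp(phi_(1-d) - phi_d)`. The weight is
#' always at least 1 and equals 2 at symmetric scores.
#'
#' @param phi numeric 2-vector `(phi0, phi1)` or an `n x 2` matrix.
#' @param d domain label(s) in `{0, 1}`.
#' @return weight(s) `>= 1`; the exponent is capped to avoid overflow.
#' @export
importance_weight <- function(phi, d) {
  if (is.null(dim(phi))) phi <- matrix(phi, ncol = 2L)
  stopifnot(ncol(phi) == 2L, all(d %in% c(0, 1)))
  d <- rep_len(d, nrow(phi))
  own <- phi[cbind(seq_len(nrow(phi)), d + 1L)]
  other <- phi[cbind(seq_len(nrow(phi)), 2L - d)]
  1 + exp(pmin(other - own, 700))
}

#' Initialize a CFR model
#'
#' One network with three paths sharing a feature extractor: `f_F`, the
#' MPNN trunk producing node states (no readout); `f_L`, a set2set
#' readout plus two linear layers predicting the property (used only on
#' training-domain molecules); and `f_W`, a separate set2set readout
#' plus two linear layers producing the two domain scores. The IPM path
#' compares mean-pooled `f_F` embeddings of the two domains.
#'
#' @param cfg an [mpnn_config] (its head field is ignored; the trunk is
#'   feature-only and both heads are built from `hidden_dim`).
#' @param atom_vocab,bond_vocab vocabularies.
#' @param alpha nonnegative weight of the IPM term in the objective.
#' @param seed initialization seed.
#' @return a `cfr_model`.
#' @export
cfr_init <- function(cfg, atom_vocab, alpha = 10, seed = 1L,
                     bond_vocab = BOND_TYPES) {
  stopifnot(alpha >= 0)
  D <- cfg$hidden_dim
  params <- with_seed(seed, list(
    trunk = init_trunk(length(atom_vocab), D, length(bond_vocab)),
    L = list(s2s = init_set2set(D), head = init_head(D, 1L)),
    W = list(s2s = init_set2set(D), head = init_head(D, 2L))
  ))
  structure(list(params = params, config = cfg, atom_vocab = atom_vocab,
                 bond_vocab = bond_vocab, alpha = alpha),
            class = "cfr_model")
}

softmax_rows <- function(M) {
  mx <- apply(M, 1, max)
  ex <- exp(M - mx)
  ex / rowSums(ex)
}

# forward pass of all three CFR paths on a prepared batch
cfr_forward_batch <- function(params, batch, cfg) {
  tf <- trunk_forward(params$trunk, batch, cfg$n_layers)
  sL <- set2set_forward(params$L$s2s, tf$H, batch, cfg$s2s_steps)
  hL <- head_forward(params$L$head, sL$qstar)
  sW <- set2set_forward(params$W$s2s, tf$H, batch, cfg$s2s_steps)
  hW <- head_forward(params$W$head, sW$qstar)
  pool <- mean_pool(tf$H, batch)
  list(trunk = tf, sL = sL, hL = hL, sW = sW, hW = hW,
       y_hat = hL$out[, 1L], phi = hW$out, pool = pool)
}

#' CFR batch objectives
#'
#' Computes the three objectives on one mixed-domain batch:
#' `o_property`, the importance-weighted squared loss over the labeled
#' (training-domain) molecules with weights from [importance_weight()]
#' at `d = 1` and no gradient through the weight head; `o_ipm`, the
#' Wasserstein distance between the mean-pooled embeddings of the two
#' domains; and `o_domain`, the mean softmax cross-entropy of the domain
#' scores against the domain labels.
#'
#' @param model a `cfr_model`.
#' @param graphs list of graphs in the batch.
#' @param d domain labels (1 = training, 0 = test).
#' @param y targets; only entries with `d == 1` are used (others may be
#'   `NA`).
#' @param ipm_method `"sinkhorn"` (default) or `"exact"`.
#' @return list `(o_property, o_ipm, o_domain)`.
#' @export
cfr_losses <- function(model, graphs, d, y, ipm_method = "sinkhorn") {
  if (!any(d == 1)) stop("batch contains no labeled (training-domain) molecules")
  batch <- build_batch(graphs, model$atom_vocab, model$bond_vocab)
  fw <- cfr_forward_batch(model$params, batch, model$config)
  lab <- which(d == 1)
  w <- importance_weight(fw$phi[lab, , drop = FALSE], 1)
  o_property <- mean(w * (y[lab] - fw$y_hat[lab])^2)
  o_ipm <- if (any(d == 0)) {
    ipm_wasserstein(fw$pool[d == 0, , drop = FALSE],
                    fw$pool[d == 1, , drop = FALSE], method = ipm_method)
  } else NA_real_
  p <- softmax_rows(fw$phi)
  o_domain <- -mean(log(pmax(p[cbind(seq_along(d), d + 1L)], 1e-12)))
  list(o_property = o_property, o_ipm = o_ipm, o_domain = o_domain)
}

# gradients of o_property + alpha * o_ipm wrt trunk and f_L (step A),
# and of o_domain wrt f_W (step B), on one prepared batch
cfr_step_grads <- function(params, batch, d, y, cfg, alpha, reg = 0.05) {
  fw <- cfr_forward_batch(params, batch, cfg)
  B <- batch$n_graphs
  lab <- which(d == 1)
  # --- step A: property + alpha * IPM; f_W frozen (weights constant)
  w <- importance_weight(fw$phi[lab, , drop = FALSE], 1)
  resid <- fw$y_hat[lab] - y[lab]
  o_property <- mean(w * resid^2)
  dout <- numeric(B)
  dout[lab] <- 2 * w * resid / length(lab)
  hbL <- head_backward(params$L$head, fw$sL$qstar, fw$hL,
                       matrix(dout, ncol = 1L))
  sbL <- set2set_backward(params$L$s2s, fw$trunk$H, batch, fw$sL, hbL$dqstar)
  dH <- sbL$dH
  o_ipm <- 0
  if (alpha > 0 && any(d == 0) && length(lab)) {
    gw <- ipm_wasserstein_grad(fw$pool[d == 0, , drop = FALSE],
                               fw$pool[d == 1, , drop = FALSE], reg = reg)
    o_ipm <- gw$cost
    dP <- matrix(0, B, ncol(fw$pool))
    dP[d == 0, ] <- alpha * gw$dZ0
    dP[d == 1, ] <- alpha * gw$dZ1
    dH <- dH + mean_pool_backward(dP, batch)
  }
  tb <- trunk_backward(params$trunk, batch, fw$trunk, dH)
  gradsA <- list(trunk = tb, L = list(s2s = sbL$grads, head = hbL$grads))
  # --- step B: domain cross-entropy; gradient stops at the trunk output
  p <- softmax_rows(fw$phi)
  onehot <- matrix(0, B, 2L)
  onehot[cbind(seq_len(B), d + 1L)] <- 1
  o_domain <- -mean(log(pmax(p[cbind(seq_len(B), d + 1L)], 1e-12)))
  dphi <- (p - onehot) / B
  hbW <- head_backward(params$W$head, fw$sW$qstar, fw$hW, dphi)
  sbW <- set2set_backward(params$W$s2s, fw$trunk$H, batch, fw$sW, hbW$dqstar)
  gradsB <- list(s2s = sbW$grads, head = hbW$grads)
  list(o_property = o_property, o_ipm = o_ipm, o_domain = o_domain,
       gradsA = gradsA, gradsB = gradsB)
}

#' Train a CFR model by alternating minimization
#'
#' Mini-batches are drawn jointly from the labeled training set (domain
#' 1) and the unlabeled test graphs (domain 0), stratified so every
#' batch contains both domains. For each batch, step A updates the
#' feature extractor and label predictor on
#' `o_property + alpha * o_ipm` with the weight head frozen; step B then
#' updates the weight head alone on `o_domain`. Model selection keeps
#' the parameters with the lowest validation `o_property` on a seeded
#' 20% training split; the domain head is validated on 20% of both sets.
#'
#' @param model a `cfr_model` from [cfr_init()].
#' @param train_graphs,y_train labeled training molecules.
#' @param test_graphs unlabeled test-domain molecules.
#' @param tcfg a [train_config].
#' @param sinkhorn_reg entropic regularization of the IPM estimator.
#' @return the model with trained parameters, `history`, `best_val`, and
#'   the domain classifier's held-out accuracy `domain_accuracy`.
#' @export
train_cfr <- function(model, train_graphs, y_train, test_graphs, tcfg,
                      sinkhorn_reg = 0.05) {
  cfg <- model$config
  alpha <- model$alpha
  n1 <- length(train_graphs); n0 <- length(test_graphs)
  stopifnot(n1 >= 2L, n0 >= 1L, length(y_train) == n1)

  vsplit <- with_seed(derive_seed(tcfg$seed, 5L), {
    list(valL = sample.int(n1, max(1L, round(tcfg$val_fraction * n1))),
         valD0 = sample.int(n0, max(1L, round(tcfg$val_fraction * n0))))
  })
  trL <- setdiff(seq_len(n1), vsplit$valL)
  trD0 <- setdiff(seq_len(n0), vsplit$valD0)

  params <- model$params
  stateA <- adam_state(params[c("trunk", "L")])
  stateB <- adam_state(params$W)
  lr <- tcfg$initial_lr
  best_val <- Inf; best_params <- params
  since_improve <- 0L
  hist <- vector("list", tcfg$max_epochs)
  frac1 <- length(trL) / (length(trL) + length(trD0))
  k1 <- min(length(trL), max(1L, round(tcfg$batch_size * frac1)))
  k0 <- min(length(trD0), max(1L, tcfg$batch_size - k1))

  # unweighted squared error on the held-out training molecules: the
  # importance weights evolve with f_W, so the weighted objective is not
  # comparable across epochs and would bias model selection toward
  # epochs with a weak weight head
  val_property <- function(params) {
    idx <- vsplit$valL
    tot <- 0
    for (chunk in split(idx, ceiling(seq_along(idx) / 512))) {
      b <- build_batch(train_graphs[chunk], model$atom_vocab,
                       model$bond_vocab)
      fw <- cfr_forward_batch(params, b, cfg)
      tot <- tot + sum((y_train[chunk] - fw$y_hat)^2)
    }
    tot / length(idx)
  }

  for (epoch in seq_len(tcfg$max_epochs)) {
    ords <- with_seed(derive_seed(tcfg$seed, 200L + epoch),
                      list(o1 = sample(trL), o0 = sample(trD0)))
    n_steps <- max(1L, floor(min(length(trL) / k1, length(trD0) / k0)))
    ep_loss <- 0
    for (s in seq_len(n_steps)) {
      i1 <- ords$o1[((s - 1L) * k1 + 1L):(s * k1)]
      i0 <- ords$o0[((s - 1L) * k0 + 1L):(s * k0)]
      graphs <- c(train_graphs[i1], test_graphs[i0])
      d <- c(rep(1L, length(i1)), rep(0L, length(i0)))
      y <- c(y_train[i1], rep(NA_real_, length(i0)))
      batch <- build_batch(graphs, model$atom_vocab, model$bond_vocab)
      sg <- cfr_step_grads(params, batch, d, y, cfg, alpha,
                           reg = sinkhorn_reg)
      if (!is.finite(sg$o_property + sg$o_domain))
        stop("non-finite CFR loss at epoch ", epoch,
             "; returning last good checkpoint is not possible mid-step")
      stA <- adam_step(params[c("trunk", "L")], sg$gradsA, stateA, lr)
      params$trunk <- stA$params$trunk; params$L <- stA$params$L
      stateA <- stA$state
      stB <- adam_step(params$W, sg$gradsB, stateB, lr)
      params$W <- stB$params; stateB <- stB$state
      ep_loss <- ep_loss + sg$o_property + alpha * sg$o_ipm
    }
    vloss <- val_property(params)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = ep_loss / n_steps,
                                val_loss = vloss, lr = lr)
    if (vloss < best_val - 1e-12) {
      best_val <- vloss; best_params <- params; since_improve <- 0L
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
  # domain-head accuracy on the held-out 20% of both sets
  vg <- c(train_graphs[vsplit$valL], test_graphs[vsplit$valD0])
  vd <- c(rep(1L, length(vsplit$valL)), rep(0L, length(vsplit$valD0)))
  vb <- build_batch(vg, model$atom_vocab, model$bond_vocab)
  vphi <- cfr_forward_batch(model$params, vb, cfg)$phi
  model$domain_accuracy <- mean(max.col(vphi) - 1L == vd)
  model
}

#' Predict properties with a trained CFR model
#'
#' The deliverable predictor is the composition of the feature extractor
#' and label predictor; the weight head and IPM play no role at
#' inference time.
#'
#' @param model a trained `cfr_model`.
#' @param graphs list of graphs.
#' @return numeric predictions.
#' @export
cfr_predict <- function(model, graphs) {
  cfg <- model$config
  out <- numeric(length(graphs))
  idx <- seq_along(graphs)
  for (chunk in split(idx, ceiling(idx / 512))) {
    batch <- build_batch(graphs[chunk], model$atom_vocab, model$bond_vocab)
    tf <- trunk_forward(model$params$trunk, batch, cfg$n_layers)
    sL <- set2set_forward(model$params$L$s2s, tf$H, batch, cfg$s2s_steps)
    hL <- head_forward(model$params$L$head, sL$qstar)
    out[chunk] <- hL$out[, 1L]
  }
  out
}
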