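#' Fit a propensity-score model (biased train vs unbiased test)
#'
#' Step one of inverse propensity scoring: a binary MPNN classifier is
#' fit to separate molecules of the biased training set (label 1) from
#' molecules of the unbiased test set (label 0) with cross-entropy loss.
#' Target property values are never seen: the function receives graphs
#' only. Validation is a seeded 20% of each of the two sets; the
#' best-validation model scores every training molecule, and scores are
#' clipped from below to stabilize the inverse weights.
#'
#' @param train_graphs graphs of the biased training set.
#' @param test_graphs graphs of the unbiased test set.
#' @param cfg an [mpnn_config] with `head = "binary_classification"`.
#' @param tcfg a [train_config].
#' @param atom_vocab atom vocabulary covering both sets.
#' @param clip_floor lower clipping bound for the scores (default 0.01).
#' @param bond_vocab bond vocabulary.
#' @return a `propensity_scores` object: `scores` (named vector over the
#'   training molecules, in `[clip_floor, 1]`), `accuracy` (held-out
#'   classification accuracy), `model` (the fitted classifier),
#'   `degenerate` (TRUE with a warning note if the classifier output is
#'   effectively constant).
#' @export
fit_propensity <- function(train_graphs, test_graphs, cfg, tcfg,
                           atom_vocab, clip_floor = 0.01,
                           bond_vocab = BOND_TYPES) {
  stopifnot(length(train_graphs) >= 1L, length(test_graphs) >= 1L,
            cfg$head == "binary_classification")
  graphs <- c(train_graphs, test_graphs)
  d <- c(rep(1, length(train_graphs)), rep(0, length(test_graphs)))
  # seeded 20% of each set for validation
  val_idx <- with_seed(derive_seed(tcfg$seed, 2L), {
    n1 <- length(train_graphs); n0 <- length(test_graphs)
    c(sample.int(n1, max(1L, round(tcfg$val_fraction * n1))),
      n1 + sample.int(n0, max(1L, round(tcfg$val_fraction * n0))))
  })
  model <- mpnn_init(cfg, atom_vocab, seed = derive_seed(tcfg$seed, 3L),
                     bond_vocab = bond_vocab)
  model <- mpnn_train(model, graphs, d, tcfg, task = "classification",
                      val_idx = val_idx)
  p_val <- mpnn_predict(model, graphs[val_idx])
  accuracy <- mean((p_val > 0.5) == d[val_idx])
  p_train <- mpnn_predict(model, train_graphs)
  degenerate <- sd(p_train) < 1e-8
  if (degenerate)
    warning("propensity classifier output is effectively constant")
  scores <- pmin(pmax(p_train, clip_floor), 1)
  names(scores) <- vapply(train_graphs, function(g) g$id, character(1))
  structure(list(scores = scores, accuracy = accuracy, model = model,
                 clip_floor = clip_floor, degenerate = degenerate),
            class = "propensity_scores")
}

#' @export
print.propensity_scores <- function(x, ...) {
  cat(sprintf("<propensity_scores: %d molecules, held-out accuracy %.3f%s>\n",
              length(x$scores), x$accuracy,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Inverse-propensity-scored loss
#'
#' The IPS objective: the mean over training molecules of the squared
#' error divided by the molecule's propensity score,
#' `(1/N) sum_i (y_i - yhat_i)^2 / pi_i`. With all scores equal to 1 it
#' reduces to the plain mean squared error; with correct scores it is
#' unbiased for the loss under uniform sampling from the chemical space.
#'
#' @param y observed targets.
#' @param y_hat predictions.
#' @param pi_hat propensity scores, all strictly positive.
#' @return nonnegative scalar.
#' @export
ips_objective <- function(y, y_hat, pi_hat) {
  stopifnot(length(y) == length(y_hat), length(y) == length(pi_hat))
  if (any(pi_hat <= 0)) stop("propensity scores must be strictly positive")
  mean((y - y_hat)^2 / pi_hat)
}

#' Fit the IPS-weighted property regressor
#'
#' Step two of IPS: a weighted regression with per-instance weights
#' `1 / pi_hat`, delegating to [mpnn_train()]. Validation is a seeded
#' 20% of the training set.
#'
#' @param graphs training graphs.
#' @param y training targets.
#' @param propensity a `propensity_scores` object (or a named numeric
#'   vector of scores) covering every training molecule.
#' @param cfg an [mpnn_config] with `head = "regression"`.
#' @param tcfg a [train_config].
#' @param atom_vocab,bond_vocab vocabularies.
#' @return a trained `mpnn_model`.
#' @export
fit_ips_regressor <- function(graphs, y, propensity, cfg, tcfg,
                              atom_vocab, bond_vocab = BOND_TYPES) {
  scores <- if (inherits(propensity, "propensity_scores"))
    propensity$scores else propensity
  ids <- vapply(graphs, function(g) g$id, character(1))
  pi_hat <- scores[ids]
  if (anyNA(pi_hat)) stop("missing propensity score for some training molecule")
  model <- mpnn_init(cfg, atom_vocab, seed = derive_seed(tcfg$seed, 4L),
                     bond_vocab = bond_vocab)
  mpnn_train(model, graphs, y, tcfg, weights = 1 / pi_hat,
             task = "regression")
}
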