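test_that("importance weights are reciprocal softmax probabilities", {
  expect_equal(importance_weight(c(0, 0), 1), 2)
  expect_equal(importance_weight(c(log(3), 0), 1), 4)  # Pr(d=1) = 1/4
  set.seed(13)
  phi <- matrix(rnorm(200, sd = 3), ncol = 2)
  d <- rbinom(100, 1, 0.5)
  w <- importance_weight(phi, d)
  p_soft <- exp(phi[cbind(1:100, d + 1)]) / rowSums(exp(phi))
  expect_true(all(abs(w * p_soft - 1) < 1e-9))
  expect_true(all(w >= 1))
  # overflow guard: extreme scores stay finite
  expect_true(is.finite(importance_weight(c(1e4, 0), 1)))
})

test_that("cfr_losses behave as the objectives dictate in edge regimes", {
  cfg <- tiny_mpnn_config()
  model <- cfr_init(cfg, DEFAULT_ATOM_VOCAB, alpha = 1, seed = 5)
  graphs <- list(triangle_carbon(), mixed_bond_graph(), path3_single(),
                 mol_graph(c("C", "O"), data.frame(u = 1, v = 2,
                                                   type = "double"), "co"))
  d <- c(1, 1, 0, 0)
  y <- c(1.0, -0.5, NA, NA)
  out <- cfr_losses(model, graphs, d, y, ipm_method = "exact")
  expect_true(out$o_property >= 0)
  expect_true(out$o_ipm >= 0)
  expect_true(out$o_domain > 0)

  # all-equal domain scores make every weight 2: o_property doubles the
  # unweighted squared loss
  zeroW <- model
  zeroW$params$W$head$W2 <- zeroW$params$W$head$W2 * 0
  zeroW$params$W$head$b2 <- c(0, 0)
  out0 <- cfr_losses(zeroW, graphs, d, y, ipm_method = "exact")
  batch <- chembias:::build_batch(graphs, DEFAULT_ATOM_VOCAB)
  fw <- chembias:::cfr_forward_batch(zeroW$params, batch, cfg)
  mse <- mean((y[1:2] - fw$y_hat[1:2])^2)
  expect_equal(out0$o_property, 2 * mse, tolerance = 1e-10)
  # and symmetric scores give cross-entropy log(2)
  expect_equal(out0$o_domain, log(2), tolerance = 1e-10)

  expect_error(cfr_losses(model, graphs, c(0, 0, 0, 0), y), "no labeled")
})

test_that("with zeroed weight head and alpha 0 the CFR gradient is twice the baseline gradient", {
  cfg <- tiny_mpnn_config()
  cm <- cfr_init(cfg, DEFAULT_ATOM_VOCAB, alpha = 0, seed = 8)
  cm$params$W$head$W2 <- cm$params$W$head$W2 * 0
  cm$params$W$head$b2 <- c(0, 0)
  graphs <- list(triangle_carbon(), mixed_bond_graph(), path3_single())
  d <- c(1, 1, 1)
  y <- c(0.3, -1, 2)
  batch <- chembias:::build_batch(graphs, DEFAULT_ATOM_VOCAB)
  sg <- chembias:::cfr_step_grads(cm$params, batch, d, y, cfg, alpha = 0)

  # baseline regressor with identical trunk + label-path parameters
  bm_params <- list(trunk = cm$params$trunk, s2s = cm$params$L$s2s,
                    head = cm$params$L$head)
  lg <- chembias:::mpnn_loss_grad(bm_params, batch, y, rep(1, 3), cfg,
                                  "regression")
  expect_equal(sg$o_property, 2 * lg$loss, tolerance = 1e-12)
  expect_equal(chembias:::param_flatten(sg$gradsA$trunk),
               2 * chembias:::param_flatten(lg$grads$trunk),
               tolerance = 1e-10)
  expect_equal(chembias:::param_flatten(sg$gradsA$L),
               2 * chembias:::param_flatten(list(lg$grads$s2s,
                                                 lg$grads$head)),
               tolerance = 1e-10)
})

test_that("CFR step-A gradients match finite differences including the IPM term", {
  cfg <- tiny_mpnn_config()
  cm <- cfr_init(cfg, DEFAULT_ATOM_VOCAB, alpha = 0.5, seed = 9)
  graphs <- list(triangle_carbon(), mixed_bond_graph(), path3_single(),
                 mol_graph(c("N", "O"), data.frame(u = 1, v = 2,
                                                   type = "single"), "no"))
  d <- c(1, 1, 0, 0)
  y <- c(0.3, -1, NA, NA)
  batch <- chembias:::build_batch(graphs, DEFAULT_ATOM_VOCAB)
  alpha <- 0.5
  sg <- chembias:::cfr_step_grads(cm$params, batch, d, y, cfg, alpha)
  lab <- which(d == 1)
  objective <- function(pA) {
    params <- cm$params; params$trunk <- pA$trunk; params$L <- pA$L
    fw <- chembias:::cfr_forward_batch(params, batch, cfg)
    w <- importance_weight(fw$phi[lab, , drop = FALSE], 1)
    o_prop <- mean(w * (y[lab] - fw$y_hat[lab])^2)
    o_ipm <- ipm_wasserstein(fw$pool[d == 0, , drop = FALSE],
                             fw$pool[d == 1, , drop = FALSE],
                             method = "sinkhorn")
    o_prop + alpha * o_ipm
  }
  pA <- cm$params[c("trunk", "L")]
  flat <- chembias:::param_flatten(pA)
  gflat <- chembias:::param_flatten(sg$gradsA)
  eps <- 1e-5
  for (i in seq(1, length(flat), by = 23)) {
    fd <- (objective(chembias:::param_unflatten(pA, replace(flat, i, flat[i] + eps))) -
           objective(chembias:::param_unflatten(pA, replace(flat, i, flat[i] - eps)))) /
      (2 * eps)
    # small slack: the IPM gradient holds the transport plan fixed
    expect_equal(gflat[i], fd, tolerance = 0.05)
  }
})

test_that("alternating updates touch only their own parameters", {
  ds <- generate_population(generator_config(n_molecules = 60, seed = 14))
  ds <- attach_property(ds, property_spec("y", c(mean_degree = 2)), seed = 2)
  y <- ds$properties$y
  cfg <- tiny_mpnn_config()
  cm <- cfr_init(cfg, ds$atom_vocab, alpha = 1, seed = 10)
  graphs <- ds$graphs
  d <- rep(c(1L, 0L), each = 30)
  batch <- chembias:::build_batch(graphs, ds$atom_vocab)
  sg <- chembias:::cfr_step_grads(cm$params, batch, d,
                                  ifelse(d == 1, y, NA), cfg, 1)
  # step A gradients exclude f_W; step B gradients exclude trunk and f_L
  expect_null(sg$gradsA$W)
  expect_named(sg$gradsA, c("trunk", "L"))
  expect_named(sg$gradsB, c("s2s", "head"))

  # a short training run leaves f_W unchanged by step A and vice versa:
  # verified by hashing parameters between manual alternating steps
  stA <- chembias:::adam_step(cm$params[c("trunk", "L")], sg$gradsA,
                              chembias:::adam_state(cm$params[c("trunk", "L")]),
                              1e-3)
  hash_W_before <- digest_params(cm$params$W)
  cm$params$trunk <- stA$params$trunk
  cm$params$L <- stA$params$L
  expect_identical(digest_params(cm$params$W), hash_W_before)
  hash_FL <- digest_params(cm$params[c("trunk", "L")])
  stB <- chembias:::adam_step(cm$params$W, sg$gradsB,
                              chembias:::adam_state(cm$params$W), 1e-3)
  cm$params$W <- stB$params
  expect_identical(digest_params(cm$params[c("trunk", "L")]), hash_FL)
})

test_that("cfr_predict composes the feature extractor and label predictor", {
  cfg <- tiny_mpnn_config()
  cm <- cfr_init(cfg, DEFAULT_ATOM_VOCAB, alpha = 1, seed = 11)
  graphs <- list(triangle_carbon(), mixed_bond_graph())
  pred <- cfr_predict(cm, graphs)
  # manual composition of the two sub-networks
  batch <- chembias:::build_batch(graphs, DEFAULT_ATOM_VOCAB)
  tf <- chembias:::trunk_forward(cm$params$trunk, batch, cfg$n_layers)
  sL <- chembias:::set2set_forward(cm$params$L$s2s, tf$H, batch, cfg$s2s_steps)
  manual <- unname(chembias:::head_forward(cm$params$L$head, sL$qstar)$out[, 1])
  expect_equal(pred, manual)
  expect_equal(cfr_predict(cm, graphs), pred)  # deterministic
})
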