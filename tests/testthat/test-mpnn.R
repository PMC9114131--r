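test_that("message passing matches hand linear algebra on small graphs", {
  D <- 3
  tp <- list(embed = diag(1, 5, D),
             msg = lapply(1:4, function(k) diag(k, D)),
             gru = chembias:::init_trunk(5, D)$gru)
  # isolated node: empty neighbor sum gives the zero message
  g0 <- mol_graph("C", id = "iso")
  b0 <- chembias:::build_batch(list(g0), DEFAULT_ATOM_VOCAB)
  fw0 <- chembias:::trunk_forward(tp, b0, 1L)
  expect_equal(unname(fw0$caches[[1]]$M), matrix(0, 1, D))

  # two nodes, one single bond, identity message weights: each node's
  # message equals the other's (nonnegative) initial state
  g2 <- mol_graph(c("C", "N"), data.frame(u = 1, v = 2, type = "single"))
  b2 <- chembias:::build_batch(list(g2), DEFAULT_ATOM_VOCAB)
  H0 <- b2$X %*% tp$embed
  fw2 <- chembias:::trunk_forward(tp, b2, 1L)
  expect_equal(fw2$caches[[1]]$M, H0[c(2, 1), ])

  # mixed bond types: hand-computed sum of per-type contributions
  g3 <- mol_graph(c("C", "N", "O"),
                  data.frame(u = c(1, 2), v = c(2, 3),
                             type = c("double", "triple")))
  b3 <- chembias:::build_batch(list(g3), DEFAULT_ATOM_VOCAB)
  H0 <- b3$X %*% tp$embed
  expected_m2 <- pmax(2 * H0[1, ] + 3 * H0[3, ], 0)  # W_double h_1 + W_triple h_3
  fw3 <- chembias:::trunk_forward(tp, b3, 1L)
  expect_equal(fw3$caches[[1]]$M[2, ], expected_m2, tolerance = 1e-6)
})

test_that("GRU update matches a reference cell implementation", {
  D <- 4
  set.seed(31)
  tp <- chembias:::init_trunk(2, D)
  g <- tp$gru
  # reference cell on random message/state, standard gated equations
  ref_gru <- function(m, h) {
    r <- plogis(m %*% g$W_ir + g$b_ir + h %*% g$W_hr + g$b_hr)
    z <- plogis(m %*% g$W_iz + g$b_iz + h %*% g$W_hz + g$b_hz)
    n <- tanh(m %*% g$W_in + g$b_in + r * (h %*% g$W_hn + g$b_hn))
    (1 - z) * n + z * h
  }
  # drive the trunk on a 2-node graph and compare its state update
  gph <- mol_graph(c("a", "b"), data.frame(u = 1, v = 2, type = "single"))
  b <- chembias:::build_batch(list(gph), c("a", "b"))
  fw <- chembias:::trunk_forward(tp, b, 1L)
  H0 <- b$X %*% tp$embed
  M <- fw$caches[[1]]$M
  expect_equal(fw$H, ref_gru(M, H0), tolerance = 1e-6)

  # zero input, zero hidden state, zero biases is a fixed point
  g0 <- lapply(g, function(x) x * 0)
  tp0 <- tp; tp0$gru <- g0; tp0$embed <- tp$embed * 0
  fw0 <- chembias:::trunk_forward(tp0, b, 1L)
  expect_equal(unname(fw0$H), matrix(0, 2, D))
})

test_that("readout is permutation invariant and classification is in (0,1)", {
  set.seed(7)
  cfg <- tiny_mpnn_config()
  model <- mpnn_init(cfg, DEFAULT_ATOM_VOCAB, seed = 2)
  ds <- generate_population(generator_config(n_molecules = 10, seed = 5))
  base_pred <- mpnn_predict(model, ds$graphs)
  for (rep in 1:10) {
    k <- sample(10, 1)
    g <- ds$graphs[[k]]
    n <- n_atoms(g)
    perm <- sample(n)
    nodes_p <- character(n); nodes_p[perm] <- g$nodes
    gp <- mol_graph(nodes_p,
                    data.frame(u = perm[g$edges$u], v = perm[g$edges$v],
                               type = g$edges$type), id = "perm")
    expect_equal(mpnn_predict(model, list(gp)), base_pred[k],
                 tolerance = 1e-6)
  }
  clf <- mpnn_init(tiny_mpnn_config("binary_classification"),
                   DEFAULT_ATOM_VOCAB, seed = 3)
  p <- mpnn_predict(clf, ds$graphs)
  expect_true(all(p > 0 & p < 1))
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_mpnn_config()
  model <- mpnn_init(cfg, DEFAULT_ATOM_VOCAB, seed = 3)
  graphs <- list(triangle_carbon(), mixed_bond_graph())
  batch <- chembias:::build_batch(graphs, DEFAULT_ATOM_VOCAB)
  y <- c(0.5, -1.2); w <- c(1.0, 2.0)
  lg <- chembias:::mpnn_loss_grad(model$params, batch, y, w, cfg, "regression")
  flat <- chembias:::param_flatten(model$params)
  gflat <- chembias:::param_flatten(lg$grads)
  eps <- 1e-6
  loss_at <- function(vec) {
    p <- chembias:::param_unflatten(model$params, vec)
    out <- chembias:::mpnn_forward_batch(p, batch, cfg)$out
    mean(w * (out - y)^2)
  }
  idx <- seq(1, length(flat), by = 7)  # probe a spread of parameters
  for (i in idx) {
    fd <- (loss_at(replace(flat, i, flat[i] + eps)) -
           loss_at(replace(flat, i, flat[i] - eps))) / (2 * eps)
    expect_lt(abs(gflat[i] - fd), 1e-7 + 1e-5 * abs(fd))
  }
})

test_that("training beats the mean predictor on a learnable target", {
  ds <- generate_population(generator_config(n_molecules = 200, seed = 12))
  spec <- property_spec("y", c(mean_degree = 5))
  ds <- attach_property(ds, spec, seed = 1)
  y <- ds$properties$y
  cfg <- mpnn_config(n_layers = 2, hidden_dim = 8, s2s_steps = 2)
  tcfg <- train_config(initial_lr = 1e-2, max_epochs = 25, seed = 5)
  model <- mpnn_train(mpnn_init(cfg, ds$atom_vocab, seed = 4),
                      ds$graphs, y, tcfg)
  pred <- mpnn_predict(model, ds$graphs)
  expect_lt(mae(y, pred), mae(y, rep(mean(y), length(y))))

  # loss trends down over training
  h <- model$history
  expect_lt(mean(tail(h$train_loss, 5)), mean(head(h$train_loss, 5)))
  # returned parameters achieve the best recorded validation loss
  expect_equal(model$best_val, min(h$val_loss), tolerance = 1e-10)
  expect_lte(model$best_val, h$val_loss[nrow(h)])
})

test_that("constant loss weights rescale the objective without changing it", {
  cfg <- tiny_mpnn_config()
  model <- mpnn_init(cfg, DEFAULT_ATOM_VOCAB, seed = 3)
  graphs <- list(triangle_carbon(), mixed_bond_graph(), path3_single())
  batch <- chembias:::build_batch(graphs, DEFAULT_ATOM_VOCAB)
  y <- c(1, 2, 3)
  lg1 <- chembias:::mpnn_loss_grad(model$params, batch, y, rep(1, 3), cfg,
                                   "regression")
  lg4 <- chembias:::mpnn_loss_grad(model$params, batch, y, rep(4, 3), cfg,
                                   "regression")
  expect_equal(lg4$loss, 4 * lg1$loss)
  expect_equal(chembias:::param_flatten(lg4$grads),
               4 * chembias:::param_flatten(lg1$grads))
})
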