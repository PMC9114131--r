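# Low-level neural building blocks with hand-written reverse-mode
# gradients: per-bond-type message passing, GRU node updates, a set2set
# (attention-LSTM) readout, linear heads, and Adam. Everything operates
# on a "batch" built by build_batch(): node features of all graphs
# stacked row-wise, sparse adjacency per bond type, and a graph index.

# ---- parameter utilities ---------------------------------------------------

# apply f to every numeric leaf of a nested parameter list
param_map <- function(p, f) {
  if (is.list(p)) lapply(p, param_map, f = f) else f(p)
}

param_map2 <- function(p, q, f) {
  if (is.list(p)) {
    out <- vector("list", length(p)); names(out) <- names(p)
    for (k in seq_along(p)) out[[k]] <- param_map2(p[[k]], q[[k]], f)
    out
  } else f(p, q)
}

param_zeros_like <- function(p) param_map(p, function(x) x * 0)

param_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, param_flatten), use.names = FALSE)
  else as.numeric(p)
}

param_unflatten <- function(p, vec) {
  pos <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  rec(p)
}

# Glorot-style uniform init
init_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

# ---- batch construction ----------------------------------------------------

# Stack graphs into one block structure. X: (n_nodes x V) one-hot;
# adj: per bond type a sparse (n x n) matrix with A[v, u] = 1 when u is
# a neighbor of v through that bond type (both directions of each
# undirected bond); gidx: graph index per node.
build_batch <- function(graphs, atom_vocab, bond_vocab = BOND_TYPES) {
  B <- length(graphs)
  sizes <- vapply(graphs, function(g) length(g$nodes), integer(1))
  offs <- c(0L, cumsum(sizes))
  n <- offs[B + 1L]
  X <- matrix(0, n, length(atom_vocab))
  gidx <- integer(n)
  ii <- vector("list", length(bond_vocab))
  jj <- vector("list", length(bond_vocab))
  for (b in seq_len(B)) {
    g <- graphs[[b]]
    rows <- (offs[b] + 1L):(offs[b] + sizes[b])
    X[cbind(rows, match(g$nodes, atom_vocab))] <- 1
    gidx[rows] <- b
    if (nrow(g$edges)) {
      t_id <- match(g$edges$type, bond_vocab)
      for (k in unique(t_id)) {
        sel <- t_id == k
        u <- g$edges$u[sel] + offs[b]; v <- g$edges$v[sel] + offs[b]
        ii[[k]] <- c(ii[[k]], v, u)   # receiver
        jj[[k]] <- c(jj[[k]], u, v)   # sender
      }
    }
  }
  adj <- lapply(seq_along(bond_vocab), function(k) {
    if (length(ii[[k]])) {
      Matrix::sparseMatrix(i = ii[[k]], j = jj[[k]], x = 1, dims = c(n, n))
    } else NULL
  })
  list(X = X, adj = adj, gidx = gidx, n_nodes = n, n_graphs = B,
       sizes = sizes)
}

# ---- message-passing trunk -------------------------------------------------

init_trunk <- function(n_vocab, D, n_bond_types = length(BOND_TYPES)) {
  list(
    embed = init_mat(n_vocab, D),
    msg = lapply(seq_len(n_bond_types), function(k) init_mat(D, D)),
    gru = list(W_ir = init_mat(D, D), W_iz = init_mat(D, D),
               W_in = init_mat(D, D),
               W_hr = init_mat(D, D), W_hz = init_mat(D, D),
               W_hn = init_mat(D, D),
               b_ir = numeric(D), b_iz = numeric(D), b_in = numeric(D),
               b_hr = numeric(D), b_hz = numeric(D), b_hn = numeric(D))
  )
}

# T rounds of m_v = relu(sum_{u in N(v)} W_{bond(v,u)} h_u) followed by
# a GRU update with message as input and node state as hidden state.
# Message and GRU weights are shared across rounds.
trunk_forward <- function(tp, batch, n_layers) {
  H <- batch$X %*% tp$embed
  H_list <- vector("list", n_layers + 1L)
  H_list[[1L]] <- H
  caches <- vector("list", n_layers)
  g <- tp$gru
  for (t in seq_len(n_layers)) {
    Mpre <- matrix(0, batch$n_nodes, ncol(H))
    for (k in seq_along(tp$msg)) {
      if (!is.null(batch$adj[[k]]))
        Mpre <- Mpre + as.matrix(batch$adj[[k]] %*% (H %*% tp$msg[[k]]))
    }
    M <- pmax(Mpre, 0)
    r <- sigmoid_(sweep(M %*% g$W_ir, 2, g$b_ir, "+") +
                  sweep(H %*% g$W_hr, 2, g$b_hr, "+"))
    z <- sigmoid_(sweep(M %*% g$W_iz, 2, g$b_iz, "+") +
                  sweep(H %*% g$W_hz, 2, g$b_hz, "+"))
    hn <- sweep(H %*% g$W_hn, 2, g$b_hn, "+")
    nt <- tanh(sweep(M %*% g$W_in, 2, g$b_in, "+") + r * hn)
    H_new <- (1 - z) * nt + z * H
    caches[[t]] <- list(Mpre = Mpre, M = M, r = r, z = z, hn = hn, nt = nt)
    H <- H_new
    H_list[[t + 1L]] <- H
  }
  list(H = H, H_list = H_list, caches = caches)
}

trunk_backward <- function(tp, batch, fw, dH) {
  n_layers <- length(fw$caches)
  gr <- param_zeros_like(tp)
  g <- tp$gru
  for (t in rev(seq_len(n_layers))) {
    cc <- fw$caches[[t]]
    H_in <- fw$H_list[[t]]
    M <- cc$M; r <- cc$r; z <- cc$z; nt <- cc$nt; hn <- cc$hn
    dz <- dH * (H_in - nt)
    dnt <- dH * (1 - z)
    dH_in <- dH * z
    dnt_pre <- dnt * (1 - nt^2)
    dM <- dnt_pre %*% t(g$W_in)
    gr$gru$W_in <- gr$gru$W_in + t(M) %*% dnt_pre
    gr$gru$b_in <- gr$gru$b_in + colSums(dnt_pre)
    dr <- dnt_pre * hn
    dhn <- dnt_pre * r
    dH_in <- dH_in + dhn %*% t(g$W_hn)
    gr$gru$W_hn <- gr$gru$W_hn + t(H_in) %*% dhn
    gr$gru$b_hn <- gr$gru$b_hn + colSums(dhn)
    dr_pre <- dr * r * (1 - r)
    dM <- dM + dr_pre %*% t(g$W_ir)
    gr$gru$W_ir <- gr$gru$W_ir + t(M) %*% dr_pre
    gr$gru$b_ir <- gr$gru$b_ir + colSums(dr_pre)
    dH_in <- dH_in + dr_pre %*% t(g$W_hr)
    gr$gru$W_hr <- gr$gru$W_hr + t(H_in) %*% dr_pre
    gr$gru$b_hr <- gr$gru$b_hr + colSums(dr_pre)
    dz_pre <- dz * z * (1 - z)
    dM <- dM + dz_pre %*% t(g$W_iz)
    gr$gru$W_iz <- gr$gru$W_iz + t(M) %*% dz_pre
    gr$gru$b_iz <- gr$gru$b_iz + colSums(dz_pre)
    dH_in <- dH_in + dz_pre %*% t(g$W_hz)
    gr$gru$W_hz <- gr$gru$W_hz + t(H_in) %*% dz_pre
    gr$gru$b_hz <- gr$gru$b_hz + colSums(dz_pre)
    dMpre <- dM * (cc$Mpre > 0)
    for (k in seq_along(tp$msg)) {
      if (!is.null(batch$adj[[k]])) {
        AtD <- as.matrix(Matrix::crossprod(batch$adj[[k]], dMpre))
        gr$msg[[k]] <- gr$msg[[k]] + t(H_in) %*% AtD
        dH_in <- dH_in + AtD %*% t(tp$msg[[k]])
      }
    }
    dH <- dH_in
  }
  gr$embed <- t(batch$X) %*% dH
  gr
}

# ---- set2set readout -------------------------------------------------------

init_set2set <- function(D) {
  list(W_i = init_mat(2L * D, 4L * D),
       W_h = init_mat(D, 4L * D),
       b = numeric(4L * D))
}

lstm_cell <- function(rp, x, h, c) {
  D <- ncol(h)
  G <- sweep(x %*% rp$W_i + h %*% rp$W_h, 2, rp$b, "+")
  gi <- sigmoid_(G[, 1:D, drop = FALSE])
  gf <- sigmoid_(G[, (D + 1):(2 * D), drop = FALSE])
  gg <- tanh(G[, (2 * D + 1):(3 * D), drop = FALSE])
  go <- sigmoid_(G[, (3 * D + 1):(4 * D), drop = FALSE])
  c_new <- gf * c + gi * gg
  tc <- tanh(c_new)
  h_new <- go * tc
  list(h = h_new, c = c_new, i = gi, f = gf, g = gg, o = go, tc = tc)
}

# attention-LSTM set aggregation ("set2set"): permutation-invariant
# graph-level vector q* in R^{2D} from node states H.
set2set_forward <- function(rp, H, batch, steps) {
  B <- batch$n_graphs; D <- ncol(H); gidx <- batch$gidx
  q <- matrix(0, B, D); cstate <- matrix(0, B, D)
  qstar <- matrix(0, B, 2L * D)
  caches <- vector("list", steps)
  for (t in seq_len(steps)) {
    prev <- list(x = qstar, h = q, c = cstate)
    cell <- lstm_cell(rp, qstar, q, cstate)
    q <- cell$h; cstate <- cell$c
    e <- rowSums(H * q[gidx, , drop = FALSE])
    emax <- as.numeric(tapply(e, gidx, max))[gidx]
    ex <- exp(e - emax)
    denom <- rowsum(ex, gidx)[gidx, 1L]
    a <- ex / denom
    r <- rowsum(a * H, gidx)
    rownames(r) <- NULL
    qstar <- cbind(q, r)
    caches[[t]] <- list(prev = prev, cell = cell, e = e, a = a, r = r, q = q)
  }
  list(qstar = qstar, caches = caches)
}

set2set_backward <- function(rp, H, batch, fw, dqstar) {
  steps <- length(fw$caches)
  B <- batch$n_graphs; D <- ncol(H); gidx <- batch$gidx
  gr <- param_zeros_like(rp)
  dH <- matrix(0, nrow(H), D)
  dq_carry <- matrix(0, B, D)
  dc_carry <- matrix(0, B, D)
  for (t in rev(seq_len(steps))) {
    cc <- fw$caches[[t]]
    dq <- dqstar[, 1:D, drop = FALSE] + dq_carry
    dr <- dqstar[, (D + 1):(2 * D), drop = FALSE]
    # r = sum_v a_v h_v per graph
    da <- rowSums(H * dr[gidx, , drop = FALSE])
    dH <- dH + cc$a * dr[gidx, , drop = FALSE]
    # softmax over nodes within each graph
    s <- rowsum(cc$a * da, gidx)[gidx, 1L]
    de <- cc$a * (da - s)
    # e_v = <h_v, q_g>
    dH <- dH + de * cc$q[gidx, , drop = FALSE]
    dq <- dq + rowsum(de * H, gidx)
    # LSTM cell backward
    cell <- cc$cell; prev <- cc$prev
    do <- dq * cell$tc
    dc <- dc_carry + dq * cell$o * (1 - cell$tc^2)
    di <- dc * cell$g
    dg <- dc * cell$i
    df <- dc * prev$c
    dc_carry <- dc * cell$f
    dG <- cbind(di * cell$i * (1 - cell$i),
                df * cell$f * (1 - cell$f),
                dg * (1 - cell$g^2),
                do * cell$o * (1 - cell$o))
    gr$W_i <- gr$W_i + t(prev$x) %*% dG
    gr$W_h <- gr$W_h + t(prev$h) %*% dG
    gr$b <- gr$b + colSums(dG)
    dqstar <- dG %*% t(rp$W_i)          # grad wrt q*_{t-1}
    dq_carry <- dG %*% t(rp$W_h)        # grad wrt hidden q_{t-1}
  }
  list(grads = gr, dH = dH)
}

# ---- two-linear-layer head -------------------------------------------------

init_head <- function(D, n_out) {
  list(W1 = init_mat(2L * D, D), b1 = numeric(D),
       W2 = init_mat(D, n_out), b2 = numeric(n_out))
}

head_forward <- function(hp, qstar) {
  a1 <- sweep(qstar %*% hp$W1, 2, hp$b1, "+")
  z1 <- pmax(a1, 0)
  out <- sweep(z1 %*% hp$W2, 2, hp$b2, "+")
  list(out = out, a1 = a1, z1 = z1)
}

head_backward <- function(hp, qstar, fw, dout) {
  gr <- param_zeros_like(hp)
  gr$W2 <- t(fw$z1) %*% dout
  gr$b2 <- colSums(dout)
  dz1 <- dout %*% t(hp$W2)
  da1 <- dz1 * (fw$a1 > 0)
  gr$W1 <- t(qstar) %*% da1
  gr$b1 <- colSums(da1)
  dqstar <- da1 %*% t(hp$W1)
  list(grads = gr, dqstar = dqstar)
}

# mean pooling of node states per graph (used by the IPM path)
mean_pool <- function(H, batch) {
  rowsum(H, batch$gidx) / batch$sizes
}

mean_pool_backward <- function(dP, batch) {
  dP[batch$gidx, , drop = FALSE] / batch$sizes[batch$gidx]
}

# ---- Adam optimizer --------------------------------------------------------

adam_state <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- param_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
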