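# Wasserstein distance between two embedding point clouds with uniform
# marginals and Euclidean ground cost. Two estimators: entropic
# (Sinkhorn, differentiable, used during CFR training) and exact
# (assignment-based, used for testing and diagnostics).

euclidean_cost <- function(X, Y) {
  x2 <- rowSums(X^2); y2 <- rowSums(Y^2)
  d2 <- outer(x2, y2, "+") - 2 * X %*% t(Y)
  sqrt(pmax(d2, 0))
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# log-domain Sinkhorn with uniform marginals. Returns the sharp
# transport cost <P, C> (reported as the distance), the plan, and the
# entropy-regularized objective value, whose exact gradient with
# respect to C is the plan itself (Danskin on the regularized problem).
sinkhorn_plan <- function(C, reg = 0.05, n_iter = 200L, tol = 1e-9) {
  n <- nrow(C); m <- ncol(C)
  la <- -log(n); lb <- -log(m)
  alpha <- numeric(n); beta <- numeric(m)
  for (it in seq_len(n_iter)) {
    alpha_new <- reg * (la - logsumexp_rows(sweep(-C, 2, beta, "+") / reg))
    beta_new <- reg * (lb - logsumexp_rows(t(sweep(-C, 1, alpha_new, "+")) / reg))
    if (max(abs(alpha_new - alpha)) < tol && max(abs(beta_new - beta)) < tol) {
      alpha <- alpha_new; beta <- beta_new
      break
    }
    alpha <- alpha_new; beta <- beta_new
  }
  logP <- (outer(alpha, beta, "+") - C) / reg
  P <- exp(logP)
  # <P,C> + reg * KL(P || a x b)
  kl <- sum(P * (logP - la - lb)) - sum(P) + 1
  list(cost = sum(P * C), plan = P, reg_value = sum(P * C) + reg * kl)
}

# O(n^3) Hungarian algorithm for a square min-cost assignment
hungarian_assignment <- function(C) {
  n <- nrow(C)
  # index 1 corresponds to the virtual 0 column/row of the classic
  # potential-based formulation
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- C[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)  # assign[j] = row matched to column j
  for (j in seq_len(n)) assign[j] <- p[j + 1L]
  assign
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# exact OT with uniform marginals via replication to a square assignment
# problem (valid since an optimal plan can be taken at a vertex of the
# Birkhoff polytope after replication)
exact_ot_cost <- function(C) {
  n <- nrow(C); m <- ncol(C)
  L <- n * m / gcd2(n, m)
  if (L > 512)
    stop("exact Wasserstein mode is intended for small clouds ",
         "(replicated size ", L, " > 512); use the sinkhorn estimator")
  ri <- rep(seq_len(n), each = L / n)
  rj <- rep(seq_len(m), each = L / m)
  CC <- C[ri, rj, drop = FALSE]
  assign <- hungarian_assignment(CC)
  sum(CC[cbind(assign, seq_len(L))]) / L
}

#' Wasserstein distance between two embedding clouds
#'
#' Optimal-transport distance between the empirical distributions of two
#' point clouds (rows are points) with uniform marginals and Euclidean
#' ground cost. The `"sinkhorn"` estimator solves the
#' entropy-regularized problem in the log domain and is the
#' differentiable estimator used inside CFR training; it carries a small
#' upward regularization bias. The `"exact"` estimator solves the
#' unregularized problem for small clouds by replicating points to a
#' square assignment problem.
#'
#' @param Z0,Z1 numeric matrices with the same number of columns.
#' @param method `"sinkhorn"` or `"exact"`.
#' @param reg entropic regularization strength (sinkhorn only).
#' @param n_iter maximum Sinkhorn iterations.
#' @return nonnegative scalar distance (the transport cost).
#' @export
ipm_wasserstein <- function(Z0, Z1, method = c("sinkhorn", "exact"),
                            reg = 0.05, n_iter = 200L) {
  method <- match.arg(method)
  Z0 <- as.matrix(Z0); Z1 <- as.matrix(Z1)
  stopifnot(nrow(Z0) >= 1L, nrow(Z1) >= 1L, ncol(Z0) == ncol(Z1))
  C <- euclidean_cost(Z0, Z1)
  if (method == "exact") exact_ot_cost(C)
  else sinkhorn_plan(C, reg = reg, n_iter = n_iter)$cost
}

# sinkhorn cost plus gradients wrt both clouds. The gradient is that of
# the entropy-regularized objective, for which the optimal plan is the
# exact cost-matrix gradient; the sharp cost <P,C> is returned for
# reporting.
ipm_wasserstein_grad <- function(Z0, Z1, reg = 0.05, n_iter = 200L,
                                 eps = 1e-9) {
  C <- euclidean_cost(Z0, Z1)
  sp <- sinkhorn_plan(C, reg = reg, n_iter = n_iter)
  P <- sp$plan
  Cs <- pmax(C, eps)
  W <- P / Cs
  # d cost / d z0_i = sum_j P_ij (z0_i - z1_j) / C_ij
  dZ0 <- Z0 * rowSums(W) - W %*% Z1
  dZ1 <- Z1 * colSums(W) - t(W) %*% Z0
  list(cost = sp$cost, reg_value = sp$reg_value, dZ0 = dZ0, dZ1 = dZ1)
}
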