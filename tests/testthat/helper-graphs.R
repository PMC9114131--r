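# small hand-built graphs reused across tests

triangle_carbon <- function() {
  mol_graph(c("C", "C", "C"),
            data.frame(u = c(1, 1, 2), v = c(2, 3, 3),
                       type = rep("single", 3)), id = "tri")
}

path3_single <- function() {
  mol_graph(c("C", "C", "C"),
            data.frame(u = c(1, 2), v = c(2, 3),
                       type = c("single", "single")), id = "p3")
}

mixed_bond_graph <- function() {
  # 4 bonds, 2 double
  mol_graph(c("C", "C", "N", "O", "H"),
            data.frame(u = c(1, 2, 3, 4), v = c(2, 3, 4, 5),
                       type = c("double", "single", "double", "single")),
            id = "mix")
}

tiny_mpnn_config <- function(head = "regression") {
  mpnn_config(n_layers = 2L, hidden_dim = 4L, s2s_steps = 2L, head = head)
}

# fingerprint of a parameter tree for frozen-parameter checks
digest_params <- function(p) sum(chembias:::param_flatten(p) *
                                 seq_along(chembias:::param_flatten(p)))

# brute-force exact OT between equal-size clouds by permutation search
brute_force_ot <- function(A, B) {
  n <- nrow(A)
  stopifnot(n == nrow(B), n <= 6)
  C <- as.matrix(chembias:::euclidean_cost(A, B))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(C[cbind(seq_len(n), p)]), numeric(1))) / n
}
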