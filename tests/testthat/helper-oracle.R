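# Brute-force oracles: full joint probability arrays built to satisfy
# conditional independence by construction, and direct conditionals read
# off the joint. These never call the combination formulas they check.

# random probability vector of length n (Dirichlet-ish via normalized
# uniforms, kept away from exact zeros)
rand_simplex <- function(n) {
  x <- stats::runif(n, 0.05, 1)
  x / sum(x)
}

# joint P(E1, ..., Ek, C) with all evidence variables conditionally
# independent given C: P(c) * prod_k P(e_k | c).
# returns array with dims (n_e[1], ..., n_e[k], n_c)
rand_ci_joint <- function(n_e, n_c) {
  p_c <- rand_simplex(n_c)
  cond <- lapply(n_e, function(m) {
    vapply(seq_len(n_c), function(j) rand_simplex(m), numeric(m))
  })  # each: m x n_c, columns P(E|C=c_j)
  joint <- array(0, dim = c(n_e, n_c))
  idx <- as.matrix(expand.grid(lapply(c(n_e, n_c), seq_len)))
  k <- length(n_e)
  vals <- apply(idx, 1L, function(ix) {
    c_j <- ix[k + 1L]
    p_c[c_j] * prod(vapply(seq_len(k),
                           function(q) cond[[q]][ix[q], c_j], 0))
  })
  joint[idx] <- vals
  joint
}

# direct P(C | E1=e1, ..., Ek=ek) from a joint array (last dim = C)
direct_conditional_c <- function(joint, e_idx) {
  k <- length(e_idx)
  slice <- do.call(`[`, c(list(joint), as.list(e_idx),
                          list(TRUE), list(drop = FALSE)))
  v <- as.numeric(slice)
  v / sum(v)
}

# marginal posterior P(C | Eq = e) from the joint, marginalizing the
# other evidence variables
marginal_posterior_c <- function(joint, q, e) {
  nd <- length(dim(joint))
  p_qc <- apply(joint, c(q, nd), sum)  # n_eq x n_c
  p_qc[e, ] / sum(p_qc[e, ])
}

# prior P(C)
prior_c <- function(joint) {
  nd <- length(dim(joint))
  apply(joint, nd, sum)
}

# name states "s1", "s2", ... so label-matching code can be exercised
pv_named <- function(x, prefix = "s") {
  prob_vector(stats::setNames(x, paste0(prefix, seq_along(x))))
}
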