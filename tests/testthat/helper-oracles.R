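# Independent brute-force oracles: plain double loops over bead pairs,
# written directly from the energy definitions and kept free of any package
# internals so they can pin the vectorized implementations.

oracle_bonded <- function(conf, k, r0) {
  u <- 0
  for (i in seq_len(nrow(conf) - 1)) {
    r <- sqrt(sum((conf[i + 1, ] - conf[i, ])^2))
    u <- u + k * (r - r0)^2
  }
  u
}

oracle_softcore <- function(conf, d, eps, cap) {
  rcut <- 2^(1 / 6) * d
  u <- 0
  n <- nrow(conf)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 2) next
    r <- sqrt(sum((conf[j, ] - conf[i, ])^2))
    if (r < rcut) {
      ulj <- if (r == 0) Inf else 4 * eps * ((d / r)^12 - (d / r)^6) + eps
      u <- u + cap * tanh(ulj / cap)
    }
  }
  u
}

oracle_collapse <- function(conf, alpha, eta, rc, same_half_only = FALSE,
                            split = nrow(conf) %/% 2) {
  u <- 0
  n <- nrow(conf)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 2) next
    if (same_half_only) {
      half_i <- if (i <= split) 1 else 2   # split is 0-based; rows 1..split
      half_j <- if (j <= split) 1 else 2
      if (half_i != half_j) next
    }
    r <- sqrt(sum((conf[j, ] - conf[i, ])^2))
    u <- u + alpha / 2 * (1 + tanh(eta * (rc - r)))
  }
  u
}

random_conformation <- function(n, spread = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(n * 3, -spread, spread), n, 3)
}

straight_chain <- function(n, spacing) {
  cbind((seq_len(n) - 1) * spacing, 0, 0)
}

# small deterministic trace for preprocessing tests
toy_trace <- function(n = 5, seed = 1, label = "WT", missing = integer(0)) {
  set.seed(seed)
  pos <- matrix(stats::runif(n * 3, 0, 600), n, 3)
  pos[missing, ] <- NA_real_
  tadfold:::new_cell_trace("toy", pos, label)
}
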