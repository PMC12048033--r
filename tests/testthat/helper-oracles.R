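# Independent brute-force oracles used to pin down expected values.

# ARI by explicit O(n^2) pair counting
ari_brute <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  n11 <- sum(same_a[up] & same_b[up])
  n00 <- sum(!same_a[up] & !same_b[up])
  n10 <- sum(same_a[up] & !same_b[up])
  n01 <- sum(!same_a[up] & same_b[up])
  total <- n * (n - 1) / 2
  expected <- (n11 + n10) * (n11 + n01) / total
  mx <- ((n11 + n10) + (n11 + n01)) / 2
  if (mx == expected) return(1)
  (n11 - expected) / (mx - expected)
}

# Benjamini-Hochberg step-up from its definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by enumerating all tables with fixed margins
fisher_brute <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small phantom population reused across tests
tiny_pop <- function(noise = 0, n = 10, k = 2, grid = c(12, 12, 12),
                     seed = 3, ...) {
  make_phantom_population(phantom_config(grid_shape = grid, n_subjects = n,
                                         k_true = k, noise_sigma = noise,
                                         seed = seed, ...))
}

# random positive-semidefinite tensor (6 unique elements)
random_psd6 <- function() {
  A <- matrix(stats::rnorm(9), 3)
  S <- crossprod(A) * 1e-3
  c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3])
}

sym_from6 <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}
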