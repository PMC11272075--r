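# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures are stored.

# small all-true-mask grid for plumbing tests
tiny_grid <- function(dims = c(4, 4, 4), mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  masked_grid(mask, diag(4))
}

# a separable noiseless cohort: each component has at least one pure
# subject (load row = e_j scaled), which makes the factorization unique
separable_cohort <- function(grid, r = 3, n = 30, seed = 11) {
  D <- generate_components(grid, r, seed = seed)
  set.seed(seed + 1)
  g <- matrix(rgamma(n * r, shape = 0.5), n, r)
  L <- g / rowSums(g) * runif(n, 0.5, 1)
  L[seq_len(r), ] <- diag(0.9, r)       # pure subjects
  X <- L %*% D
  list(X = X, L = L, D = D)
}

# exhaustive active-set oracle for min ||x - l D||^2, l >= 0, sum(l) <= 1:
# enumerate every support set, with and without the sum cap active, solve
# the corresponding equality system, keep the best feasible candidate
oracle_capped_ls <- function(D, x) {
  r <- nrow(D)
  G <- tcrossprod(D)
  cc <- as.numeric(D %*% x)
  obj <- function(l) sum((x - as.numeric(crossprod(D, l)))^2)
  best <- list(val = obj(numeric(r)), l = numeric(r))
  for (S in seq_len(2^r - 1)) {
    idx <- which(bitwAnd(S, 2^(seq_len(r) - 1)) > 0)
    k <- length(idx)
    for (eq in c(FALSE, TRUE)) {
      l <- numeric(r)
      sol <- if (!eq) {
        tryCatch(solve(G[idx, idx, drop = FALSE], cc[idx]),
                 error = function(e) NULL)
      } else {
        K <- rbind(cbind(2 * G[idx, idx, drop = FALSE], 1),
                   c(rep(1, k), 0))
        s <- tryCatch(solve(K, c(2 * cc[idx], 1)), error = function(e) NULL)
        if (is.null(s)) NULL else s[seq_len(k)]
      }
      if (is.null(sol)) next
      l[idx] <- sol
      if (any(l < -1e-12) || sum(l) > 1 + 1e-12) next
      v <- obj(l)
      if (v < best$val - 1e-14) best <- list(val = v, l = l)
    }
  }
  best$l
}

expect_monotone_trace <- function(trace, rel = 1e-9) {
  expect_true(all(diff(trace) <= rel * max(abs(trace[1]), 1)))
}
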