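test_that("objective and reconstruction MAE match naive recomputation", {
  set.seed(21)
  # exact factorization, no penalty -> exactly zero
  L <- matrix(runif(8 * 2), 8, 2); D <- matrix(runif(2 * 10), 2, 10)
  expect_identical(minvol_objective(L %*% D, L, D, lambda = 0, delta = 1), 0)
  expect_identical(reconstruction_mae(L %*% D, L, D), 0)

  # r = 1: logdet term is log(||d||^2 + delta)
  d <- matrix(runif(6), 1, 6); l <- matrix(runif(4), 4, 1)
  X <- l %*% d + 0.1
  expect_equal(minvol_objective(X, l, d, lambda = 1, delta = 0.5),
               sum((X - l %*% d)^2) + log(sum(d^2) + 0.5),
               tolerance = 1e-12)

  # random instance vs naive double loops
  X <- matrix(runif(6 * 8), 6, 8)
  L <- matrix(runif(6 * 2), 6, 2); D <- matrix(runif(2 * 8), 2, 8)
  data_term <- 0; mae <- 0
  for (i in 1:6) for (j in 1:8) {
    pred <- sum(L[i, ] * D[, j])
    data_term <- data_term + (X[i, j] - pred)^2
    mae <- mae + abs(X[i, j] - pred)
  }
  G <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) G[a, b] <- sum(D[a, ] * D[b, ])
  logdet <- log(det(G + diag(2) * 0.7))
  expect_equal(minvol_objective(X, L, D, lambda = 0.3, delta = 0.7),
               data_term + 0.3 * logdet, tolerance = 1e-10)
  expect_equal(reconstruction_mae(X, L, D), mae / 48, tolerance = 1e-12)

  # forced arithmetic: all residuals are 0.5
  expect_equal(reconstruction_mae(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                                  matrix(1, 2, 1), matrix(0.5, 1, 2)), 0.5)
  expect_error(reconstruction_mae(X, L, matrix(0, 2, 5)), "shape|conform")
})

test_that("init_factors is deterministic, feasible, and SVD-consistent", {
  set.seed(31)
  X <- matrix(runif(12 * 20), 12, 20)
  cfg <- nmf_config(rank = 3, seed = 99, init = "random")
  a <- init_factors(X, cfg); b <- init_factors(X, cfg)
  expect_identical(a, b)
  expect_true(all(a$L >= 0) && all(a$D >= 0))
  expect_true(all(rowSums(a$L) <= 1 + 1e-9))

  cfg2 <- nmf_config(rank = 2, seed = 1, init = "nndsvd")
  c1 <- init_factors(X, cfg2); c2 <- init_factors(X, cfg2)
  expect_identical(c1, c2)
  expect_true(all(rowSums(c1$L) <= 1 + 1e-9))

  # rank-1 input: first dictionary row proportional to the dominant right
  # singular vector's nonnegative part (independent SVD oracle)
  u <- runif(10); w <- runif(15)
  X1 <- outer(u, w)
  f <- init_factors(X1, nmf_config(rank = 1, seed = 1, init = "nndsvd"))
  v1 <- svd(X1)$v[, 1]
  if (sum(v1) < 0) v1 <- -v1
  cosang <- sum(f$D[1, ] * v1) / sqrt(sum(f$D[1, ]^2) * sum(v1^2))
  expect_equal(cosang, 1, tolerance = 1e-10)

  expect_error(init_factors(X, nmf_config(rank = 15, seed = 1)), "rank")
})

test_that("fit recovers planted components on noiseless separable data", {
  g <- default_phantom_grid(12)
  sc <- separable_cohort(g, r = 3, n = 30, seed = 11)
  fit <- fit_minvol_nmf(sc$X, nmf_config(rank = 3, seed = 2, max_iter = 400,
                                         rel_tol = 1e-8))
  expect_lte(fit$summary$reconstruction_mae, 1e-3 * mean(sc$X))
  m <- match_components(fit$model$dictionary, sc$D)
  expect_true(all(m$correlations >= 0.99))
  expect_true(all(fit$model$dictionary >= 0))
  expect_true(all(fit$model$loads >= 0))
  expect_true(all(rowSums(fit$model$loads) <= 1 + 1e-9))
  expect_monotone_trace(fit$model$objective_trace)

  # scale identifiability: a different (random) initialization recovers the
  # same components up to permutation
  fit2 <- fit_minvol_nmf(sc$X, nmf_config(rank = 3, seed = 77, max_iter = 400,
                                          rel_tol = 1e-8, init = "random"))
  m2 <- match_components(fit2$model$dictionary, sc$D)
  expect_true(all(m2$correlations >= 0.99))
})

test_that("exact rank-1 data is reconstructed to machine-level error", {
  set.seed(41)
  X <- outer(runif(15, 0.1, 1), runif(30, 0.1, 1))
  fit <- fit_minvol_nmf(X, nmf_config(rank = 1, seed = 3, vol_weight = 1e-6,
                                      max_iter = 500, rel_tol = 1e-12))
  rel <- fit$summary$reconstruction_mae / mean(X)
  expect_lte(rel, 1e-6)
})

test_that("objective trace is monotone on arbitrary nonnegative data", {
  set.seed(51)
  for (k in 1:3) {
    X <- matrix(rexp(20 * 50), 20, 50)
    fit <- fit_minvol_nmf(X, nmf_config(rank = 4, seed = k, max_iter = 120))
    expect_monotone_trace(fit$model$objective_trace)
    expect_true(all(fit$model$loads >= 0) && all(fit$model$dictionary >= 0))
    expect_true(all(rowSums(fit$model$loads) <= 1 + 1e-9))
  }
  expect_error(fit_minvol_nmf(matrix(c(-1, 1, 1, 1), 2), nmf_config(rank = 1)),
               "negative")
})

test_that("stronger volume penalty shrinks the dictionary log-volume", {
  g <- default_phantom_grid(10)
  sc <- separable_cohort(g, r = 3, n = 25, seed = 13)
  X <- sc$X + matrix(pmax(rnorm(length(sc$X), 0, 0.02), 0), nrow(sc$X))
  logdets <- vapply(c(0.001, 0.01, 0.1, 1), function(w) {
    fit <- fit_minvol_nmf(X, nmf_config(rank = 3, seed = 5, vol_weight = w,
                                        max_iter = 250, rel_tol = 1e-8))
    voxelnmf:::.logdet_gram(fit$model$dictionary, 1)
  }, numeric(1))
  expect_true(all(diff(logdets) <= 1e-6))
})

test_that("project_loads solves the training subproblem on new data", {
  set.seed(61)
  D <- matrix(runif(3 * 50), 3, 50)
  l_true <- c(0.3, 0.1, 0.4)
  x <- as.numeric(crossprod(D, l_true))
  L <- project_loads(rbind(x, 0), D)
  expect_equal(as.numeric(L[1, ]), l_true, tolerance = 1e-6)
  expect_equal(as.numeric(L[2, ]), rep(0, 3))

  # agreement with the exhaustive oracle at small rank
  for (k in 1:25) {
    r <- sample(2:3, 1); v <- sample(4:6, 1)
    Dk <- matrix(runif(r * v), r, v)
    xk <- runif(v) * sample(c(0.5, 2), 1)
    l_pkg <- as.numeric(project_loads(matrix(xk, 1), Dk))
    l_ora <- oracle_capped_ls(Dk, xk)
    obj <- function(l) sum((xk - as.numeric(crossprod(Dk, l)))^2)
    expect_lt(abs(obj(l_pkg) - obj(l_ora)), 1e-8)
  }

  noisy <- matrix(pmax(rep(x, 5) + rnorm(250, 0, 0.1), 0), 5, byrow = TRUE)
  Ln <- project_loads(noisy, D)
  expect_true(all(Ln >= 0))
  expect_true(all(rowSums(Ln) <= 1 + 1e-9))
  expect_error(project_loads(matrix(1, 1, 10), D), "column mismatch")
})
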