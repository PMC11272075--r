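#' Nonnegative least squares on the capped simplex
#'
#' Solves, for one subject at a time,
#' \deqn{\min_{\ell} \|x - \ell D\|_2^2 \quad \mathrm{s.t.}\quad \ell \ge 0,
#'   \ \sum_j \ell_j \le 1,}
#' the load subproblem of the factorization (the "capped simplex" constraint
#' fixes the scale of the factorization). A two-phase active-set method is
#' used: plain Lawson–Hanson NNLS first; if its solution violates the sum
#' cap, the problem is re-solved with the sum constraint held at equality.
#' Both phases work on the Gram system, so the cost is governed by the rank
#' `r`, not by the number of voxels.
#'
#' @param D numeric r x v dictionary (rows are components).
#' @param X numeric matrix (subjects x v) or a single vector of length v.
#' @param tol dual-feasibility tolerance.
#' @return matrix of loads (subjects x r); rows are nonnegative with sums
#'   at most 1 (up to `tol`).
#' @export
capped_simplex_ls <- function(D, X, tol = 1e-10) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(D))
    stop("column mismatch: X has ", ncol(X), " voxels, D has ", ncol(D))
  G <- tcrossprod(D)                      # r x r
  Ct <- tcrossprod(X, D)                  # subjects x r
  L <- matrix(0, nrow = nrow(X), ncol = nrow(D))
  for (i in seq_len(nrow(X)))
    L[i, ] <- .capped_ls_gram(G, Ct[i, ], tol = tol)
  L
}

# robust linear solve for possibly-singular active-set systems
.solve_safe <- function(A, b) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out) || anyNA(out)) {
    ridge <- max(mean(abs(diag(A))), 1) * 1e-10
    out <- solve(A + diag(ridge, nrow(A)), b)
  }
  out
}

# Phase 1: Lawson-Hanson NNLS in Gram form: min l'Gl - 2c'l, l >= 0
.nnls_gram <- function(G, c, tol) {
  r <- length(c)
  l <- numeric(r)
  P <- logical(r)
  for (outer in seq_len(30L * r + 30L)) {
    w <- c - as.vector(G %*% l)          # -grad/2
    w[P] <- -Inf
    j <- which.max(w)
    if (!is.finite(w[j]) || w[j] <= tol * max(1, max(abs(c)))) break
    P[j] <- TRUE
    repeat {
      s <- numeric(r)
      s[P] <- .solve_safe(G[P, P, drop = FALSE], c[P])
      if (all(s[P] > 0)) { l <- s; break }
      viol <- P & (s <= 0)
      alpha <- min(l[viol] / (l[viol] - s[viol]))
      l <- l + alpha * (s - l)
      P[P & (l <= tol)] <- FALSE
      l[!P] <- 0
    }
  }
  pmax(l, 0)
}

# Phase 2: active-set QP for min l'Gl - 2c'l, l >= 0, sum(l) = 1
.simplex_ls_gram <- function(G, c, tol) {
  r <- length(c)
  l <- rep(1 / r, r)                     # feasible start
  P <- rep(TRUE, r)
  scale <- max(1, max(abs(c)), max(abs(G)))
  for (outer in seq_len(60L * r + 60L)) {
    # equality-constrained solve on the passive set:
    #   2 G_P s_P + mu * 1 = 2 c_P, sum(s_P) = 1
    k <- sum(P)
    K <- rbind(cbind(2 * G[P, P, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
    sol <- .solve_safe(K, c(2 * c[P], 1))
    s <- numeric(r)
    s[P] <- sol[seq_len(k)]
    mu <- sol[k + 1]
    if (any(s[P] < -tol)) {
      # step from current feasible l toward s until a variable hits zero
      neg <- which(P & (s < 0))
      ratio <- l[neg] / (l[neg] - s[neg])
      alpha <- min(1, ratio)
      jmin <- neg[which.min(ratio)]
      l <- l + alpha * (s - l)
      P[jmin] <- FALSE
      l[jmin] <- 0
      l[!P] <- 0
      next
    }
    l <- pmax(s, 0)
    # dual check on the active (zero) variables
    gz <- 2 * as.vector(G %*% l) - 2 * c + mu
    idx <- which(!P)
    if (length(idx) == 0L || all(gz[idx] >= -tol * scale)) break
    P[idx[which.min(gz[idx])]] <- TRUE
  }
  l / max(1, sum(l))                     # enforce the cap against roundoff
}

.capped_ls_gram <- function(G, c, tol = 1e-10) {
  l <- .nnls_gram(G, c, tol)
  if (sum(l) <= 1 + 1e-9) return(l)
  .simplex_ls_gram(G, c, tol)
}

# Row-wise Euclidean projection onto the capped simplex
# {l >= 0, sum(l) <= 1}; used by the projected-gradient load updates.
.project_capped_simplex_rows <- function(V) {
  V <- pmax(V, 0)
  s <- rowSums(V)
  over <- which(s > 1)
  for (i in over) {
    v <- V[i, ]
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u - (css - 1) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    V[i, ] <- pmax(v - theta, 0)
  }
  V
}
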