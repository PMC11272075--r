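#' Configuration for the minimum-volume NMF fit
#'
#' The factorization approximates a nonnegative subjects-by-voxels matrix
#' `X` as `L %*% D` with subject loads `L >= 0` constrained row-wise to the
#' capped simplex (row sums at most 1) and a nonnegative component
#' dictionary `D`. The objective is
#' \deqn{\|X - LD\|_F^2 + \lambda \log\det(DD^\top + \delta I_r),}
#' the standard minimum-volume criterion: the log-det penalty shrinks the
#' simplex spanned by the component rows, which restores identifiability
#' even when `D` is rank-deficient, as voxel data with heavy spatial
#' smoothing typically are. The capped-simplex constraint on loads removes
#' the diagonal rescaling ambiguity, so the only tunable parameter of
#' substance is the rank.
#'
#' @param rank number of components `r` (>= 1).
#' @param vol_weight relative weight of the volume penalty. The absolute
#'   `lambda` used is `vol_weight * ||X - L0 D0||_F^2 /
#'   max(1, |logdet(D0 D0' + delta I)|)` evaluated at the initial factors,
#'   making the penalty scale-free across datasets.
#' @param logdet_ridge `delta > 0`, keeps the log-determinant bounded below.
#' @param max_iter maximum outer iterations.
#' @param rel_tol relative objective-change convergence tolerance.
#' @param seed integer seed; required so every fit is reproducible.
#' @param init `"nndsvd"` (deterministic, SVD-based) or `"random"` (seeded
#'   successive-projection exemplar selection).
#' @return an object of class `nmf_config`.
#' @export
nmf_config <- function(rank, vol_weight = 0.01, logdet_ridge = 1,
                       max_iter = 500L, rel_tol = 1e-6, seed = 1L,
                       init = c("nndsvd", "random")) {
  init <- match.arg(init)
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be >= 1")
  if (logdet_ridge <= 0) stop("logdet_ridge must be > 0")
  if (rel_tol <= 0) stop("rel_tol must be > 0")
  if (vol_weight < 0) stop("vol_weight must be >= 0")
  structure(list(rank = rank, vol_weight = vol_weight,
                 logdet_ridge = logdet_ridge, max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, seed = as.integer(seed), init = init),
            class = "nmf_config")
}

.xvalues <- function(X) {
  if (inherits(X, "voxel_matrix")) X$values else as.matrix(X)
}

.logdet_gram <- function(D, delta) {
  G <- tcrossprod(D) + diag(delta, nrow(D))
  determinant(G, logarithm = TRUE)$modulus[[1]]
}

#' Minimum-volume NMF objective value
#'
#' `||X - L D||_F^2 + lambda * logdet(D D' + delta I)`.
#'
#' @param X subjects x voxels matrix (or [voxel_matrix()]).
#' @param L subjects x r loads.
#' @param D r x voxels dictionary.
#' @param lambda absolute volume-penalty weight (>= 0).
#' @param delta log-det ridge (> 0).
#' @export
minvol_objective <- function(X, L, D, lambda, delta) {
  X <- .xvalues(X)
  if (nrow(L) != nrow(X) || ncol(D) != ncol(X) || ncol(L) != nrow(D))
    stop("non-conforming shapes in objective")
  if (lambda < 0 || delta <= 0) stop("need lambda >= 0 and delta > 0")
  R <- X - L %*% D
  sum(R * R) + lambda * .logdet_gram(D, delta)
}

#' Mean absolute reconstruction error
#'
#' Mean over all matrix entries of `|X - L D|`; the loss used throughout
#' the cross-validated rank scan.
#'
#' @inheritParams minvol_objective
#' @export
reconstruction_mae <- function(X, L, D) {
  X <- .xvalues(X)
  if (nrow(L) != nrow(X) || ncol(D) != ncol(X) || ncol(L) != nrow(D))
    stop("non-conforming shapes in reconstruction_mae")
  mean(abs(X - L %*% D))
}

#' Initial factors for the NMF
#'
#' `"nndsvd"` builds deterministic factors from the truncated SVD of `X`
#' (nonnegative parts of the leading singular pairs, the larger of the
#' positive/negative part pair per component). `"random"` is a seeded
#' successive-projection (SPA) exemplar initialization: the dictionary is
#' seeded with subject rows chosen to span the data cone (random high-norm
#' first pick, then maximal residual norm), and the loads solved exactly
#' against it. Load rows always end up on the capped simplex.
#'
#' @param X subjects x voxels nonnegative matrix (or [voxel_matrix()]).
#' @param config an [nmf_config()].
#' @return list with elements `L` (n x r) and `D` (r x v).
#' @export
init_factors <- function(X, config) {
  X <- .xvalues(X)
  r <- config$rank
  n <- nrow(X); v <- ncol(X)
  if (r > min(n, v))
    stop("rank ", r, " exceeds min(n, v) = ", min(n, v))
  if (config$init == "nndsvd") {
    sv <- svd(X, nu = r, nv = r)
    L0 <- matrix(0, n, r); D0 <- matrix(0, r, v)
    for (j in seq_len(r)) {
      u <- sv$u[, j]; w <- sv$v[, j]; s <- sv$d[j]
      if (j == 1L) {
        # leading pair of a nonnegative matrix is sign-fixable to >= 0
        if (sum(u) < 0) { u <- -u; w <- -w }
        up <- pmax(u, 0); wp <- pmax(w, 0)
        L0[, j] <- sqrt(s) * up
        D0[j, ] <- sqrt(s) * wp
      } else {
        up <- pmax(u, 0); un <- pmax(-u, 0)
        wp <- pmax(w, 0); wn <- pmax(-w, 0)
        np <- sqrt(sum(up^2)) * sqrt(sum(wp^2))
        nn <- sqrt(sum(un^2)) * sqrt(sum(wn^2))
        if (np >= nn && np > 0) {
          L0[, j] <- sqrt(s * np) * up / sqrt(sum(up^2))
          D0[j, ] <- sqrt(s * np) * wp / sqrt(sum(wp^2))
        } else if (nn > 0) {
          L0[, j] <- sqrt(s * nn) * un / sqrt(sum(un^2))
          D0[j, ] <- sqrt(s * nn) * wn / sqrt(sum(wn^2))
        } else {
          L0[, j] <- mean(abs(u)); D0[j, ] <- mean(abs(w))
        }
      }
    }
  } else {
    # seeded successive-projection exemplar init: the first exemplar is a
    # random high-norm subject row, later ones maximize the residual norm
    # after projecting out the rows already chosen; on separable data the
    # exemplars land near the pure subjects regardless of the seed
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(config$seed)
    R <- X
    norms <- rowSums(R^2)
    top <- order(norms, decreasing = TRUE)[seq_len(max(1L, ceiling(n / 4)))]
    chosen <- integer(r)
    chosen[1] <- top[sample.int(length(top), 1)]
    for (j in seq_len(r)) {
      if (j > 1L) {
        norms <- rowSums(R^2)
        norms[chosen[seq_len(j - 1L)]] <- -Inf
        chosen[j] <- which.max(norms)
      }
      w <- R[chosen[j], ]
      nw <- sum(w^2)
      if (nw > 0) R <- R - (R %*% w) %*% matrix(w / nw, 1)
    }
    D0 <- X[chosen, , drop = FALSE] +
      matrix(stats::runif(r * v, 0, 0.01 * (mean(X) + 1e-12)), r, v)
    L0 <- capped_simplex_ls(D0, X)
  }
  # single global rescaling puts every load row on the capped simplex
  cmax <- max(rowSums(L0))
  if (cmax > 1) { L0 <- L0 / cmax; D0 <- D0 * cmax }
  list(L = L0, D = D0)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit the minimum-volume NMF
#'
#' Block-coordinate descent with guaranteed monotone objective:
#' \itemize{
#'   \item Load update: projected-gradient steps on the convex quadratic
#'     load subproblem (projection onto the capped simplex, step size
#'     `1/Lipschitz`), followed on the final iteration by an exact
#'     active-set solve (the same solver [capped_simplex_ls()] used by
#'     [project_loads()]).
#'   \item Dictionary update: majorize–minimize. The concave log-det term is
#'     majorized by its tangent at the current dictionary, giving a convex
#'     quadratic surrogate minimized by projected-gradient steps onto the
#'     nonnegative orthant. Decreasing the surrogate decreases the true
#'     objective.
#' }
#' Iterations stop when the relative objective change drops below
#' `rel_tol` or `max_iter` is reached. The recorded `objective_trace` is
#' non-increasing up to accumulation tolerance.
#'
#' @param X a [voxel_matrix()] or plain nonnegative matrix.
#' @param config an [nmf_config()].
#' @param inner_steps projected-gradient steps per block per iteration.
#' @return list with elements `model` (class `nmf_model`: `config`,
#'   `dictionary`, `loads`, `lambda`, `objective_trace`, `converged`,
#'   `grid`) and `summary` (class `nmf_fit_summary`: `reconstruction_mae`,
#'   `final_objective`, `iterations_run`).
#' @export
fit_minvol_nmf <- function(X, config, inner_steps = 3L) {
  grid <- if (inherits(X, "voxel_matrix")) X$grid else NULL
  subject_ids <- if (inherits(X, "voxel_matrix")) X$subject_ids else NULL
  Xv <- .xvalues(X)
  if (min(Xv) < 0) stop("X contains negative entries; NMF requires X >= 0")
  r <- config$rank
  if (r > min(dim(Xv)))
    stop("rank ", r, " exceeds min(n, v) = ", min(dim(Xv)))
  delta <- config$logdet_ridge

  fac <- init_factors(Xv, config)
  L <- fac$L; D <- fac$D

  # scale-free absolute penalty weight, anchored at the initial factors
  R0 <- Xv - L %*% D
  lambda <- config$vol_weight * sum(R0 * R0) /
    max(1, abs(.logdet_gram(D, delta)))

  obj <- minvol_objective(Xv, L, D, lambda, delta)
  trace <- numeric(config$max_iter + 1L)
  trace[1] <- obj
  converged <- FALSE
  it <- 0L

  for (it in seq_len(config$max_iter)) {
    ## -- load block: PGD on 0.5-smooth quadratic, capped-simplex projection
    G <- tcrossprod(D)
    XD <- tcrossprod(Xv, D)
    lipL <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    if (lipL > 0) {
      stepL <- 1 / lipL
      for (s in seq_len(inner_steps)) {
        gradL <- 2 * (L %*% G - XD)
        L <- .project_capped_simplex_rows(L - stepL * gradL)
      }
    }

    ## -- dictionary block: MM surrogate (tangent majorizer of logdet)
    Ginv <- chol2inv(chol(tcrossprod(D) + diag(delta, r)))
    A <- crossprod(L) + lambda * Ginv          # r x r, positive definite
    B <- crossprod(L, Xv)                      # r x v
    lipD <- 2 * max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    D_old <- D
    obj_old <- obj
    stepD <- 1 / lipD
    for (s in seq_len(inner_steps)) {
      gradD <- 2 * (A %*% D - B)
      D <- pmax(D - stepD * gradD, 0)
    }
    obj <- minvol_objective(Xv, L, D, lambda, delta)
    if (!is.finite(obj))
      stop("non-finite objective at iteration ", it)
    if (obj > obj_old + 1e-12 * max(1, trace[1])) {
      # MM guarantees descent in exact arithmetic; guard against roundoff
      D <- D_old
      obj <- minvol_objective(Xv, L, D, lambda, delta)
    }
    trace[it + 1L] <- obj
    if (abs(trace[it] - obj) <= config$rel_tol * max(abs(trace[it]), 1e-30)) {
      converged <- TRUE
      break
    }
  }

  # exact load polish: solves each subject's subproblem to optimality
  L <- capped_simplex_ls(D, Xv)
  obj <- minvol_objective(Xv, L, D, lambda, delta)
  trace <- c(trace[seq_len(it + 1L)], min(obj, trace[it + 1L]))

  if (!is.null(subject_ids)) rownames(L) <- subject_ids
  colnames(L) <- sprintf("comp_%02d", seq_len(r))
  rownames(D) <- colnames(L)
  model <- structure(
    list(config = config, dictionary = D, loads = L, lambda = lambda,
         objective_trace = trace, converged = converged, grid = grid),
    class = "nmf_model")
  summary <- structure(
    list(reconstruction_mae = reconstruction_mae(Xv, L, D),
         final_objective = trace[length(trace)],
         iterations_run = it),
    class = "nmf_fit_summary")
  list(model = model, summary = summary)
}

#' @export
print.nmf_model <- function(x, ...) {
  cat("minimum-volume NMF: rank", x$config$rank, "|",
      nrow(x$loads), "subjects x", ncol(x$dictionary), "voxels |",
      if (x$converged) "converged" else "max_iter reached", "\n")
  invisible(x)
}

#' Project new subjects onto a fixed dictionary
#'
#' Solves, for each row of `X_new`, the same capped-simplex nonnegative
#' least-squares subproblem used for the loads during fitting, holding the
#' dictionary fixed. This is how held-out subjects acquire component loads.
#'
#' @param X_new matrix or [voxel_matrix()] of new subjects (>= 0).
#' @param D r x voxels dictionary (an `nmf_model` is also accepted).
#' @return loads matrix, rows nonnegative with sums at most 1.
#' @export
project_loads <- function(X_new, D) {
  if (inherits(D, "nmf_model")) D <- D$dictionary
  ids <- if (inherits(X_new, "voxel_matrix")) X_new$subject_ids else NULL
  Xv <- .xvalues(X_new)
  if (ncol(Xv) != ncol(D))
    stop("column mismatch: X_new has ", ncol(Xv), " voxels, dictionary has ",
         ncol(D))
  if (min(Xv) < 0) stop("X_new contains negative entries")
  L <- capped_simplex_ls(D, Xv)
  if (!is.null(ids)) rownames(L) <- ids
  colnames(L) <- sprintf("comp_%02d", seq_len(nrow(D)))
  L
}
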