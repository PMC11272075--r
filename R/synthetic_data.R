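#' Default phantom grid
#'
#' A cubic grid with an ellipsoidal "brain" mask — large enough that
#' Gaussian-blob components are spatially distinct, small enough for fast
#' tests. The 24-voxel default mask covers ~5.5k voxels.
#'
#' @param dim edge length of the cubic grid.
#' @param radius_frac ellipsoid semi-axes as a fraction of the half-width.
#' @export
default_phantom_grid <- function(dim = 24L, radius_frac = 0.85) {
  dim <- as.integer(dim)
  ctr <- (dim + 1) / 2
  rad <- radius_frac * (dim - 1) / 2
  co <- seq_len(dim)
  d2 <- outer(outer((co - ctr)^2, (co - ctr)^2, "+"), (co - ctr)^2, "+")
  masked_grid(array(d2 <= rad^2, dim = c(dim, dim, dim)))
}

# separable 3D Gaussian smoothing (reflecting edges), sigma in voxels
.gauss_smooth_3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  smooth_axis <- function(a, axis) {
    dims <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = dim(ap)[1])
    n <- nrow(m)
    idx <- seq_len(n)
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(kern)) {
      shift <- o - half - 1L
      src <- idx + shift
      src <- ifelse(src < 1L, 2L - src, ifelse(src > n, 2L * n - src, src))
      src <- pmin(pmax(src, 1L), n)   # clamp when kernel wider than the axis
      out <- out + kern[o] * m[src, , drop = FALSE]
    }
    ap <- array(out, dim = dim(ap))
    aperm(ap, order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

#' Generate smooth nonnegative spatial components
#'
#' Each component is a sum of `blobs` isotropic Gaussian bumps centred at
#' seeded random mask voxels, lightly smoothed to mimic the spatial
#' covariance of smoothed imaging data, and max-normalized to 1. Components
#' are resampled (up to 100 attempts each) until all pairwise Pearson
#' correlations over the mask are below `max_cor`, so the planted patterns
#' are genuinely distinct.
#'
#' @param grid a [masked_grid()].
#' @param r number of components.
#' @param blobs Gaussian bumps per component.
#' @param fwhm_voxels bump full width at half maximum, in voxels.
#' @param smooth_sigma extra smoothing sigma in voxels (0 disables).
#' @param max_cor pairwise correlation bound enforced by resampling.
#' @param seed integer seed.
#' @return r x voxels nonnegative dictionary matrix (rows max-normalized).
#' @export
generate_components <- function(grid, r, blobs = 3L, fwhm_voxels = 4,
                                smooth_sigma = 0.8, max_cor = 0.6, seed = 1L) {
  if (r < 1L) stop("r must be >= 1")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  sigma <- fwhm_voxels / (2 * sqrt(2 * log(2)))
  coords <- grid$voxel_index
  nv <- nrow(coords)

  one_component <- function() {
    centers <- coords[sample.int(nv, blobs, replace = TRUE), , drop = FALSE]
    flat <- numeric(nv)
    for (b in seq_len(blobs)) {
      d2 <- (coords[, 1] - centers[b, 1])^2 +
            (coords[, 2] - centers[b, 2])^2 +
            (coords[, 3] - centers[b, 3])^2
      flat <- flat + exp(-d2 / (2 * sigma^2))
    }
    vol <- .gauss_smooth_3d(devectorize_volume(flat, grid, 0), smooth_sigma)
    flat <- pmax(vectorize_volume(vol, grid), 0)
    flat / max(flat)
  }

  D <- matrix(0, r, nv)
  for (j in seq_len(r)) {
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      cand <- one_component()
      if (j == 1L ||
          all(abs(stats::cor(cand, t(D[seq_len(j - 1L), , drop = FALSE]))) <
              max_cor)) {
        D[j, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not generate component ", j, " with pairwise correlation < ",
           max_cor, " in 100 attempts; use a larger mask or smaller r")
  }
  rownames(D) <- sprintf("comp_%02d", seq_len(r))
  D
}

#' Outcome link specification for synthetic cohorts
#'
#' @param name outcome column name.
#' @param family `"binary"` (Bernoulli with logit link) or `"continuous"`
#'   (Gaussian noise around the linear predictor).
#' @param intercept,age_coef link coefficients; age enters centred at 70 y
#'   so the intercept is interpretable at a typical cohort age.
#' @param load_coefs one coefficient per planted component.
#' @param sigma residual SD for continuous outcomes.
#' @export
outcome_link <- function(name, family = c("binary", "continuous"),
                         intercept = 0, age_coef = 0, load_coefs,
                         sigma = 1) {
  family <- match.arg(family)
  structure(list(name = name, family = family, intercept = intercept,
                 age_coef = age_coef, load_coefs = load_coefs, sigma = sigma),
            class = "outcome_link")
}

#' Generate a synthetic phantom cohort
#'
#' Builds a nonnegative subject-by-voxel matrix `X = L D + E` from planted
#' components: loads are Dirichlet-distributed (independent gamma draws
#' normalized per subject) and scaled by a per-subject total drawn
#' uniformly from `total_range`, so every row lies strictly inside the
#' capped simplex; `E` is zero-truncated Gaussian noise (`pmax(N(0, sd),
#' 0)`), keeping `X` nonnegative as tissue-volume and SUVR data are.
#' Clinical outcomes are tied to the true loads through linear (Gaussian)
#' or logistic links with an age covariate, mirroring how the prediction
#' stage models real outcomes.
#'
#' @param D_true r x voxels dictionary, e.g. from [generate_components()].
#' @param n number of subjects.
#' @param dirichlet_alpha concentration of the per-subject load direction.
#' @param total_range range of per-subject load totals (inside (0, 1]).
#' @param noise_sd SD of the truncated additive noise (0 for noiseless).
#' @param age_range cohort age range in years (uniform).
#' @param outcome_links list of [outcome_link()]s (may be empty).
#' @param grid optional [masked_grid()] stored with the matrix.
#' @param modality modality tag for the generated matrix.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return list with `X` (a [voxel_matrix()] if `grid` given, else matrix),
#'   `clinical` (a [clinical_table()]), `truth` (loads, dictionary, links,
#'   seed).
#' @export
generate_cohort <- function(D_true, n, dirichlet_alpha = 0.8,
                            total_range = c(0.5, 1), noise_sd = 0.05,
                            age_range = c(55, 85), outcome_links = list(),
                            grid = NULL, modality = "other", seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  r <- nrow(D_true)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)

  g <- matrix(stats::rgamma(n * r, shape = dirichlet_alpha), n, r)
  dir <- g / rowSums(g)
  total <- stats::runif(n, total_range[1], total_range[2])
  L <- dir * total
  X <- L %*% D_true
  if (noise_sd > 0)
    X <- X + pmax(matrix(stats::rnorm(length(X), sd = noise_sd),
                         nrow(X), ncol(X)), 0)

  ids <- sprintf("subj_%03d", seq_len(n))
  rownames(L) <- ids
  colnames(L) <- rownames(D_true) %||% sprintf("comp_%02d", seq_len(r))
  age <- round(stats::runif(n, age_range[1], age_range[2]), 1)
  clin <- data.frame(subject_id = ids, age = age)
  for (link in outcome_links) {
    lp <- link$intercept + link$age_coef * (age - 70) +
      as.numeric(L %*% link$load_coefs)
    clin[[link$name]] <-
      if (link$family == "binary") stats::rbinom(n, 1, stats::plogis(lp))
      else lp + stats::rnorm(n, sd = link$sigma)
  }

  Xout <- if (!is.null(grid)) {
    voxel_matrix(X, ids, modality = modality, grid = grid)
  } else {
    rownames(X) <- ids
    X
  }
  list(X = Xout, clinical = clinical_table(clin),
       truth = list(L = L, D = D_true, noise_sd = noise_sd,
                    outcome_links = outcome_links, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match estimated components to ground truth
#'
#' NMF is identifiable only up to row permutation, so recovered components
#' are compared to planted ones through the one-to-one assignment that
#' maximizes total Pearson correlation (solved as a linear assignment
#' problem). Zero-variance rows have undefined correlation and are flagged
#' unmatched.
#'
#' @param D_est estimated dictionary (rows <= rows of `D_true`).
#' @param D_true reference dictionary with the same number of columns.
#' @return list with `assignment` (for each row of `D_est`, the matched row
#'   of `D_true`, `NA` if unmatched), `correlations` (per matched pair),
#'   `mean_correlation`.
#' @export
match_components <- function(D_est, D_true) {
  if (ncol(D_est) != ncol(D_true)) stop("column counts differ")
  if (nrow(D_est) > nrow(D_true)) stop("D_est may not have more rows")
  sd_est <- apply(D_est, 1, stats::sd)
  sd_true <- apply(D_true, 1, stats::sd)
  C <- matrix(-1, nrow(D_est), nrow(D_true))
  valid <- outer(sd_est > 0, sd_true > 0, "&")
  if (any(valid)) {
    Cfull <- suppressWarnings(stats::cor(t(D_est), t(D_true)))
    C[valid] <- Cfull[valid]
  }
  sol <- clue::solve_LSAP(C + 1, maximum = TRUE)   # shift to nonnegative
  assignment <- as.integer(sol)
  correlations <- C[cbind(seq_len(nrow(D_est)), assignment)]
  unmatched <- sd_est == 0 | sd_true[assignment] == 0
  assignment[unmatched] <- NA_integer_
  correlations[unmatched] <- NA_real_
  list(assignment = assignment, correlations = correlations,
       mean_correlation = mean(correlations, na.rm = TRUE))
}
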