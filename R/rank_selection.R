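#' Repeated cross-validated rank scan
#'
#' For each candidate rank, the subjects are split into `k` roughly equal
#' folds (sizes differing by at most one); the NMF is fit on the `k - 1`
#' discovery folds, the discovery reconstruction error (mean absolute
#' error) is recorded, the held-out fold is projected onto the fitted
#' dictionary with [project_loads()], and its hold-out reconstruction error
#' is recorded. The whole split-and-fit cycle is repeated `repeats` times
#' with fresh random splits, so each rank accumulates `k * repeats`
#' (discovery, hold-out) error pairs — with the defaults `k = 5`,
#' `repeats = 5`, that is 25 pairs per rank. A good rank keeps both errors
#' low: too small a rank underfits the discovery folds, too large a rank
#' fits noise components that inflate the hold-out error.
#'
#' Every fit's seed is derived deterministically from `seed` and the
#' (rank, repeat, fold) triple, so the scan is reproducible yet no two
#' fits share a seed.
#'
#' @param X a [voxel_matrix()] or nonnegative matrix.
#' @param ranks integer vector of candidate ranks.
#' @param k number of folds (default 5).
#' @param repeats number of repeats of the whole CV cycle (default 5).
#' @param config an [nmf_config()] used as template (its `rank` and `seed`
#'   are overridden per fit).
#' @param seed integer controlling fold splits and fit seeds.
#' @return object of class `rank_scan` with fields `ranks`, `errors` (a
#'   data.frame with columns rank, repeat_idx, fold, discovery_mae,
#'   holdout_mae), `chosen_rank`, `rule`.
#' @export
cv_rank_scan <- function(X, ranks, k = 5L, repeats = 5L,
                         config = nmf_config(rank = 2L), seed = 1L) {
  Xv <- .xvalues(X)
  n <- nrow(Xv); v <- ncol(Xv)
  k <- as.integer(k); repeats <- as.integer(repeats)
  ranks <- sort(unique(as.integer(ranks)))
  if (length(ranks) == 0L) stop("ranks must be nonempty")
  if (k < 2L || n < k) stop("need n >= k >= 2 (n = ", n, ", k = ", k, ")")
  min_disc <- n - ceiling(n / k)          # smallest discovery-fold size
  bad <- ranks[ranks > min(min_disc, v)]
  if (length(bad))
    stop("rank(s) ", paste(bad, collapse = ", "),
         " infeasible for discovery folds of size ", min_disc,
         " and ", v, " voxels")

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  rows <- vector("list", length(ranks) * repeats * k)
  fold_assignments <- matrix(NA_integer_, repeats, n)
  pos <- 0L
  for (m in seq_len(repeats)) {
    set.seed((seed * 1009L + m) %% 2147483647L)
    fold_of <- sample(rep(seq_len(k), length.out = n))
    fold_assignments[m, ] <- fold_of
    for (r in ranks) {
      for (f in seq_len(k)) {
        disc <- which(fold_of != f)
        hold <- which(fold_of == f)
        cfg <- config
        cfg$rank <- r
        cfg$seed <- (seed * 7919L + r * 104729L + m * 1299709L + f) %%
          2147483647L
        fit <- fit_minvol_nmf(Xv[disc, , drop = FALSE], cfg)
        Dh <- fit$model$dictionary
        disc_mae <- fit$summary$reconstruction_mae
        Lh <- project_loads(Xv[hold, , drop = FALSE], Dh)
        hold_mae <- reconstruction_mae(Xv[hold, , drop = FALSE], Lh, Dh)
        pos <- pos + 1L
        rows[[pos]] <- data.frame(rank = r, repeat_idx = m, fold = f,
                                  discovery_mae = disc_mae,
                                  holdout_mae = hold_mae)
      }
    }
  }
  errors <- do.call(rbind, rows)
  out <- structure(list(ranks = ranks, errors = errors,
                        folds = fold_assignments, k = k, repeats = repeats,
                        chosen_rank = NA_integer_,
                        rule = "1se-min-holdout-mae"),
                   class = "rank_scan")
  out$chosen_rank <- choose_rank(out)
  out
}

#' Choose the rank from a scan
#'
#' Applies a one-standard-error rule to the hold-out errors: among the mean
#' hold-out MAEs per rank, find the global minimum, compute the standard
#' error of the hold-out values at that minimizing rank, and return the
#' smallest rank whose mean is within one standard error of the minimum.
#' This is a deterministic, conservative reading of "both errors at or near
#' their lowest point": it never picks a larger rank than the minimizer and
#' prefers parsimony when ranks are statistically indistinguishable.
#'
#' @param scan a `rank_scan` object (or its `errors` data.frame).
#' @return the chosen rank (integer).
#' @export
choose_rank <- function(scan) {
  errors <- if (inherits(scan, "rank_scan")) scan$errors else scan
  if (is.null(errors) || nrow(errors) == 0L) stop("empty rank-scan result")
  means <- tapply(errors$holdout_mae, errors$rank, mean)
  rks <- as.integer(names(means))
  i_min <- which.min(means)
  at_min <- errors$holdout_mae[errors$rank == rks[i_min]]
  se <- stats::sd(at_min) / sqrt(length(at_min))
  if (!is.finite(se)) se <- 0
  ok <- which(means <= means[i_min] + se)
  rks[min(ok)]
}

#' @export
print.rank_scan <- function(x, ...) {
  means <- tapply(x$errors$holdout_mae, x$errors$rank, mean)
  cat("rank scan over ranks", paste(range(x$ranks), collapse = ".."),
      "| chosen rank:", x$chosen_rank, "\n")
  print(round(means, 6))
  invisible(x)
}

#' @export
plot.rank_scan <- function(x, ...) {
  disc <- tapply(x$errors$discovery_mae, x$errors$rank, mean)
  hold <- tapply(x$errors$holdout_mae, x$errors$rank, mean)
  rks <- as.integer(names(hold))
  graphics::matplot(rks, cbind(disc, hold), type = "b", pch = c(1, 16),
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "rank", ylab = "reconstruction MAE", ...)
  graphics::abline(v = x$chosen_rank, lty = 3)
  graphics::legend("topright", c("discovery", "hold-out"),
                   col = c("grey40", "firebrick"), pch = c(1, 16), lty = 1)
  invisible(x)
}
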