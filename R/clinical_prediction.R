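#' Clinical table and outcome specification
#'
#' The clinical table holds one row per subject: an ID, age in years, and
#' any number of named outcome columns. Binary outcomes are coded 0/1 with
#' `NA` for missing; continuous outcomes are numeric scores in their
#' scale-specific units (e.g. MoCA points). `outcome_spec()` declares how a
#' column is modelled.
#'
#' @param df data.frame with columns `subject_id`, `age`, plus outcomes.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("subject_id", "age")
  if (!all(need %in% names(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("duplicate subject IDs")
  df$subject_id <- as.character(df$subject_id)
  structure(df, class = c("clinical_table", "data.frame"))
}

#' @rdname clinical_table
#' @param path CSV file with a header row; empty cells are missing values.
#' @export
read_clinical_table <- function(path) {
  clinical_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                 na.strings = c("", "NA")))
}

#' @rdname clinical_table
#' @param name outcome column name.
#' @param family `"binary"` or `"continuous"`.
#' @param scale free-text label of the source clinical scale.
#' @export
outcome_spec <- function(name, family = c("binary", "continuous"),
                         scale = NA_character_) {
  family <- match.arg(family)
  structure(list(name = name, family = family, scale = scale),
            class = "outcome_spec")
}

#' Assemble a prediction design matrix
#'
#' Joins one or two blocks of component loads with the clinical table on
#' subject ID and returns the complete-case design (columns: `age`, then
#' the load columns of each block) and response for one outcome. Subjects
#' missing the outcome, age, or any required load block are dropped.
#'
#' @param loads_blocks named list of one or two load matrices with subject
#'   IDs as rownames (names become column prefixes, e.g. `MRI`, `FDG`).
#' @param clinical a [clinical_table()].
#' @param outcome an [outcome_spec()].
#' @param min_cases minimum number of complete cases (default 10).
#' @return list with `design` (matrix), `response` (numeric vector),
#'   `subjects` (character), `outcome`.
#' @export
assemble_design <- function(loads_blocks, clinical, outcome, min_cases = 10L) {
  if (inherits(loads_blocks, "matrix")) loads_blocks <- list(loads = loads_blocks)
  if (is.null(names(loads_blocks)) || any(names(loads_blocks) == ""))
    names(loads_blocks) <- paste0("block", seq_along(loads_blocks))
  if (!outcome$name %in% names(clinical))
    stop("outcome column not in clinical table: ", outcome$name)
  for (b in loads_blocks)
    if (is.null(rownames(b)))
      stop("each loads block needs subject IDs as rownames")

  ids <- Reduce(intersect, c(list(clinical$subject_id),
                             lapply(loads_blocks, rownames)))
  cl <- clinical[match(ids, clinical$subject_id), ]
  y <- cl[[outcome$name]]
  keep <- !is.na(y) & !is.na(cl$age)
  ids <- ids[keep]; y <- y[keep]
  blocks <- lapply(seq_along(loads_blocks), function(i) {
    b <- loads_blocks[[i]][ids, , drop = FALSE]
    colnames(b) <- paste(names(loads_blocks)[i], colnames(b), sep = "_")
    b
  })
  design <- cbind(age = cl$age[keep], do.call(cbind, blocks))
  rownames(design) <- ids
  if (nrow(design) < min_cases)
    stop("insufficient data: only ", nrow(design), " complete cases for ",
         outcome$name)
  if (stats::var(y) == 0)
    stop("degenerate outcome (zero variance): ", outcome$name)
  if (outcome$family == "binary" && !all(y %in% c(0, 1)))
    stop("binary outcome ", outcome$name, " has values outside {0, 1}")
  list(design = design, response = as.numeric(y), subjects = ids,
       outcome = outcome)
}

#' Fit an elastic-net prediction model
#'
#' Penalized regression of a clinical outcome on age and component loads,
#' minimizing the Gaussian (continuous) or binomial-logit (binary) negative
#' log-likelihood plus the elastic-net penalty
#' `lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)` over predictors
#' standardized to unit variance (intercept unpenalized, response left on
#' its own scale). The regularization strength is chosen by `cv_folds`-fold
#' cross-validation (minimum mean deviance along the lambda path). The
#' mixing convention follows the study design: `alpha = 0.2` (ridge-
#' leaning) for single-modality models, `alpha = 0.8` (lasso-leaning) for
#' combined MRI+FDG models.
#'
#' @param design predictor matrix (first column conventionally `age`).
#' @param response numeric outcome vector.
#' @param family `"continuous"` (Gaussian) or `"binary"` (logit).
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param cv_folds folds for the lambda cross-validation (default 5).
#' @param seed integer seed controlling the CV fold assignment.
#' @param outcome_name label stored with the model, used in messages/reports.
#' @param ... passed on to [glmnet::cv.glmnet()] (e.g. `thresh`).
#' @return object of class `prediction_model`: outcome name and family,
#'   `alpha`, selected `lambda`, `intercept`, `coefficients`
#'   (original-scale, named), `coefficients_std` (standardized-predictor
#'   scale), `center`/`scale` per predictor, `training` fitted values.
#' @export
fit_elastic_net <- function(design, response, family = c("continuous", "binary"),
                            alpha = 0.2, cv_folds = 5L, seed = 1L,
                            outcome_name = "outcome", ...) {
  family <- match.arg(family)
  design <- as.matrix(design)
  if (nrow(design) != length(response)) stop("design/response length mismatch")
  if (nrow(design) < cv_folds)
    stop("fewer rows than CV folds")
  if (family == "binary") {
    tab <- table(factor(response, levels = c(0, 1)))
    if (min(tab) < 3L)
      stop("class imbalance for ", outcome_name, ": only ", min(tab),
           " cases in the minority class (need >= 3)")
  }
  glm_family <- if (family == "binary") "binomial" else "gaussian"

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(design)))
  # glmnet warns about small per-fold class counts on small cohorts; the
  # explicit class-balance check above already guards the degenerate case
  muffle_small_fold <- function(w) {
    if (grepl("fewer than 8", conditionMessage(w)))
      invokeRestart("muffleWarning")
  }
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(design, response, family = glm_family,
                      alpha = alpha, foldid = foldid,
                      standardize = TRUE, ...),
    warning = muffle_small_fold)
  # refit at the selected strength: path coefficients are warm-start
  # approximations, the dedicated fit is converged at lambda.min itself
  refit <- glmnet::glmnet(design, response, family = glm_family,
                          alpha = alpha, lambda = cv$lambda.min,
                          standardize = TRUE, ...)
  co <- as.numeric(stats::coef(refit))
  names(co) <- c("(Intercept)", colnames(design))
  ctr <- colMeans(design)
  scl <- apply(design, 2, stats::sd)
  scl[scl == 0] <- 1
  beta <- co[-1]
  model <- structure(list(
    outcome = outcome_name, family = family, alpha = alpha,
    lambda = cv$lambda.min,
    intercept = co[[1]],
    coefficients = beta,                    # original predictor scale
    coefficients_std = beta * scl,          # standardized predictor scale
    center = ctr, scale = scl,
    predictors = colnames(design),
    cv_folds = cv_folds, seed = seed), class = "prediction_model")
  model$training <- predict_outcome(model, design)
  model
}

#' @export
print.prediction_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("elastic-net ", x$family, " model for '", x$outcome, "': alpha = ",
      x$alpha, ", lambda = ", signif(x$lambda, 4), ", ", nz, "/",
      length(x$coefficients), " nonzero slopes\n", sep = "")
  invisible(x)
}

#' Predict a clinical outcome from a fitted model
#'
#' Continuous models return the linear predictor on the response scale;
#' binary models return the predicted probability and the hard label at
#' the 0.5 threshold.
#'
#' @param model a `prediction_model`.
#' @param newdata matrix with the model's predictor columns (same names,
#'   same order).
#' @return for continuous outcomes a numeric vector; for binary outcomes a
#'   data.frame with columns `probability` and `label`.
#' @export
predict_outcome <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), model$predictors))
    stop("newdata columns must match the model design (names and order)")
  lp <- as.numeric(model$intercept + newdata %*% model$coefficients)
  if (model$family == "continuous") return(lp)
  p <- stats::plogis(lp)
  data.frame(probability = p, label = as.integer(p >= 0.5))
}

#' Binary classification metrics from confusion counts
#'
#' `mcc()` is the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, the Pearson
#' correlation between truth and prediction indicators. It ranges over
#' \[-1, 1\], with 0 the expected value of a coin-tossing classifier; by the
#' usual convention it returns 0 when any marginal total is zero.
#' `accuracy()` is `(tp + tn) / total`.
#'
#' @param tp,fp,tn,fn confusion-matrix counts (nonnegative).
#' @export
mcc <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  if (sum(counts) == 0) stop("empty confusion matrix")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' @rdname mcc
#' @export
accuracy <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (any(c(tp, fp, tn, fn) < 0)) stop("confusion counts must be nonnegative")
  if (total == 0) stop("empty confusion matrix")
  (tp + tn) / total
}

#' Confusion counts from label vectors
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return list with tp, fp, tn, fn.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  list(tp = sum(truth == 1 & predicted == 1),
       fp = sum(truth == 0 & predicted == 1),
       tn = sum(truth == 0 & predicted == 0),
       fn = sum(truth == 1 & predicted == 0))
}

#' Continuous prediction metrics
#'
#' `r_squared()` is `1 - SS_res / SS_tot`; out of sample it can be
#' negative. `mean_abs_error()` and `median_abs_error()` summarize
#' `|y - yhat|`; which one a report labels "MAE" is a configuration switch
#' (default median in the evaluation report).
#'
#' @param y observed values; `yhat` predictions of the same length.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2L || stats::var(y) == 0)
    stop("r_squared needs >= 2 observations with variance > 0")
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' @rdname r_squared
#' @export
mean_abs_error <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  mean(abs(y - yhat))
}

#' @rdname r_squared
#' @export
median_abs_error <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  stats::median(abs(y - yhat))
}

#' Paired comparison of per-subject errors between modalities
#'
#' Two-sided sign-flip permutation test of the null that the mean paired
#' error difference is zero, applied to per-subject errors (0/1
#' misclassification indicators for binary outcomes, absolute errors for
#' continuous) on the subjects shared by both models. All `2^n` sign
#' assignments are enumerated when `n <= 12`; otherwise `n_perm`
#' Monte-Carlo sign flips are drawn from `seed`. Returns a p-value in
#' (0, 1]; identical error vectors give exactly 1.
#'
#' @param errors_a,errors_b numeric per-subject errors, equal length >= 5.
#' @param n_perm Monte-Carlo draws when exact enumeration is infeasible.
#' @param seed integer seed for the Monte-Carlo branch.
#' @export
compare_paired_errors <- function(errors_a, errors_b, n_perm = 10000L,
                                  seed = 1L) {
  if (length(errors_a) != length(errors_b)) stop("length mismatch")
  n <- length(errors_a)
  if (n < 5L) stop("need >= 5 paired observations")
  d <- errors_a - errors_b
  if (all(d == 0)) return(1)
  t_obs <- abs(mean(d))
  eps <- 1e-12 * max(1, max(abs(d)))
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_null <- abs(as.numeric(signs %*% d)) / n
    return(mean(t_null >= t_obs - eps))
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  t_null <- abs(as.numeric(signs %*% d)) / n
  (1 + sum(t_null >= t_obs - eps)) / (1 + n_perm)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`
#' over the sorted p-values, mapped back to the input order. Monotone
#' non-decreasing in p and never above 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(pmin(1, p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
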