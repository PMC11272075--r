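make_loads <- function(ids, r, prefix = "comp", seed = 1) {
  set.seed(seed)
  m <- matrix(runif(length(ids) * r, 0, 1 / r), length(ids), r,
              dimnames = list(ids, sprintf("%s_%02d", prefix, seq_len(r))))
  m
}

test_that("assemble_design joins blocks, drops incomplete cases", {
  ids <- sprintf("s%02d", 1:15)
  clin <- clinical_table(data.frame(
    subject_id = ids, age = 60 + seq_len(15),
    gaze_palsy = c(rep(c(0, 1), 7), NA),
    moca = c(NA, 21:34)))
  mri <- make_loads(ids, 3, seed = 2)
  fdg <- make_loads(ids, 4, seed = 3)

  d1 <- assemble_design(list(MRI = mri), clin, outcome_spec("gaze_palsy"),
                        min_cases = 5)
  expect_equal(nrow(d1$design), 14)              # one missing outcome dropped
  expect_equal(colnames(d1$design),
               c("age", paste0("MRI_comp_0", 1:3)))

  d2 <- assemble_design(list(MRI = mri, FDG = fdg), clin,
                        outcome_spec("moca", "continuous"), min_cases = 5)
  expect_equal(ncol(d2$design), 1 + 3 + 4)
  expect_false("s01" %in% d2$subjects)

  # rows are aligned by subject ID, not position
  d3 <- assemble_design(list(MRI = mri[sample(15), ], FDG = fdg), clin,
                        outcome_spec("moca", "continuous"), min_cases = 5)
  expect_identical(d3$design, d2$design)

  # blocks without IDs cannot be aligned
  anon <- mri; rownames(anon) <- NULL
  expect_error(assemble_design(list(MRI = anon), clin,
                               outcome_spec("gaze_palsy")), "rownames")

  expect_error(assemble_design(list(MRI = mri), clin,
                               outcome_spec("gaze_palsy"), min_cases = 50),
               "insufficient")
  clin$flat <- 1
  expect_error(assemble_design(list(MRI = mri), clin,
                               outcome_spec("flat", "continuous"),
                               min_cases = 5), "degenerate|zero variance")
})

test_that("the combined-model design has 1 + r_mri + r_fdg columns", {
  ids <- sprintf("p%02d", 1:30)
  clin <- clinical_table(data.frame(subject_id = ids, age = runif(30, 55, 85),
                                    y = rnorm(30)))
  d <- assemble_design(list(MRI = make_loads(ids, 9), FDG = make_loads(ids, 14)),
                       clin, outcome_spec("y", "continuous"))
  expect_equal(ncol(d$design), 24)               # age + 9 + 14
})

test_that("elastic net shows ridge symmetry and recovers strong signal", {
  set.seed(71)
  n <- 120
  x <- runif(n)
  design <- cbind(age = runif(n, 55, 85), a = x, b = x)  # duplicated predictor
  y <- 3 * x + rnorm(n, 0, 0.1)
  fit <- fit_elastic_net(design, y, family = "continuous", alpha = 0,
                         seed = 4, thresh = 1e-16)
  expect_equal(fit$coefficients[["a"]], fit$coefficients[["b"]],
               tolerance = 1e-6)

  # strong-signal held-out R^2
  set.seed(72)
  n <- 200
  L <- matrix(runif(n * 3, 0, 0.5), n, 3,
              dimnames = list(NULL, c("c1", "c2", "c3")))
  des <- cbind(age = runif(n, 55, 85), L)
  yy <- 2 * L[, 1] + rnorm(n, 0, 0.05)
  tr <- 1:150; te <- 151:200
  mod <- fit_elastic_net(des[tr, ], yy[tr], "continuous", alpha = 0.2,
                         seed = 5)
  pred <- predict_outcome(mod, des[te, ])
  expect_gte(r_squared(yy[te], pred), 0.8)

  # training predictions are reproduced bitwise
  expect_identical(predict_outcome(mod, des[tr, ]), mod$training)

  # hand-computed linear predictor for one row
  row <- des[155, , drop = FALSE]
  by_hand <- mod$intercept + sum(mod$coefficients * as.numeric(row))
  expect_equal(pred[5], by_hand, tolerance = 1e-12)

  expect_error(predict_outcome(mod, des[te, c(2, 1, 3, 4)]), "match")
})

test_that("binary elastic net predicts probabilities and enforces balance", {
  set.seed(81)
  n <- 200
  L <- matrix(runif(n * 2, 0, 0.5), n, 2, dimnames = list(NULL, c("c1", "c2")))
  des <- cbind(age = runif(n, 55, 85), L)
  y <- rbinom(n, 1, plogis(-2 + 10 * L[, 1]))
  mod <- fit_elastic_net(des, y, "binary", alpha = 0.2, seed = 6)
  pred <- predict_outcome(mod, des)
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  expect_true(all(pred$label %in% 0:1))
  cc <- confusion_counts(y, pred$label)
  expect_gt(mcc(cc$tp, cc$fp, cc$tn, cc$fn), 0)

  y_rare <- c(rep(0, n - 2), 1, 1)
  expect_error(fit_elastic_net(des, y_rare, "binary", outcome_name = "rare"),
               "imbalance.*rare")
})

test_that("regularization path shrinks the l1 norm monotonically", {
  set.seed(91)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- X %*% c(2, -1, 0.5, 0, 0) + rnorm(n, 0, 0.3)
  fit <- glmnet::glmnet(X, y, alpha = 0.5)       # path oracle
  l1 <- colSums(abs(as.matrix(fit$beta)))
  expect_true(all(diff(rev(l1)) <= 1e-8))        # increasing lambda direction
})

test_that("mcc and accuracy reproduce the worked confusion examples", {
  # 16 subjects with the sign, 12 predicted positive; 4 without, 3 positive
  expect_equal(mcc(tp = 12, fp = 3, tn = 1, fn = 4), 0)
  expect_equal(accuracy(tp = 12, fp = 3, tn = 1, fn = 4), 0.65)
  # 8/16 true positives, 0/4 false positives
  expect_equal(round(mcc(tp = 8, fp = 0, tn = 4, fn = 8), 3), 0.408)
  expect_equal(accuracy(tp = 8, fp = 0, tn = 4, fn = 8), 0.6)

  expect_equal(mcc(10, 0, 5, 0), 1)              # perfect classifier
  expect_equal(accuracy(0, 7, 0, 3), 0)          # everything wrong
  expect_equal(mcc(5, 0, 0, 5), 0)               # zero marginal convention
  expect_error(mcc(-1, 0, 0, 1), "nonnegative")
  expect_error(accuracy(0, 0, 0, 0), "empty")
})

test_that("mcc equals the Pearson correlation of indicator vectors", {
  # brute force over all 2x2 tables with total <= 6
  for (total in 2:6) {
    parts <- expand.grid(tp = 0:total, fp = 0:total, tn = 0:total)
    parts$fn <- total - parts$tp - parts$fp - parts$tn
    parts <- parts[parts$fn >= 0, ]
    for (i in seq_len(nrow(parts))) {
      p <- parts[i, ]
      truth <- c(rep(1, p$tp), rep(0, p$fp), rep(0, p$tn), rep(1, p$fn))
      pred <- c(rep(1, p$tp), rep(1, p$fp), rep(0, p$tn), rep(0, p$fn))
      m <- mcc(p$tp, p$fp, p$tn, p$fn)
      r <- suppressWarnings(cor(truth, pred))
      if (is.na(r)) expect_equal(m, 0) else expect_equal(m, r, tolerance = 1e-12)
    }
  }
  # symmetry under class swap; antisymmetry under prediction flip
  expect_equal(mcc(7, 2, 5, 3), mcc(5, 3, 7, 2))
  expect_equal(mcc(7, 2, 5, 3), -mcc(2, 7, 3, 5))
})

test_that("r_squared and the absolute-error summaries match hand arithmetic", {
  y <- c(1, 2, 3); yhat <- c(1, 1, 5)
  expect_equal(median_abs_error(y, yhat), 1)     # errors {0, 1, 2}
  expect_equal(mean_abs_error(y, yhat), 1)
  expect_equal(r_squared(y, yhat), -1.5)         # 1 - 5/2
  expect_equal(r_squared(y, y), 1)
  expect_equal(mean_abs_error(y, y), 0)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_error(r_squared(y, 1:4), "mismatch")
  expect_error(r_squared(c(1, 1), c(1, 2)), "variance")
})

test_that("sign-flip permutation test: exact, Monte-Carlo, and null level", {
  expect_equal(compare_paired_errors(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 1)

  # 8 all-positive distinct differences: only the two all-same-sign flips
  # reach |mean(d)|, so exact two-sided p = 2/256
  a <- c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9, 7.3, 8.8); b <- rep(0, 8)
  expect_equal(compare_paired_errors(a, b), 2 / 256)

  # Monte-Carlo branch agrees with exact enumeration on an n = 12 replica
  set.seed(15)
  d <- rnorm(12, 0.4, 1)
  p_exact <- compare_paired_errors(d, rep(0, 12))
  d30 <- c(d, rep(0, 18))                        # pad to force MC (n = 30)
  p_mc <- compare_paired_errors(d30, rep(0, 30), n_perm = 10000, seed = 2)
  expect_lt(abs(p_mc - p_exact), 0.02)

  # type-I error at alpha = 0.05 over 1000 null simulations
  set.seed(16)
  rejections <- 0L
  for (s in 1:1000) {
    dd <- rnorm(12)
    if (compare_paired_errors(dd, rep(0, 12)) <= 0.05)
      rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / 1000 - 0.05), 0.02)

  expect_error(compare_paired_errors(1:3, 1:3), ">= 5")
})

test_that("fdr_adjust implements Benjamini-Hochberg step-up", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # textbook formula oracle: min over the tail of p * m / rank
  set.seed(17)
  for (k in 1:20) {
    p <- runif(sample(2:12, 1))
    q_ref <- stats::p.adjust(p, method = "BH")
    expect_equal(fdr_adjust(p), q_ref, tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(fdr_adjust(p[perm]), fdr_adjust(p)[perm])
  }
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})
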