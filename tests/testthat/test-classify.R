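rand_matrix <- function(n = 20, p = 30, seed = 1, group = rep(c("case", "control"), each = n / 2)) {
  set.seed(seed)
  vals <- matrix(abs(rnorm(n * p, 100, 20)), n, p,
                 dimnames = list(sprintf("s%02d", 1:n),
                                 paste0("TRBV", 1:p, "|TRBJ1")))
  structure(list(values = vals, group = group), class = "vj_matrix")
}

test_that("roc_auc closed forms and pairwise-concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0)), 0.75)
  # all 4-sample score/label configurations over a tied grid
  grid <- expand.grid(s1 = 1:3, s2 = 1:3, s3 = 1:3, s4 = 1:3) / 4
  labsets <- Filter(function(l) any(l == 1) && any(l == 0),
                    lapply(0:15, function(k) as.integer(intToBits(k)[1:4])))
  for (i in seq_len(nrow(grid))) {
    sc <- as.numeric(grid[i, ])
    for (l in labsets)
      expect_equal(roc_auc(sc, l), auc_oracle(sc, l))
  }
})

test_that("bootstrap CI: separable upper bound, level monotonicity, coverage of the point AUC", {
  scores <- c(0.99, 0.9, 0.85, 0.2, 0.15, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  ci <- auc_bootstrap_ci(scores, labels, n_boot = 500, seed = 4)
  expect_equal(ci$high, 1.0)
  narrow <- auc_bootstrap_ci(scores, labels, n_boot = 500, level = 0.5, seed = 4)
  expect_lte(narrow$high - narrow$low, ci$high - ci$low)
  # interval contains the point AUC on random-score data
  set.seed(6)
  contained <- vapply(1:50, function(s) {
    sc <- runif(20); lb <- rep(c(1, 0), 10)
    a <- roc_auc(sc, lb)
    ci <- auc_bootstrap_ci(sc, lb, n_boot = 200, seed = s)
    ci$low <= a && a <= ci$high
  }, TRUE)
  expect_gte(mean(contained), 0.99)
})

test_that("loocv_classify: separable cohort gives AUC 1 and is deterministic", {
  m <- rand_matrix(seed = 2)
  m$values[, 1] <- ifelse(m$group == "case", 500, 10)  # perfect separator
  res <- loocv_classify(m, n_trees = 200, n_boot = 200, seed = 3)
  expect_equal(res$auc, 1.0)
  expect_true(all(res$oof$oof_probability >= 0 & res$oof$oof_probability <= 1))
  expect_lte(res$ci_low, res$auc)
  expect_gte(res$ci_high, res$auc)
  res2 <- loocv_classify(m, n_trees = 200, n_boot = 200, seed = 3)
  expect_identical(res, res2)
  # the perfect separator dominates the importance ranking
  expect_equal(names(res$importance)[1], colnames(m$values)[1])
  expect_error(loocv_classify(rand_matrix(n = 4, seed = 1)), "3 samples")
})

test_that("out-of-fold discipline: fold i never sees row i in training", {
  m <- rand_matrix(n = 10, p = 8, seed = 9)
  m$values[, 2] <- ifelse(m$group == "case", 300, 20)
  res <- loocv_classify(m, n_trees = 100, n_boot = 100, seed = 11)
  y01 <- as.integer(m$group == "case")
  mtry <- floor(sqrt(8))
  for (i in c(1, 5, 10)) {
    # manual refit on all-but-i (direct forest call, bypassing the fold
    # helper) reproduces the out-of-fold prediction bit for bit
    fit <- tcrlens:::with_seed(derive_seed(11, 4000L + i),
      tcrlens:::rf_fit_predict_cpp(m$values[-i, ], y01[-i],
                                   m$values[i, , drop = FALSE], 100, mtry, 1L))
    expect_identical(res$oof$oof_probability[i], fit$prob[1])
    # mutating row i in the matrix handed to training, while predicting the
    # original row, changes nothing: row i never enters the training set
    xmut <- m$values
    xmut[i, ] <- 1e6
    fit_mut <- tcrlens:::with_seed(derive_seed(11, 4000L + i),
      tcrlens:::rf_fit_predict_cpp(xmut[-i, ], y01[-i],
                                   m$values[i, , drop = FALSE], 100, mtry, 1L))
    expect_identical(fit_mut$prob[1], res$oof$oof_probability[i])
  }
})

test_that("permuted labels give null-centred AUC", {
  m <- rand_matrix(seed = 13)
  aucs <- vapply(1:50, function(s) {
    set.seed(s)
    mp <- m
    mp$group <- sample(m$group)
    loocv_classify(mp, n_trees = 100, n_boot = 50, seed = s)$auc
  }, 0.0)
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("signature importance: constant features score ~0, ranking deterministic", {
  m <- rand_matrix(seed = 17, p = 10)
  m$values[, 4] <- 42  # constant
  m$values[, 7] <- ifelse(m$group == "case", 900, 5)
  res <- loocv_classify(m, n_trees = 200, n_boot = 100, seed = 5)
  sig <- signature_importance(res, top_k = 3)
  expect_equal(sig$combo[1], colnames(m$values)[7])
  expect_equal(unname(res$importance[colnames(m$values)[4]]), 0)
  res2 <- loocv_classify(m, n_trees = 200, n_boot = 100, seed = 5)
  expect_identical(signature_importance(res2, 3), sig)
})

test_that("asymmetric-feature mode selects inside the fold and classifies spiked cohorts", {
  ref <- fix_ref()
  spec <- cohort_spec(n_cases = 6, n_controls = 6, clones_per_sample = 200,
                      reads_per_sample = 4000, error_rate = 0,
                      spiked_combinations = signature_spikes(2e-3), seed = 61)
  reps <- truth_to_repertoires(simulate_truth(spec, ref), spec)
  m <- build_vj_matrix(reps)
  res <- loocv_classify(m, n_trees = 200, n_boot = 100, seed = 7,
                        features = "asymmetric")
  expect_equal(res$features, "asymmetric")
  expect_gte(res$auc, 0.7)
})
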