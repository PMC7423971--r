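#' ROC AUC (Mann-Whitney form)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counted one half; equivalent to the area under the
#' empirical ROC curve.
#'
#' @param scores numeric score vector (higher = more case-like).
#' @param labels binary vector (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  r <- rank(scores)  # midranks: ties contribute 1/2
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples (score, label) pairs with replacement within each class, so
#' every bootstrap draw contains both classes, and returns the percentile
#' interval of the bootstrap AUC distribution.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot number of bootstrap draws.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `low`, `high`, `level`, `n_boot`.
#' @export
auc_bootstrap_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                             seed = 1) {
  labels <- as.logical(labels)
  pos <- which(labels); neg <- which(!labels)
  aucs <- with_seed(derive_seed(seed, 333L), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      roc_auc(scores[idx], labels[idx])
    }, 0.0)
  })
  qs <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(low = qs[1], high = qs[2], level = level, n_boot = n_boot)
}

#' ROC curve points
#'
#' @param scores,labels as in [roc_auc()].
#' @return a `data.table` with `threshold`, `fpr`, `tpr` (one row per
#'   distinct score, plus the endpoints).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  rbindlist(lapply(thr, function(t0) {
    data.table(threshold = t0,
               fpr = mean(scores[!labels] >= t0),
               tpr = mean(scores[labels] >= t0))
  }))
}

# one LOOCV fold: fit on all rows but `i`, predict row i; independently
# seeded so the fold is reproducible in isolation. With features =
# "asymmetric" the feature set is re-selected inside the fold (training
# rows only) so no information about the held-out sample leaks in.
loocv_fold <- function(x, y01, i, n_trees, mtry, seed, features = "all",
                       group = NULL, case_label = "case", min_positive = 3) {
  cols <- seq_len(ncol(x))
  if (features == "asymmetric") {
    mtrain <- structure(list(values = x[-i, , drop = FALSE],
                             group = group[-i]), class = "vj_matrix")
    hits <- detect_asymmetric(mtrain, min_positive = min_positive,
                              case_label = case_label)
    if (nrow(hits))
      cols <- which(colnames(x) %in% paste(hits$v_gene, hits$j_gene, sep = "|"))
  }
  fit <- with_seed(derive_seed(seed, 4000L + i), {
    rf_fit_predict_cpp(x[-i, cols, drop = FALSE], y01[-i],
                       x[i, cols, drop = FALSE], n_trees,
                       min(mtry, length(cols)), 1L)
  })
  imp <- numeric(ncol(x))
  imp[cols] <- fit$importance
  list(prob = fit$prob, importance = imp)
}

#' Leave-one-out cross-validated random-forest classification
#'
#' For each sample, a random forest (CART trees grown to purity, Gini
#' criterion, bootstrap resampling, `mtry` features per split, impurity
#' importance) is fitted on all other samples and the held-out sample's
#' case-probability is recorded. The pooled out-of-fold probabilities give
#' the ROC/AUC; a stratified percentile bootstrap gives the CI. Each fold
#' uses an independently derived seed, so a sample's out-of-fold prediction
#' is independent of its own feature values in training.
#'
#' Pooled ROC scores are the out-of-fold probabilities centered by each
#' fold's training-class prevalence (`prob - mean(y_train)`). Without this,
#' leave-one-out folds are systematically imbalanced (holding out a case
#' leaves one fewer case in training), which biases the pooled null AUC
#' below 0.5; centering makes scores comparable across folds. Both the raw
#' probability and the centered score are reported.
#'
#' @param m a [build_vj_matrix()] result (>= 3 samples per group).
#' @param n_trees trees per forest.
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed.
#' @param n_boot bootstrap draws for the CI.
#' @param case_label the positive-class group label.
#' @param features `"all"` (default: the full V-J matrix) or `"asymmetric"`
#'   (per fold, restrict to combinations flagged by [detect_asymmetric()]
#'   on the training rows only; falls back to all columns when no hit).
#' @return an object of class `loocv_result`: list with `oof` (data.table:
#'   sample_id, group, oof_probability, oof_score), `auc`, `ci_low`,
#'   `ci_high`,
#'   `importance` (named, mean impurity importance across folds, decreasing),
#'   `n_trees`, `mtry`, `seed`.
#' @export
loocv_classify <- function(m, n_trees = 500, mtry = NULL, seed = 1,
                           n_boot = 2000, case_label = "case",
                           features = c("all", "asymmetric")) {
  features <- match.arg(features)
  x <- m$values
  if (any(!is.finite(x))) stop("non-finite feature values")
  y01 <- as.integer(m$group == case_label)
  if (sum(y01) < 3 || sum(1 - y01) < 3)
    stop("need at least 3 samples per group")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  n <- nrow(x)
  prob <- numeric(n)
  imp <- matrix(0, n, ncol(x))
  for (i in seq_len(n)) {
    fit <- loocv_fold(x, y01, i, n_trees, mtry, seed, features = features,
                      group = m$group, case_label = case_label)
    prob[i] <- fit$prob[1]
    imp[i, ] <- fit$importance
  }
  train_prev <- (sum(y01) - y01) / (n - 1)
  score <- prob - train_prev
  auc <- roc_auc(score, y01)
  ci <- auc_bootstrap_ci(score, y01, n_boot = n_boot, seed = seed)
  importance <- colMeans(imp)
  names(importance) <- colnames(x)
  importance <- sort(importance, decreasing = TRUE)
  structure(list(
    oof = data.table(sample_id = rownames(x), group = m$group,
                     oof_probability = prob, oof_score = score),
    auc = auc, ci_low = ci$low, ci_high = ci$high,
    importance = importance, n_trees = n_trees, mtry = mtry, seed = seed,
    features = features
  ), class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("loocv_result: AUC %.3f (95%% CI %.3f-%.3f), %d samples, %d trees\n",
              x$auc, x$ci_low, x$ci_high, nrow(x$oof), x$n_trees))
  invisible(x)
}

#' Top signature V-J combinations by importance
#'
#' @param result a [loocv_classify()] result.
#' @param top_k number of combinations to return.
#' @return a `data.table` with `rank`, `combo`, `importance`.
#' @export
signature_importance <- function(result, top_k = 10) {
  imp <- head(result$importance, top_k)
  data.table(rank = seq_along(imp), combo = names(imp), importance = imp)
}
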