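# Age-group classification from two behavioral features.

#' Response-time change across the direction switch
#'
#' Mean response time in block 5 minus block 4, over observed retrieval
#' trials: the transient cost of encountering familiar intersections from
#' novel viewpoints after the experiment's midpoint.
#'
#' @param trials one subject's canonical trial table.
#' @return Difference in seconds, or `NA` (with attribute
#'   `missing_feature = TRUE`) when either block has no observed response
#'   times.
#' @export
rt_change_feature <- function(trials) {
  retr <- trials[trials$trial_kind == "retrieval", ]
  rt4 <- retr$response_time[retr$block == 4L & !is.na(retr$response_time)]
  rt5 <- retr$response_time[retr$block == 5L & !is.na(retr$response_time)]
  if (length(rt4) == 0L || length(rt5) == 0L) {
    return(structure(NA_real_, missing_feature = TRUE))
  }
  mean(rt5) - mean(rt4)
}

stratified_folds <- function(labels, folds) {
  idx <- integer(length(labels))
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    if (length(members) < folds) {
      stopf("stratification error: class '%s' has %d subjects for %d folds",
            cl, length(members), folds)
    }
    idx[members] <- sample(rep_len(seq_len(folds), length(members)))
  }
  idx
}

rank_auc <- function(labels01, scores) {
  # Wilcoxon/Mann-Whitney identity; ties get half credit
  r <- rank(scores)
  n1 <- sum(labels01 == 1L)
  n0 <- sum(labels01 == 0L)
  (sum(r[labels01 == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classify age group from behavioral features
#'
#' L2-regularized logistic regression on z-scored features with nested
#' stratified cross-validation: the outer folds provide held-out
#' probabilities and a per-fold AUC; an inner cross-validation on each
#' training set picks the regularization strength from a log-spaced grid
#' (10^-3..10^3). Feature scaling is estimated on the training folds only.
#'
#' @param features numeric matrix or data frame (subjects x 2), e.g.
#'   columns `mean_amount` and `rt_change`.
#' @param labels factor or character vector with two classes; the first
#'   level alphabetically is modelled as the positive class unless
#'   `positive` is given.
#' @param folds number of outer (and inner) folds, default 10.
#' @param seed integer seed (fold assignment).
#' @param positive label of the class whose probability is reported
#'   (default `"young"` when present, else the first level).
#' @return A `navlearn_classifier`: out-of-fold `probabilities`,
#'   `fold_auc`, `mean_auc`, `sd_auc`, and the chosen `lambda` per fold.
#' @export
classify_age <- function(features, labels, folds = 10L, seed = 1L,
                         positive = NULL) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stopf("need exactly two classes")
  positive <- positive %||% if ("young" %in% classes) "young" else classes[1]
  yy <- as.integer(labels == positive)

  keep <- apply(x, 2, function(col) stats::sd(col) > 1e-12)
  if (!all(keep)) {
    warnf("dropping constant feature(s): %s",
          paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) stopf("no non-constant features left")

  lambda_grid <- 10^seq(3, -3, length.out = 13)
  with_local_seed(seed, {
    fold_id <- stratified_folds(labels, folds)
    prob <- rep(NA_real_, length(yy))
    fold_auc <- rep(NA_real_, folds)
    fold_lambda <- rep(NA_real_, folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      ctr <- colMeans(x[tr, , drop = FALSE])
      scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      scl[scl < 1e-12] <- 1
      ztr <- sweep(sweep(x[tr, , drop = FALSE], 2, ctr), 2, scl, "/")
      zte <- sweep(sweep(x[!tr, , drop = FALSE], 2, ctr), 2, scl, "/")
      if (ncol(ztr) == 1L) {
        # glmnet requires >= 2 columns; pad with an inert zero column
        ztr <- cbind(ztr, 0)
        zte <- cbind(zte, 0)
      }
      # inner folds: stratified when classes allow it, else plain random;
      # cv.glmnet needs at least 3 folds
      n_inner <- min(max(3L, min(folds, min(table(labels[tr])))), sum(tr))
      inner_id <- if (min(table(labels[tr])) >= n_inner) {
        stratified_folds(labels[tr], n_inner)
      } else {
        sample(rep_len(seq_len(n_inner), sum(tr)))
      }
      cv <- glmnet::cv.glmnet(ztr, yy[tr], family = "binomial", alpha = 0,
                              lambda = lambda_grid, foldid = inner_id,
                              type.measure = "deviance")
      fold_lambda[f] <- cv$lambda.min
      prob[!tr] <- as.numeric(stats::predict(cv, zte, s = "lambda.min",
                                             type = "response"))
      fold_auc[f] <- rank_auc(yy[!tr], prob[!tr])
    }
  })
  structure(list(probabilities = stats::setNames(prob, rownames(x)),
                 positive = positive,
                 fold_auc = fold_auc,
                 mean_auc = mean(fold_auc, na.rm = TRUE),
                 sd_auc = stats::sd(fold_auc),
                 lambda = fold_lambda,
                 overall_auc = rank_auc(yy, prob)),
            class = "navlearn_classifier")
}

#' @export
print.navlearn_classifier <- function(x, ...) {
  cat(sprintf("<navlearn_classifier> P(%s): mean AUC %.3f +/- %.3f over %d folds\n",
              x$positive, x$mean_auc, x$sd_auc, length(x$fold_auc)))
  invisible(x)
}
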