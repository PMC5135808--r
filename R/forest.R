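# Random forest training and evaluation on labeled feature tables.
#
# A "feature table" is a tibble holding the 35 feature columns of
# feature_schema() plus a logical `label` column and (for sample-wise CV) a
# `sample_id` column. The forest is the randomForest implementation with its
# classification defaults (mtry = floor(sqrt(35)) = 5, unlimited depth,
# bootstrap with replacement, node size 1), 1000 trees unless overridden.

feature_matrix <- function(table) {
  feats <- feature_schema()
  missing <- setdiff(feats, names(table))
  extra <- setdiff(
    names(table),
    c(
      feats, "label", "sample_id", "chrom", "pos", "ref", "alt",
      "cancer_type", "gene_id", "key"
    )
  )
  if (length(missing) > 0 || length(extra) > 0) {
    rlang::abort(sprintf(
      "feature schema mismatch; missing: [%s]; unexpected: [%s]",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")
    ))
  }
  m <- as.matrix(table[, feats])
  if (any(!is.finite(m))) rlang::abort("non-finite feature value")
  m
}

label_factor <- function(table) {
  assert_cols(table, "label", "feature table")
  factor(ifelse(table$label, "true", "false"), levels = c("false", "true"))
}

#' Train the random forest classifier
#'
#' Fits a classification forest (default 1000 trees) on the feature columns
#' of a labeled feature table. The returned object wraps the randomForest
#' fit together with out-of-bag vote proportions and in-bag counts, and is
#' fully reproducible for a fixed seed.
#'
#' @param table feature table with the 35 schema columns and a logical
#'   `label` column; both classes must be present with >= 2 rows each.
#' @param n_trees number of trees (default 1000).
#' @param seed RNG seed.
#' @param mtry variables tried per split (default `floor(sqrt(35))`).
#' @param importance also compute permutation variable importance (default
#'   `FALSE`; it roughly doubles training time and only
#'   [variable_importance()] and [tidy()] need it).
#' @return an object of class `recur_forest`: list with the `fit`, the
#'   training `votes` (out-of-bag positive-vote proportion per row),
#'   `inbag` counts, and the training schema.
#' @export
train_forest <- function(table, n_trees = 1000, seed = 1,
                         mtry = floor(sqrt(length(feature_schema()))),
                         importance = FALSE) {
  x <- feature_matrix(table)
  y <- label_factor(table)
  if (any(table(y) < 2)) {
    rlang::abort("need >= 2 rows per class to train")
  }
  fit <- withr::with_seed(seed, randomForest::randomForest(
    x, y,
    ntree = n_trees, mtry = mtry, importance = importance, keep.inbag = TRUE
  ))
  structure(
    list(
      fit = fit,
      votes = unname(fit$votes[, "true"]),
      inbag = fit$inbag,
      n_trees = n_trees,
      seed = seed,
      schema = feature_schema()
    ),
    class = "recur_forest"
  )
}

#' @export
print.recur_forest <- function(x, ...) {
  cat(sprintf(
    "# recur_forest: %d trees, OOB error %.3f\n",
    x$n_trees, tail(x$fit$err.rate[, "OOB"], 1)
  ))
  invisible(x)
}

#' Positive-vote proportions for new mutations
#'
#' Runs every tree of a trained forest on new feature rows and returns the
#' proportion voting for the recurrent class; rows are rankable by vote for
#' top-voted selection.
#'
#' @param forest a `recur_forest`.
#' @param table feature table whose feature columns match the training
#'   schema (extra identifying columns allowed; mismatches error naming the
#'   offending columns).
#' @return `table` as a tibble with an added `vote` column in `[0, 1]`.
#' @export
predict_votes <- function(forest, table) {
  x <- feature_matrix(table)
  v <- stats::predict(forest$fit, x, type = "vote", norm.votes = TRUE)
  out <- as_tibble(table)
  out$vote <- unname(v[, "true"])
  out
}

#' Tie-aware ROC AUC
#'
#' Area under the ROC curve via the Mann-Whitney rank statistic with midrank
#' handling of ties; identical to the trapezoidal area under the tie-aware
#' ROC curve.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical (or coercible) true class per score.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE)) # 1
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("both classes must be present to compute AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC points (FPR, TPR) with ties collapsed, from (0,0) to (1,1)
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(l)[keep] / sum(l)
  fpr <- cumsum(!l)[keep] / sum(!l)
  tibble(fpr = c(0, fpr), tpr = c(0, tpr))
}

# stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin into `folds` groups
stratified_folds <- function(labels, folds, seed) {
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      assignment[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, rows are dealt into `folds` label-stratified folds
#' (seeded); each fold is held out once, votes from a forest trained on the
#' remainder are pooled over the folds, and the pooled votes give that
#' repeat's AUC. The report's "average AUC" is the mean over repeats.
#'
#' @param table labeled feature table.
#' @param folds number of folds (default 5); every class must have at least
#'   `folds` rows.
#' @param repeats number of repeats (default 10).
#' @param n_trees trees per forest (default 1000).
#' @param seed RNG seed; fold assignments and forests derive from it.
#' @return a `recur_cv` object: list with `auc` (per-repeat AUCs),
#'   `mean_auc`, `roc` (pooled ROC points over all repeats), `votes`
#'   (per-row held-out votes per repeat), and the call parameters.
#' @export
repeated_cv <- function(table, folds = 5, repeats = 10, n_trees = 1000,
                        seed = 1) {
  y <- label_factor(table)
  if (any(table(y) < folds)) {
    rlang::abort("each class needs at least `folds` rows")
  }
  aucs <- numeric(repeats)
  vote_mat <- matrix(NA_real_, nrow = nrow(table), ncol = repeats)
  for (r in seq_len(repeats)) {
    fold_of <- stratified_folds(y, folds, derive_seed(seed, r))
    votes <- numeric(nrow(table))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      forest <- train_forest(table[!test, , drop = FALSE],
        n_trees = n_trees, seed = derive_seed(seed, r * 100 + f)
      )
      votes[test] <- predict_votes(forest, table[test, , drop = FALSE])$vote
    }
    vote_mat[, r] <- votes
    aucs[r] <- roc_auc(votes, table$label)
  }
  pooled <- roc_points(as.vector(vote_mat), rep(table$label, repeats))
  structure(
    list(
      auc = aucs, mean_auc = mean(aucs), roc = pooled, votes = vote_mat,
      folds = folds, repeats = repeats, n_trees = n_trees, seed = seed
    ),
    class = "recur_cv"
  )
}

#' @export
print.recur_cv <- function(x, ...) {
  cat(sprintf(
    "# recur_cv: %d-repeated %d-fold CV, mean AUC %.3f (range %.3f-%.3f)\n",
    x$repeats, x$folds, x$mean_auc, min(x$auc), max(x$auc)
  ))
  invisible(x)
}

#' Permute the labels of a feature table
#'
#' Uniformly permutes the `label` column across rows (features untouched),
#' preserving class balance; the control used to check that classifier
#' performance collapses to chance without a feature-label association.
#'
#' @param table labeled feature table.
#' @param seed RNG seed.
#' @return the table with permuted labels.
#' @export
randomize_labels <- function(table, seed = 1) {
  out <- as_tibble(table)
  out$label <- withr::with_seed(seed, sample(out$label))
  out
}

#' Leave-one-sample-out cross-validation
#'
#' For each distinct `sample_id`, all of that sample's rows form the test
#' set and a forest is trained on the remaining samples' rows — never on any
#' row of the held-out sample. Within each training set the false rows are
#' re-sampled (seeded) down to `ratio` times the true rows, mirroring how
#' training sets are constructed.
#'
#' @param table labeled feature table with a `sample_id` column; >= 2
#'   distinct samples.
#' @param n_trees trees per forest (default 1000).
#' @param ratio false:true ratio enforced within each training set
#'   (default 3).
#' @param seed RNG seed.
#' @return a tibble of vote records: the identifying columns of `table`
#'   plus `vote`, one row per input row.
#' @export
loocv_by_sample <- function(table, n_trees = 1000, ratio = 3, seed = 1) {
  assert_cols(table, c("sample_id", "label"), "feature table")
  samples <- unique(table$sample_id)
  if (length(samples) < 2) rlang::abort("need >= 2 distinct samples")
  out <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    test <- table$sample_id == s
    train <- table[!test, , drop = FALSE]
    stopifnot(!any(train$sample_id == s)) # leakage guard
    true_rows <- which(train$label)
    false_rows <- which(!train$label)
    n_false <- min(length(false_rows), ratio * length(true_rows))
    keep_false <- withr::with_seed(
      derive_seed(seed, k),
      sample(false_rows, n_false, replace = FALSE)
    )
    train <- train[c(true_rows, keep_false), , drop = FALSE]
    forest <- train_forest(train, n_trees = n_trees, seed = derive_seed(seed, 1000 + k))
    out[[k]] <- predict_votes(forest, table[test, , drop = FALSE])
  }
  dplyr::bind_rows(out)
}

#' Permutation variable importance (Mean Decrease Accuracy)
#'
#' For each feature: per-tree accuracy on out-of-bag rows minus accuracy
#' after permuting that feature's out-of-bag values, averaged over trees and
#' expressed in percentage points. This is the unscaled permutation
#' importance of the randomForest implementation; values can be slightly
#' negative for uninformative features.
#'
#' @param table labeled feature table.
#' @param n_trees trees (default 1000).
#' @param seed RNG seed.
#' @return a tibble `(feature, mda)` sorted in schema order.
#' @export
variable_importance <- function(table, n_trees = 1000, seed = 1) {
  forest <- train_forest(table, n_trees = n_trees, seed = seed, importance = TRUE)
  imp <- randomForest::importance(forest$fit, type = 1, scale = FALSE)
  tibble(
    feature = rownames(imp),
    mda = as.numeric(imp[, "MeanDecreaseAccuracy"]) * 100
  )
}
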