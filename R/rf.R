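#' Configuration of the resistance classifier
#'
#' Hyperparameters of the random-forest model and its evaluation scheme:
#' an 80:20 stratified train-to-validation split and stratified 5-fold
#' cross-validation on the training part. Forest hyperparameters follow
#' common defaults (500 trees, sqrt(p) candidate features per split, minimum
#' node size 5). Feature importance is, by default, permutation importance
#' measured on each held-out fold (AUC drop when a feature is permuted),
#' which is model-agnostic and fold-aware; impurity importance is available
#' as an alternative.
#'
#' @param train_fraction fraction of patients in the training set (default 0.8).
#' @param n_folds number of cross-validation folds (default 5).
#' @param n_trees number of trees per forest (default 500).
#' @param min_leaf minimum node size (default 5).
#' @param mtry number of candidate features per split; `NULL` = `sqrt(p)`.
#' @param importance_method `"permutation"` (held-out-fold AUC drop) or
#'   `"impurity"` (Gini importance from the fitted forest).
#' @param n_perm permutations per feature for permutation importance.
#' @param seed integer seed controlling the split, fold assignment, forests
#'   and permutations.
#' @return object of class `model_config`.
#' @export
model_config <- function(train_fraction = 0.8, n_folds = 5L, n_trees = 500L,
                         min_leaf = 5L, mtry = NULL,
                         importance_method = c("permutation", "impurity"),
                         n_perm = 3L, seed = 1L) {
  importance_method <- match.arg(importance_method)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  if (n_trees < 1L) stop("n_trees must be at least 1", call. = FALSE)
  structure(list(train_fraction = train_fraction, n_folds = as.integer(n_folds),
                 n_trees = as.integer(n_trees), min_leaf = as.integer(min_leaf),
                 mtry = mtry, importance_method = importance_method,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "model_config")
}

# coerce a feature data.frame to the all-numeric matrix the forest consumes
as_feature_matrix <- function(features) {
  x <- features
  x$patient_id <- NULL
  if (!is.null(x$gender)) x$gender <- as.numeric(x$gender == "female")
  for (col in names(x)) {
    if (is.logical(x[[col]])) x[[col]] <- as.numeric(x[[col]])
    if (!is.numeric(x[[col]]))
      stop("feature column '", col, "' is not numeric", call. = FALSE)
  }
  as.matrix(x)
}

# column-median imputation: medians estimated on `ref`, applied to `x`
impute_medians <- function(ref, x = ref) {
  med <- apply(ref, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

#' Stratified train/validation split
#'
#' Partitions patients into disjoint, exhaustive train and validation sets,
#' preserving the class balance to within one patient per class. Seeded and
#' reproducible.
#'
#' @param features feature data.frame or matrix (one row per patient).
#' @param labels logical (or 0/1) outcome vector; both classes must be
#'   present and at least 10 patients labeled.
#' @param config a [model_config()].
#' @return list with elements `train` and `validation`, each holding
#'   `features`, `labels` and the row indices `idx`.
#' @export
split_train_validate <- function(features, labels, config = model_config()) {
  labels <- as.logical(labels)
  n <- length(labels)
  if (nrow(as.data.frame(features)) != n)
    stop("features and labels lengths differ", call. = FALSE)
  if (n < 10L) stop("need at least 10 labeled patients", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  local_seed(config$seed)
  train_idx <- integer(0)
  for (cl in c(TRUE, FALSE)) {
    idx <- which(labels == cl)
    k <- round(config$train_fraction * length(idx))
    train_idx <- c(train_idx, sample(idx, k))
  }
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_len(n), train_idx)
  subset_rows <- function(i) {
    f <- if (is.matrix(features)) features[i, , drop = FALSE]
         else features[i, , drop = FALSE]
    list(features = f, labels = labels[i], idx = i)
  }
  list(train = subset_rows(train_idx), validation = subset_rows(val_idx))
}

# stratified fold assignment; re-seeded re-draws are handled by the caller
assign_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# probability-of-resistance predictions from a ranger forest
rf_predict <- function(model, x) {
  pr <- predict(model, data = as.data.frame(x))$predictions
  pr[, "TRUE"]
}

# Mann-Whitney AUC with midrank tie handling (no input-domain checks)
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated feature importance ranking
#'
#' Runs stratified k-fold cross-validation of the random forest on the given
#' (training) patients. Within each fold, features are ranked 1 (most
#' important) to p by the configured importance measure; a feature's rank
#' score is the mean of its per-fold ranks (with 5 folds, a multiple of 0.2).
#' Out-of-fold predicted probabilities are pooled into the composite ROC-AUC.
#'
#' @inheritParams split_train_validate
#' @return object of class `hu_rf_cv` with elements
#'   `ranking` (data.frame: `feature`, `fold_1..fold_k` ranks, `rank_score`,
#'   `direction` -- the sign of the resistant-minus-non-resistant group mean
#'   -- sorted by rank score), `per_fold_auc`, `oof` (pooled out-of-fold
#'   probabilities, input order), `composite_auc`, `folds`, `config`.
#' @export
cross_validated_importance <- function(features, labels, config = model_config()) {
  labels <- as.logical(labels)
  x <- as_feature_matrix(as.data.frame(features))
  p <- ncol(x)
  n <- nrow(x)
  if (length(labels) != n) stop("features and labels lengths differ", call. = FALSE)
  if (min(table(labels)) < config$n_folds)
    stop("need at least n_folds patients per class", call. = FALSE)
  local_seed(config$seed)

  fold <- assign_folds(labels, config$n_folds)
  for (attempt in seq_len(5L)) {
    ok <- all(vapply(seq_len(config$n_folds), function(f)
      length(unique(labels[fold == f])) == 2L &&
      length(unique(labels[fold != f])) == 2L, logical(1)))
    if (ok) break
    if (attempt == 5L)
      stop("could not build folds containing both classes after 5 attempts",
           call. = FALSE)
    fold <- assign_folds(labels, config$n_folds)
  }

  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(p))) else config$mtry
  ranks <- matrix(NA_integer_, p, config$n_folds,
                  dimnames = list(colnames(x), NULL))
  oof <- rep(NA_real_, n)
  per_fold_auc <- numeric(config$n_folds)

  for (f in seq_len(config$n_folds)) {
    in_f <- fold != f
    xtr <- impute_medians(x[in_f, , drop = FALSE])
    xte <- impute_medians(x[in_f, , drop = FALSE], x[!in_f, , drop = FALSE])
    fit <- ranger::ranger(
      x = as.data.frame(xtr), y = factor(labels[in_f], levels = c(FALSE, TRUE)),
      num.trees = config$n_trees, mtry = mtry, min.node.size = config$min_leaf,
      probability = TRUE, seed = config$seed + f,
      importance = if (config$importance_method == "impurity") "impurity" else "none",
      num.threads = 1L)
    pred <- rf_predict(fit, xte)
    oof[!in_f] <- pred
    per_fold_auc[f] <- auc_rank(pred, labels[!in_f])

    if (config$importance_method == "impurity") {
      imp <- fit$variable.importance
    } else {
      base <- per_fold_auc[f]
      imp <- vapply(seq_len(p), function(j) {
        drops <- vapply(seq_len(config$n_perm), function(r) {
          xp <- xte
          xp[, j] <- sample(xp[, j])
          base - auc_rank(rf_predict(fit, xp), labels[!in_f])
        }, numeric(1))
        mean(drops)
      }, numeric(1))
      names(imp) <- colnames(x)
    }
    # ties broken at random inside the seeded scope: deterministic given the
    # config seed, but without the positional bias of ties.method = "first"
    ranks[, f] <- rank(-imp, ties.method = "random")
  }

  direction <- vapply(seq_len(p), function(j) {
    d <- mean(x[labels, j], na.rm = TRUE) - mean(x[!labels, j], na.rm = TRUE)
    if (is.na(d)) 0 else sign(d)
  }, numeric(1))

  ranking <- data.frame(feature = colnames(x), stringsAsFactors = FALSE)
  for (f in seq_len(config$n_folds)) ranking[[paste0("fold_", f)]] <- ranks[, f]
  ranking$rank_score <- rowMeans(ranks)
  ranking$direction <- direction
  ranking <- ranking[order(ranking$rank_score, ranking$feature), ]
  rownames(ranking) <- NULL

  structure(list(ranking = ranking, per_fold_auc = per_fold_auc, oof = oof,
                 composite_auc = auc_rank(oof, labels), folds = fold,
                 config = config),
            class = "hu_rf_cv")
}

#' @export
print.hu_rf_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated random forest (composite ROC-AUC %.3f)\n",
              x$config$n_folds, x$composite_auc))
  cat("Top features by mean rank:\n")
  print(head(x$ranking[, c("feature", "rank_score", "direction")], 10L),
        row.names = FALSE)
  invisible(x)
}

#' Composite ROC-AUC of pooled out-of-fold predictions
#'
#' The area under the receiver operating characteristic curve computed as
#' the Mann-Whitney probability that a randomly chosen resistant patient
#' receives a higher score than a randomly chosen non-resistant one, ties
#' counted half.
#'
#' @param scores per-patient scores in `[0, 1]`.
#' @param labels logical (or 0/1) outcome vector; both classes required.
#' @return numeric AUC in `[0, 1]`.
#' @export
composite_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  auc_rank(scores, labels)
}

#' Fit the full resistance classifier
#'
#' Convenience wrapper: stratified 80:20 split, cross-validated importance
#' ranking on the training part, a final forest on the full training part
#' and its ROC-AUC on the held-back validation patients.
#'
#' @inheritParams split_train_validate
#' @return object of class `hu_rf`: `cv` (a `hu_rf_cv`), `top10` (first ten
#'   rows of the ranking), `validation_auc`, `model` (the final ranger
#'   forest), `split`.
#' @export
fit_resistance_model <- function(features, labels, config = model_config()) {
  sp <- split_train_validate(features, labels, config)
  cv <- cross_validated_importance(sp$train$features, sp$train$labels, config)
  xtr <- as_feature_matrix(as.data.frame(sp$train$features))
  xval <- as_feature_matrix(as.data.frame(sp$validation$features))
  xval <- impute_medians(xtr, xval)
  xtr <- impute_medians(xtr)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(xtr)))) else config$mtry
  fit <- ranger::ranger(
    x = as.data.frame(xtr),
    y = factor(sp$train$labels, levels = c(FALSE, TRUE)),
    num.trees = config$n_trees, mtry = mtry, min.node.size = config$min_leaf,
    probability = TRUE, seed = config$seed, num.threads = 1L)
  val_auc <- auc_rank(rf_predict(fit, xval), sp$validation$labels)
  structure(list(cv = cv, top10 = head(cv$ranking, 10L),
                 validation_auc = val_auc, model = fit, split = sp,
                 config = config),
            class = "hu_rf")
}

#' @export
print.hu_rf <- function(x, ...) {
  cat(sprintf("Resistance classifier: composite CV ROC-AUC %.3f, validation ROC-AUC %.3f\n",
              x$cv$composite_auc, x$validation_auc))
  cat("Top 10 features:\n")
  print(x$top10[, c("feature", "rank_score", "direction")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.hu_rf <- function(object, ...) {
  print(object)
  cat(sprintf("Per-fold ROC-AUC: %s\n",
              paste(sprintf("%.3f", object$cv$per_fold_auc), collapse = ", ")))
  invisible(object)
}
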