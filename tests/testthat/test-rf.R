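make_features <- function(n, p = 6, seed = 1) {
  set.seed(seed)
  as.data.frame(matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", seq_len(p)))))
}

test_that("train/validation split is stratified, disjoint, exhaustive and seeded", {
  X <- make_features(100)
  y <- rep(c(TRUE, FALSE), c(60, 40))
  sp <- split_train_validate(X, y, model_config(seed = 3))
  expect_equal(length(sp$train$idx), 80)
  expect_equal(length(sp$validation$idx), 20)
  expect_equal(sort(c(sp$train$idx, sp$validation$idx)), 1:100)
  # class proportions preserved to within one patient per class
  expect_equal(sum(sp$train$labels), 48)
  expect_equal(sum(sp$validation$labels), 12)
  sp2 <- split_train_validate(X, y, model_config(seed = 3))
  expect_identical(sp$train$idx, sp2$train$idx)
  sp3 <- split_train_validate(X, y, model_config(seed = 4))
  expect_false(identical(sp$train$idx, sp3$train$idx))
  expect_error(split_train_validate(X, rep(TRUE, 100), model_config()),
               "both outcome classes")
  expect_error(split_train_validate(X[1:8, ], y[1:8], model_config()), "10")
})

test_that("rank scores are means of per-fold rank permutations", {
  X <- make_features(150, seed = 5)
  y <- X$f1 + rnorm(150) > 0
  cv <- cross_validated_importance(X, y, model_config(n_trees = 100, seed = 2))
  rk <- cv$ranking
  folds <- paste0("fold_", 1:5)
  for (f in folds) expect_setequal(rk[[f]], 1:6)
  expect_equal(rk$rank_score, rowMeans(rk[folds]))
  # with 5 folds every rank score is a multiple of 0.2
  expect_true(all(abs(rk$rank_score * 5 - round(rk$rank_score * 5)) < 1e-12))
  expect_true(all(diff(rk$rank_score) >= 0))
})

test_that("a label-determining feature is ranked first in every fold", {
  for (seed in 1:10) {
    X <- make_features(150, p = 5, seed = seed)
    y <- X$f3 > median(X$f3)      # f3 alone determines the label
    cv <- cross_validated_importance(X, y, model_config(n_trees = 100,
                                                        seed = seed))
    expect_equal(cv$ranking$feature[1], "f3")
    expect_equal(cv$ranking$rank_score[1], 1.0)
  }
})

test_that("pure-noise features have exchangeable mean ranks", {
  p <- 5
  set.seed(77)
  scores <- replicate(40, {
    seed <- sample.int(1e6, 1)
    X <- make_features(60, p = p, seed = seed)
    y <- rep(c(TRUE, FALSE), 30)
    cv <- cross_validated_importance(X, y, model_config(n_trees = 60, n_perm = 1,
                                                        seed = seed))
    cv$ranking$rank_score[match(paste0("f", 1:p), cv$ranking$feature)]
  })
  m <- rowMeans(scores)
  expect_true(all(abs(m - (p + 1) / 2) < 0.6))
})

test_that("direction of association follows the group means", {
  X <- make_features(200, p = 3, seed = 9)
  y <- runif(200) < plogis(2 * X$f1 - 2 * X$f2)
  cv <- cross_validated_importance(X, y, model_config(n_trees = 50, seed = 1))
  rk <- cv$ranking
  expect_equal(rk$direction[rk$feature == "f1"], 1)
  expect_equal(rk$direction[rk$feature == "f2"], -1)
})

test_that("composite AUC is the tie-aware Mann-Whitney probability", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(composite_auc(c(0.9, 0.8, 0.2, 0.1), y), 1.0)
  expect_equal(composite_auc(rep(0.5, 4), y), 0.5)
  expect_equal(composite_auc(c(0.1, 0.2, 0.8, 0.9), y), 0.0)
  for (s in 1:5) {
    set.seed(s)
    sc <- round(runif(30), 2)   # rounding forces ties
    yy <- runif(30) < 0.5
    if (length(unique(yy)) < 2) next
    expect_equal(composite_auc(sc, yy), oracle_auc(sc, yy))
  }
  expect_error(composite_auc(c(0.5, 0.5), c(TRUE, TRUE)), "both outcome classes")
  expect_error(composite_auc(c(1.5, 0.5), y[c(1, 3)]), "0, 1")
})

test_that("the fitted classifier separates a planted signal on held-out patients", {
  X <- make_features(300, p = 6, seed = 13)
  y <- runif(300) < plogis(1.5 * X$f1 + 1.5 * X$f2)
  m <- fit_resistance_model(X, y, model_config(n_trees = 150, seed = 7))
  expect_gt(m$cv$composite_auc, 0.6)
  expect_gt(m$validation_auc, 0.6)
  expect_true(all(m$cv$oof >= 0 & m$cv$oof <= 1))
  expect_equal(m$cv$composite_auc, composite_auc(m$cv$oof, m$split$train$labels))
})

test_that("median imputation is fit on the training side only", {
  X <- make_features(120, p = 4, seed = 15)
  y <- X$f1 > 0
  X$f2[sample(120, 30)] <- NA
  m <- fit_resistance_model(X, y, model_config(n_trees = 50, seed = 2))
  expect_true(is.finite(m$validation_auc))  # NA features handled end to end
})
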