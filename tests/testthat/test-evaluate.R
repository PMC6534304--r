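test_that("standard-score normalization is fitted on training rows only", {
  st <- standardize(matrix(c(0, 10), 2, 1), matrix(5, 1, 1))
  expect_equal(st$center, 5)
  expect_equal(st$scale, 5)                 # population SD
  expect_equal(as.numeric(st$train), c(-1, 1))
  expect_equal(as.numeric(st$apply), 0)     # a row at the mean maps to 0

  set.seed(14)
  x <- matrix(rnorm(40 * 6, 3, 2), 40, 6)
  st2 <- standardize(x)
  expect_lt(max(abs(colMeans(st2$train))), 1e-9)
  expect_lt(max(abs(apply(st2$train, 2, vocemark:::pop_sd) - 1)), 1e-9)
  back <- sweep(sweep(st2$train, 2, st2$scale, "*"), 2, st2$center, "+")
  expect_equal(back, x, tolerance = 1e-9)

  xz <- cbind(x[, 1], 7)
  expect_warning(stz <- standardize(xz), "zero-variance")
  expect_equal(unname(stz$train[, 2]), rep(0, 40))
  expect_error(standardize(x[1, , drop = FALSE]), "2 training rows")
})

test_that("every classifier family fits, predicts and is seed-deterministic", {
  set.seed(15)
  n <- 40
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- factor(rep(c("FMD", "ND"), each = n / 2))
  x[y == "ND", 1:2] <- x[y == "ND", 1:2] + 3
  xt <- x + rnorm(length(x), 0, 0.1)
  for (clf in names(default_grids())) {
    g <- default_grids()[[clf]][1, , drop = FALSE]
    m1 <- fit_classifier(clf, x, y, g, seed = 42)
    m2 <- fit_classifier(clf, x, y, g, seed = 42)
    p1 <- predict(m1, xt); p2 <- predict(m2, xt)
    expect_identical(p1, p2)
    expect_gte(mean(p1 == y), 0.9)
  }
})

test_that("stratified folds balance classes and partition the rows", {
  y <- factor(rep(c("FMD", "ND"), each = 15))
  f <- vocemark:::stratified_folds(y, 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f, y) == 3))
  expect_length(f, 30)
})

test_that("nested cross-validation is exact on separable data and reproducible", {
  set.seed(16)
  x <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("FMD", "ND"), each = 15)
  x[y == "ND", 1] <- x[y == "ND", 1] + 8
  tab <- feature_table(x, y, seq_len(30))
  r <- suppressWarnings(
    nested_kfold(tab, route = "utest", classifiers = "svm_linear",
                 n_feat_grid = c(1, 2), seed = 4))
  acc <- subset(r$results, classifier == "svm_linear" &
                  regime == "selected")$mean_accuracy
  expect_equal(acc, 1.0)
  # outer test folds partition the samples exactly once
  pr <- r$predictions[["svm_linear.selected"]]
  expect_equal(nrow(pr), 30)
  r2 <- suppressWarnings(
    nested_kfold(tab, route = "utest", classifiers = "svm_linear",
                 n_feat_grid = c(1, 2), seed = 4))
  expect_identical(r$results, r2$results)
})

test_that("leave-one-group-out keeps every speaker on one side only", {
  set.seed(17)
  n_grp <- 10; per <- 4
  x <- matrix(rnorm(n_grp * per * 5), n_grp * per, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(rep(c("FMD", "ND"), each = per), n_grp / 2)
  g <- rep(paste0("p", 1:n_grp), each = per)
  x[y == "ND", 1] <- x[y == "ND", 1] + 4
  tab <- feature_table(x, y, g)
  r <- suppressWarnings(
    logout_eval(tab, route = "utest", classifiers = "svm_linear",
                n_feat_grid = c(2, 5), seed = 5))
  pr <- r$predictions[["svm_linear.selected"]]
  expect_equal(length(unique(pr$fold)), n_grp)      # one split per group
  expect_equal(nrow(pr), n_grp * per)               # all segments tested once
  # each fold's test set is exactly one group, so no group straddles a split
  by_fold <- split(pr$group, pr$fold)
  expect_true(all(vapply(by_fold, function(gg) length(unique(gg)) == 1, TRUE)))
  expect_setequal(unlist(lapply(by_fold, unique)), unique(g))
  # pooled (segment) and group-mean accuracies are both reported
  expect_true(all(c("mean_accuracy", "group_mean_accuracy") %in%
                    names(r$results)))
})

test_that("segment-pooled and group-mean accuracies differ under imbalance", {
  pr <- data.frame(fold = c(1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2),
                   truth = c(rep("FMD", 8), rep("ND", 4)),
                   pred = c(rep("FMD", 4), rep("ND", 4), rep("ND", 4)),
                   group = c(rep("a", 8), rep("b", 4)))
  pooled <- mean(pr$pred == pr$truth)
  grp <- mean(vapply(split(pr, pr$fold),
                     function(d) mean(d$pred == d$truth), 0))
  expect_equal(pooled, 8 / 12)
  expect_equal(grp, 0.75)
  expect_false(isTRUE(all.equal(pooled, grp)))
})

test_that("confusion metrics pool fold-level predictions", {
  fake <- structure(list(predictions = list(
    "svm_linear.selected" = data.frame(
      fold = 1, truth = c(rep("ND", 16), rep("FMD", 14)),
      pred = c("FMD", rep("ND", 15), rep("FMD", 14)),
      group = NA))), class = "voc_eval")
  cm <- confusion_metrics(fake)
  expect_equal(cm$sensitivity, 0.9375)      # 15/16 ND recalled
  expect_equal(cm$specificity, 1.0)
  fake$predictions[[1]]$pred <- "FMD"       # degenerate all-FMD predictor
  cm2 <- confusion_metrics(fake)
  expect_equal(cm2$sensitivity, 0)
  expect_equal(cm2$specificity, 1)
})

test_that("permuted labels keep nested accuracy near chance", {
  set.seed(18)
  x <- matrix(rnorm(30 * 20), 30, 20, dimnames = list(NULL, paste0("f", 1:20)))
  accs <- vapply(1:5, function(s) {
    y <- sample(rep(c("FMD", "ND"), each = 15))
    tab <- feature_table(x, y, seq_len(30))
    r <- suppressWarnings(
      nested_kfold(tab, route = "utest", classifiers = "svm_linear",
                   n_feat_grid = c(5, 20), seed = s))
    subset(r$results, regime == "selected")$mean_accuracy
  }, 0)
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})
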