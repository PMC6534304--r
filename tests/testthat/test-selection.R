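test_that("Mann-Whitney U equals brute-force pairwise counting", {
  set.seed(21)
  for (rep in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- sample(1:8, n1, replace = TRUE) + rnorm(n1, 0, 0.01 * rbinom(1, 1, 0.5))
    y <- sample(1:8, n2, replace = TRUE) + rnorm(n2, 0, 0.01 * rbinom(1, 1, 0.5))
    u <- vocemark:::u_statistic(x, y)
    expect_equal(unname(u["U"]), brute_u(x, y))
  }
})

test_that("small-sample U behaviour matches exhaustive enumeration", {
  x <- c(1, 2); y <- c(3, 4)
  expect_equal(unname(vocemark:::u_statistic(x, y)["U"]), 0)
  # exhaustive one-sided p over all C(4,2) label assignments
  pool <- c(x, y)
  labelings <- combn(4, 2)
  us <- apply(labelings, 2, function(i) {
    u1 <- 0
    for (a in pool[i]) for (b in pool[-i])
      u1 <- u1 + (a > b) + 0.5 * (a == b)
    u1
  })
  expect_equal(mean(us <= 0), 1 / 6)

  # identical multisets sit at the tie convention U = n^2 / 2
  z <- c(1, 2, 3, 4)
  expect_equal(unname(vocemark:::u_statistic(z, z)["U"]), 16 / 2)
  expect_gt(vocemark:::u_pvalue(z, z), 0.9)
})

test_that("utest ranking selects significant features and stays in bounds", {
  set.seed(5)
  x <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c("FMD", "ND"), each = 15)
  x[y == "ND", 1] <- x[y == "ND", 1] + 3
  tab <- feature_table(x, y, seq_len(30))
  sel <- mannwhitney_rank(tab)
  expect_equal(sel$ranking[1], "f1")
  expect_true("f1" %in% sel$selected)
  expect_true(all(sel$scores$score <= 15 * 15 / 2))    # min(U1,U2) bound
  expect_true(all(sel$scores$score >= 0))
  expect_setequal(sel$ranking, paste0("f", 1:10))
  sig <- sel$scores$p_value[match(sel$selected, sel$scores$feature)]
  expect_true(all(sig < 0.05))
})

test_that("label permutation keeps the false-positive rate near alpha", {
  set.seed(31)
  x <- matrix(rnorm(30 * 51), 30, 51,
              dimnames = list(NULL, paste0("f", 1:51)))
  hits <- 0; total <- 0
  for (perm in 1:40) {
    y <- sample(rep(c("FMD", "ND"), each = 15))
    sel <- mannwhitney_rank(feature_table(x, y, seq_len(30)))
    hits <- hits + sum(sel$scores$p_value < 0.05)
    total <- total + 51
  }
  expect_gt(hits / total, 0.01)
  expect_lt(hits / total, 0.10)
})

test_that("RFE ranks a perfectly separating feature first", {
  set.seed(6)
  n <- 20
  x <- cbind(A = rep(c(-2, 2), each = n / 2) + rnorm(n, 0, 0.1),
             B = rnorm(n), C = rnorm(n))
  y <- factor(rep(c("FMD", "ND"), each = n / 2))
  st <- standardize(x)
  sel <- rfe_rank(list(x = st$train, y = y))
  expect_equal(sel$ranking[1], "A")
  # refit oracle: accuracy with A alone beats any A-less subset
  acc <- function(cols) {
    m <- e1071::svm(st$train[, cols, drop = FALSE], y, kernel = "linear",
                    scale = FALSE)
    mean(predict(m, st$train[, cols, drop = FALSE]) == y)
  }
  expect_gte(acc("A"), acc(c("B", "C")))
})

test_that("a duplicated feature column occupies adjacent ranks", {
  set.seed(7)
  n <- 24
  x <- cbind(A = rep(c(-1, 1), each = n / 2) + rnorm(n, 0, 0.4),
             B = rnorm(n), C = rnorm(n))
  x <- cbind(x, A2 = x[, "A"])
  y <- factor(rep(c("FMD", "ND"), each = n / 2))
  sel <- rfe_rank(list(x = standardize(x)$train, y = y))
  expect_equal(abs(diff(match(c("A", "A2"), sel$ranking))), 1)
})

test_that("single-shot elimination equals the absolute-weight order", {
  set.seed(8)
  x <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(rep(c("FMD", "ND"), each = 15))
  x[y == "ND", 2] <- x[y == "ND", 2] + 1.5
  st <- standardize(x)$train
  sel <- rfe_rank(list(x = st, y = y), step = 6, cost = 1)
  m <- e1071::svm(st, y, kernel = "linear", cost = 1, scale = FALSE)
  w <- abs(as.numeric(t(m$coefs) %*% m$SV))
  expect_equal(sel$ranking, colnames(st)[order(-w, seq_along(w))])
})

test_that("RFE on standardized data is invariant to raw feature rescaling", {
  set.seed(9)
  x <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(rep(c("FMD", "ND"), each = 15))
  x[y == "ND", 3] <- x[y == "ND", 3] + 1
  x2 <- x; x2[, 4] <- x2[, 4] * 1000
  r1 <- rfe_rank(list(x = standardize(x)$train, y = y))
  r2 <- rfe_rank(list(x = standardize(x2)$train, y = y))
  expect_equal(r1$ranking, r2$ranking)
})

test_that("embedded importances surface the separating feature, deterministically", {
  set.seed(10)
  x <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c("FMD", "ND"), each = 15)
  x[y == "ND", 5] <- x[y == "ND", 5] + 3
  tab <- feature_table(x, y, seq_len(30))
  s1 <- embedded_rank(tab)
  s2 <- embedded_rank(tab)
  expect_equal(s1$ranking[1], "f5")
  expect_identical(s1$ranking, s2$ranking)   # fixed seed -> identical
  # all-identical features receive comparable importances
  xi <- matrix(rep(rnorm(30), 4), 30, 4,
               dimnames = list(NULL, paste0("g", 1:4)))
  si <- embedded_rank(feature_table(xi, y, seq_len(30)))
  imp <- si$scores$score
  expect_lt(diff(range(imp)) / (mean(imp) + 1e-12), 1.5)
})

test_that("non-linear evaluators without an importance surface are rejected", {
  x <- matrix(rnorm(20 * 3), 20, 3)
  y <- factor(rep(c("FMD", "ND"), each = 10))
  expect_error(rfe_rank(list(x = x, y = y), evaluator = "svm_rbf"),
               "importance")
})
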