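#' Default hyper-parameter grids for the five classifier families
#'
#' Linear SVM (cost), random forest (trees, depth; depth 0 = unlimited),
#' AdaBoost (boosting rounds), single-hidden-layer MLP (hidden units) and a
#' hinge-loss linear model trained by SGD (regularization).
#'
#' @return named list of parameter data frames
#' @export
default_grids <- function() {
  list(
    svm_linear = data.frame(cost = c(0.01, 0.1, 1, 10)),
    random_forest = expand.grid(num_trees = c(100, 300),
                                max_depth = c(0, 5)),
    adaboost = data.frame(n_rounds = c(50, 200)),
    mlp = data.frame(size = c(16, 64)),
    sgd = data.frame(alpha = c(1e-4, 1e-3)))
}

#' Fit one classifier
#'
#' Uniform front end over the five model families; `x` is a numeric matrix
#' of (standardized) features and `y` a two-level factor.
#'
#' @param name one of "svm_linear", "random_forest", "adaboost", "mlp", "sgd"
#' @param x feature matrix
#' @param y two-level factor of labels
#' @param params one row of the classifier's grid (list or data frame row)
#' @param seed seed for the stochastic fitters
#' @return a `voc_model`
#' @export
fit_classifier <- function(name, x, y, params = list(), seed = 1) {
  x <- as.matrix(x); y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2)
  params <- as.list(params)
  fit <- switch(name,
    svm_linear = e1071::svm(x, y, kernel = "linear",
                            cost = params$cost %||% 1, scale = FALSE),
    random_forest = {
      depth <- params$max_depth %||% 0
      ranger::ranger(x = as.data.frame(x), y = y,
                     num.trees = params$num_trees %||% 300,
                     max.depth = if (depth > 0) depth else NULL,
                     seed = seed, num.threads = 1)
    },
    adaboost = ada_fit(x, y, n_rounds = params$n_rounds %||% 100),
    mlp = mlp_fit(x, y, size = params$size %||% 16, seed = seed),
    sgd = sgd_fit(x, y, alpha = params$alpha %||% 1e-4, seed = seed),
    stop("unknown classifier: ", name))
  structure(list(name = name, fit = fit, levels = levels(y),
                 features = colnames(x)),
            class = "voc_model")
}

#' Predict class labels from a fitted classifier
#' @param object a `voc_model`
#' @param newdata numeric feature matrix
#' @param ... unused
#' @return factor of predicted labels
#' @export
predict.voc_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  lv <- object$levels
  out <- switch(object$name,
    svm_linear = as.character(predict(object$fit, x)),
    random_forest = as.character(predict(object$fit,
                                         data = as.data.frame(x),
                                         num.threads = 1)$predictions),
    adaboost = ada_predict(object$fit, x),
    mlp = mlp_predict(object$fit, x),
    sgd = sgd_predict(object$fit, x))
  factor(out, levels = lv)
}

## ---- AdaBoost with decision stumps (SAMME, binary) -------------------------

## The stump search is vectorised over all features at once: with rows
## presorted per feature, the weighted error of every (feature, cut,
## polarity) is a cumulative-sum expression, computed for the whole grid
## with one flat cumsum per class.
ada_fit <- function(x, y, n_rounds = 100) {
  lv <- levels(y)
  yv <- ifelse(y == lv[2], 1, -1)
  n <- nrow(x); p <- ncol(x)
  ord <- apply(x, 2, order)
  ovec <- as.vector(ord)               # row index per sorted position
  xs <- matrix(x[ovec + rep((seq_len(p) - 1L) * n, each = n)], n, p)
  valid <- as.vector(rbind(xs[-n, , drop = FALSE] < xs[-1, , drop = FALSE],
                           FALSE))
  w <- rep(1 / n, n)
  is_pos <- yv > 0
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  for (t in seq_len(n_rounds)) {
    wp_flat <- cumsum((w * is_pos)[ovec] )
    wn_flat <- cumsum((w * !is_pos)[ovec])
    # per-column cumulative sums from the flat ones
    base_p <- c(0, wp_flat[seq(n, by = n, length.out = p - 1)])
    base_n <- c(0, wn_flat[seq(n, by = n, length.out = p - 1)])
    wp <- wp_flat - rep(base_p, each = n)
    wn <- wn_flat - rep(base_n, each = n)
    tot_pos <- sum(w[is_pos]); tot <- sum(w)
    e_up <- wp + (tot - tot_pos) - wn  # stump "+1 above the cut"
    e_dn <- tot - e_up                 # opposite polarity
    e_up[!valid] <- Inf; e_dn[!valid] <- Inf
    i_up <- which.min(e_up); i_dn <- which.min(e_dn)
    if (e_up[i_up] <= e_dn[i_dn]) { idx <- i_up; pol <- 1; err <- e_up[i_up] }
    else { idx <- i_dn; pol <- -1; err <- e_dn[i_dn] }
    if (!is.finite(err)) break
    j <- (idx - 1L) %/% n + 1L; k <- (idx - 1L) %% n + 1L
    st <- list(feature = j, polarity = pol,
               threshold = (xs[k, j] + xs[min(k + 1L, n), j]) / 2)
    err <- min(max(err / tot, 1e-10), 1 - 1e-10)
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    h <- st$polarity * ifelse(x[, st$feature] > st$threshold, 1, -1)
    w <- w * exp(-a * yv * h)
    w <- w / sum(w)
    used <- used + 1L
    stumps[[used]] <- st
    alphas[used] <- a
    if (err < 1e-9) break
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)],
       levels = lv)
}

ada_predict <- function(fit, x) {
  if (length(fit$stumps) == 0)
    return(rep(fit$levels[1], nrow(x)))
  score <- numeric(nrow(x))
  for (t in seq_along(fit$stumps)) {
    st <- fit$stumps[[t]]
    score <- score + fit$alphas[t] * st$polarity *
      ifelse(x[, st$feature] > st$threshold, 1, -1)
  }
  ifelse(score > 0, fit$levels[2], fit$levels[1])
}

## ---- single-hidden-layer MLP trained by full-batch Adam ---------------------

## tanh hidden layer, softmax output, cross-entropy + L2; deterministic
## under the seed.  Matches the behaviour of the usual Adam-trained
## MLP classifiers at these problem sizes while keeping every fit a few
## small BLAS calls.
mlp_fit <- function(x, y, size = 16, epochs = 150, lr = 0.01, l2 = 1e-4,
                    seed = 1) {
  lv <- levels(y)
  n <- nrow(x); p <- ncol(x)
  Y <- cbind(y == lv[1], y == lv[2]) * 1
  par <- with_seed(seed, list(
    W1 = matrix(rnorm(p * size, 0, 1 / sqrt(p)), p, size),
    b1 = numeric(size),
    W2 = matrix(rnorm(size * 2, 0, 1 / sqrt(size)), size, 2),
    b2 = numeric(2)))
  m <- lapply(par, function(z) z * 0); v <- m
  b1t <- 1; b2t <- 1
  for (ep in seq_len(epochs)) {
    H <- tanh(x %*% par$W1 + rep(par$b1, each = n))
    Z <- H %*% par$W2 + rep(par$b2, each = n)
    Z <- Z - pmax(Z[, 1], Z[, 2])
    P <- exp(Z); P <- P / (P[, 1] + P[, 2])
    dZ <- (P - Y) / n
    g <- list(W1 = NULL, b1 = NULL, W2 = crossprod(H, dZ) + l2 * par$W2,
              b2 = colSums(dZ))
    dH <- (dZ %*% t(par$W2)) * (1 - H^2)
    g$W1 <- crossprod(x, dH) + l2 * par$W1
    g$b1 <- colSums(dH)
    b1t <- b1t * 0.9; b2t <- b2t * 0.999
    for (nm in names(par)) {
      m[[nm]] <- 0.9 * m[[nm]] + 0.1 * g[[nm]]
      v[[nm]] <- 0.999 * v[[nm]] + 0.001 * g[[nm]]^2
      par[[nm]] <- par[[nm]] - lr * (m[[nm]] / (1 - b1t)) /
        (sqrt(v[[nm]] / (1 - b2t)) + 1e-8)
    }
  }
  c(par, list(levels = lv))
}

mlp_predict <- function(fit, x) {
  n <- nrow(x)
  H <- tanh(x %*% fit$W1 + rep(fit$b1, each = n))
  Z <- H %*% fit$W2 + rep(fit$b2, each = n)
  fit$levels[max.col(Z, ties.method = "first")]
}

## ---- hinge-loss linear model trained by SGD (Pegasos schedule) --------------

sgd_fit <- function(x, y, alpha = 1e-4, epochs = 30, seed = 1) {
  lv <- levels(y)
  yv <- ifelse(y == lv[2], 1, -1)
  n <- nrow(x); p <- ncol(x)
  w <- numeric(p); b <- 0; t <- 0
  wa <- numeric(p); ba <- 0; na <- 0            # tail-averaged iterates
  half <- epochs %/% 2
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- 1 / (alpha * (t + 1 / alpha))    # bounded initial step
        margin <- yv[i] * (sum(w * x[i, ]) + b)
        w <- (1 - eta * alpha) * w
        if (margin < 1) {
          w <- w + eta * yv[i] * x[i, ]
          b <- b + eta * yv[i] * 0.1
        }
        if (ep > half) { wa <- wa + w; ba <- ba + b; na <- na + 1 }
      }
    }
  })
  list(w = wa / na, b = ba / na, levels = lv)
}

sgd_predict <- function(fit, x) {
  s <- as.numeric(x %*% fit$w + fit$b)
  ifelse(s > 0, fit$levels[2], fit$levels[1])
}
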