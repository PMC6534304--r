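## Mann-Whitney U for two samples; ties counted half via midranks
u_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  c(U1 = U1, U2 = U2, U = min(U1, U2))
}

## two-sided p-value: exact for small untied samples, tie-corrected normal
## approximation otherwise (both delegated to stats::wilcox.test)
u_pvalue <- function(x, y) {
  exact <- length(x) < 8 && length(y) < 8 && !any(duplicated(c(x, y)))
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

selection_result <- function(route, ranking, scores, selected) {
  structure(list(route = route, ranking = ranking, scores = scores,
                 selected = selected),
            class = "voc_selection")
}

#' @export
print.voc_selection <- function(x, ...) {
  cat(sprintf("<voc_selection> route=%s, %d features ranked, %d selected\n",
              x$route, length(x$ranking), length(x$selected)))
  print(utils::head(x$scores, 10))
  invisible(x)
}

#' Serialize a selection result as CSV (rank, feature, score, p_value)
#' @param sel a `voc_selection`
#' @param path output path
#' @export
write_selection <- function(sel, path) {
  sc <- sel$scores
  df <- data.frame(rank = seq_along(sel$ranking), feature = sel$ranking,
                   score = sc$score[match(sel$ranking, sc$feature)],
                   p_value = if ("p_value" %in% names(sc))
                     sc$p_value[match(sel$ranking, sc$feature)]
                   else NA_real_)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Mann-Whitney U feature ranking
#'
#' Per feature, a two-sided Mann-Whitney U test between the two classes
#' (reported U is min(U1, U2), the SPSS convention; ties counted half).
#' Features are ranked by ascending U, then ascending p; the selected subset
#' is every feature significant at `alpha`.
#'
#' @param tab a `voc_features` table with both classes present
#' @param alpha significance level for the selected subset
#' @return a `voc_selection` with per-feature U and p-values
#' @export
mannwhitney_rank <- function(tab, alpha = 0.05) {
  feats <- feature_columns(tab)
  y <- tab$label
  if (any(table(y) < 2)) stop("each class needs at least 2 samples")
  xa <- tab[y == levels(y)[1], feats, drop = FALSE]
  xb <- tab[y == levels(y)[2], feats, drop = FALSE]
  sc <- t(vapply(feats, function(f) {
    u <- u_statistic(xa[[f]], xb[[f]])
    c(U = unname(u["U"]), p = u_pvalue(xa[[f]], xb[[f]]))
  }, c(U = 0, p = 0)))
  ord <- order(sc[, "U"], sc[, "p"])
  ranking <- feats[ord]
  scores <- data.frame(feature = feats, score = sc[, "U"],
                       p_value = sc[, "p"], row.names = NULL)
  selection_result("utest", ranking, scores,
                   ranking[scores$p_value[match(ranking, scores$feature)] <
                             alpha])
}

## importance surface of an RFE evaluator fit on (x, y)
rfe_importance <- function(evaluator, x, y, cost, seed) {
  if (evaluator == "svm_linear") {
    m <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    as.numeric(abs(t(m$coefs) %*% m$SV))
  } else if (evaluator == "random_forest") {
    m <- ranger::ranger(x = as.data.frame(x), y = y,
                        num.trees = 300, importance = "impurity",
                        seed = seed, num.threads = 1)
    as.numeric(m$variable.importance)
  } else {
    stop("RFE needs an evaluator with a coefficient or importance surface, ",
         "got: ", evaluator)
  }
}

#' Recursive feature elimination ranking
#'
#' Repeatedly fits the evaluator and eliminates the `step` features with the
#' smallest absolute weight (linear SVM) or impurity importance (random
#' forest); the ranking is the reverse elimination order, so the feature
#' whose removal matters most is ranked first. Equal importances are broken
#' by dropping the later column. The caller supplies standardized
#' training-fold rows.
#'
#' @param tab a `voc_features` table or a list(x, y) with a numeric matrix
#' @param evaluator "svm_linear" (default) or "random_forest"
#' @param step features eliminated per iteration
#' @param cost SVM cost parameter of the evaluator; the small default
#'   stabilizes the weight vector at the cohort's small sample sizes
#' @param seed seed for stochastic evaluators
#' @return a `voc_selection` (scores = elimination order, 1 = dropped first)
#' @export
rfe_rank <- function(tab, evaluator = "svm_linear", step = 1, cost = 0.01,
                     seed = 13) {
  if (inherits(tab, "voc_features")) {
    x <- as.matrix(tab[, feature_columns(tab)]); y <- droplevels(tab$label)
  } else { x <- as.matrix(tab$x); y <- droplevels(as.factor(tab$y)) }
  feats <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  colnames(x) <- feats
  active <- seq_len(ncol(x))
  elim <- integer(0)
  while (length(active) > 0) {
    if (length(active) == 1) { elim <- c(elim, active); break }
    imp <- rfe_importance(evaluator, x[, active, drop = FALSE], y, cost, seed)
    ns <- min(step, length(active) - 1L)
    # order of removal: smallest importance first, ties resolved towards
    # the later column
    ord <- order(imp, -seq_along(active))
    drop_local <- ord[seq_len(ns)]
    elim <- c(elim, active[drop_local])
    active <- active[-drop_local]
    if (length(active) == 0) break
    if (length(elim) + length(active) == ncol(x) &&
        length(active) == 1) { elim <- c(elim, active); break }
  }
  if (length(elim) < ncol(x)) elim <- c(elim, setdiff(seq_len(ncol(x)), elim))
  ranking <- feats[rev(elim)]
  scores <- data.frame(feature = feats,
                       score = match(seq_len(ncol(x)), elim),
                       row.names = NULL)
  selection_result("rfe", ranking, scores, utils::head(ranking, 22))
}

#' Tree-ensemble embedded feature ranking
#'
#' Mean impurity-decrease importance of a random forest, deterministic under
#' the fixed seed.
#'
#' @param tab a `voc_features` table or list(x, y)
#' @param num_trees number of trees
#' @param seed forest seed (default 13)
#' @return a `voc_selection` (scores = importances)
#' @export
embedded_rank <- function(tab, num_trees = 500, seed = 13) {
  if (inherits(tab, "voc_features")) {
    x <- as.matrix(tab[, feature_columns(tab)]); y <- droplevels(tab$label)
  } else { x <- as.matrix(tab$x); y <- droplevels(as.factor(tab$y)) }
  feats <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  m <- ranger::ranger(x = as.data.frame(x), y = y, num.trees = num_trees,
                      importance = "impurity", seed = seed, num.threads = 1)
  imp <- as.numeric(m$variable.importance)
  ord <- order(-imp, seq_along(imp))
  selection_result("embedded", feats[ord],
                   data.frame(feature = feats, score = imp,
                              row.names = NULL),
                   utils::head(feats[ord], 22))
}
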