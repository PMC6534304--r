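#' Standard-score normalization fitted on training rows only
#'
#' (x - mu) / sigma with the per-feature mean and population standard
#' deviation of the training rows. Zero-variance columns are centred and
#' passed through with a warning.
#'
#' @param train numeric matrix of training rows (>= 2)
#' @param apply optional matrix transformed with the training parameters
#' @return list with `train`, `apply` (when given), `center`, `scale`
#' @export
standardize <- function(train, apply = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("standardization needs at least 2 training rows")
  mu <- colMeans(train)
  sg <- sqrt(colMeans(train^2) - mu^2)
  sg[!is.finite(sg)] <- 0
  if (any(sg <= 1e-12)) {
    warning(sum(sg <= 1e-12),
            " zero-variance feature(s) pass through centred")
    sg[sg <= 1e-12] <- 1
  }
  tr <- sweep(sweep(train, 2, mu), 2, sg, "/")
  out <- list(train = tr, center = mu, scale = sg)
  if (!is.null(apply))
    out$apply <- sweep(sweep(as.matrix(apply), 2, mu), 2, sg, "/")
  out
}

## stratified k-fold assignment (balanced classes per fold)
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

## group-aware fold assignment: whole groups dealt per class
group_folds <- function(groups, y, k, seed) {
  gdf <- unique(data.frame(g = groups, y = y, stringsAsFactors = FALSE))
  gfold <- integer(nrow(gdf))
  with_seed(seed, {
    for (lv in unique(gdf$y)) {
      idx <- sample(which(gdf$y == lv))
      gfold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  gfold[match(groups, gdf$g)]
}

## route ranking from (standardized) training data; RFE eliminates two
## features per iteration on large segment tables to bound the fit count
route_ranking <- function(route, x, y, seed) {
  if (route == "none") return(colnames(x))
  sel <- switch(route,
    rfe = rfe_rank(list(x = x, y = y),
                   step = if (nrow(x) > 100) 2 else 1, seed = seed),
    embedded = embedded_rank(list(x = x, y = y), seed = seed),
    utest = mannwhitney_rank(
      feature_table(x, as.character(y), seq_len(nrow(x)))),
    stop("unknown selection route: ", route))
  sel$ranking
}

## inner-loop model selection shared by both validation scenarios.
## folds: inner fold id per training row; returns best (n_feat, grid row)
## per classifier plus the prepared per-fold standardizations/rankings.
inner_select <- function(x, y, folds, route, classifiers, grids,
                         n_feat_grid, seed, ranking_override = NULL) {
  ks <- sort(unique(folds))
  prep <- lapply(ks, function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || sum(!tr) == 0) return(NULL)
    st <- standardize(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    rk <- ranking_override %||%
      route_ranking(route, st$train, y[tr], seed)
    list(xtr = st$train, xva = st$apply, ytr = y[tr], yva = y[!tr],
         ranking = rk)
  })
  prep <- Filter(Negate(is.null), prep)
  nf_grid <- sort(unique(pmin(n_feat_grid, ncol(x))))
  np <- max(length(prep), 1)
  score <- function(clf, keep, params) {
    a <- 0
    for (pf in prep) {
      m <- fit_classifier(clf, pf$xtr[, utils::head(pf$ranking, keep),
                                      drop = FALSE],
                          pf$ytr, params, seed = seed)
      a <- a + mean(predict(m, pf$xva[, utils::head(pf$ranking, keep),
                                      drop = FALSE]) == pf$yva)
    }
    a / np
  }
  best <- list()
  for (clf in classifiers) {
    grid <- grids[[clf]]
    mid <- grid[ceiling(nrow(grid) / 2), , drop = FALSE]
    # two-stage search: retained-feature count at the middle grid point,
    # then the hyper-parameter grid at the chosen count
    acc_n <- vapply(nf_grid, function(k) score(clf, k, mid), 0)
    n_feat <- nf_grid[which.max(acc_n)]     # ties -> fewer features
    acc_g <- vapply(seq_len(nrow(grid)),
                    function(gi) score(clf, n_feat, grid[gi, , drop = FALSE]),
                    0)
    gi <- which.max(acc_g)                  # ties -> earlier row
    best[[clf]] <- list(n_feat = n_feat,
                        params = grid[gi, , drop = FALSE],
                        inner_accuracy = max(acc_g))
  }
  best
}

eval_report <- function(scenario, route, rows, predictions, folds, seed) {
  structure(list(scenario = scenario, route = route,
                 results = rows, predictions = predictions,
                 folds = folds, seed = seed),
            class = "voc_eval")
}

#' @export
print.voc_eval <- function(x, ...) {
  cat(sprintf("<voc_eval> scenario=%s route=%s (seed %s)\n",
              x$scenario, x$route, x$seed))
  df <- x$results
  df$accuracy <- sprintf("%.1f%% ± %.2f", 100 * df$mean_accuracy,
                         df$sd_accuracy)
  print(df[, c("classifier", "regime", "accuracy", "n_selected")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.voc_eval <- function(object, ...) {
  cm <- confusion_metrics(object)
  out <- merge(object$results, cm,
               by = c("classifier", "regime"), sort = FALSE)
  out
}

#' Nested stratified k-fold evaluation (scenario 1)
#'
#' Outer loop: class-balanced stratified k-fold over recordings. Inner loop
#' (on the outer-training rows only): stratified k-fold tuning of the
#' retained feature count and each classifier's hyper-parameters.
#' Standardization and the feature ranking are fitted inside each training
#' portion, never on held-out rows. The best inner configuration is refit on
#' the full outer-training rows and scored once on the outer test fold;
#' reported accuracy is the mean and SD across outer folds.
#'
#' @param tab a `voc_features` table (one row per recording)
#' @param k outer folds (default 5)
#' @param route feature ranking route: "rfe", "embedded", "utest" or "none"
#' @param classifiers subset of the registry names
#' @param grids hyper-parameter grids, see [default_grids()]
#' @param n_feat_grid candidate retained-feature counts for the inner loop
#' @param inner_k inner folds
#' @param seed integer seed controlling folds and stochastic fits
#' @param regimes evaluate with "all" features and/or the "selected" regime
#' @param leak_selection diagnostic mode: compute the feature ranking once
#'   on the full table (training and test rows together) instead of inside
#'   the training folds. This deliberately re-creates the selection-outside-
#'   the-folds mistake and exists so tests can demonstrate the optimistic
#'   bias; never use it for reporting.
#' @return a `voc_eval` report
#' @export
nested_kfold <- function(tab, k = 5, route = "rfe",
                         classifiers = names(default_grids()),
                         grids = default_grids(),
                         n_feat_grid = c(9, 22, 51),
                         inner_k = 5, seed = 1,
                         regimes = c("all", "selected"),
                         leak_selection = FALSE) {
  feats <- feature_columns(tab)
  x <- as.matrix(tab[, feats]); y <- droplevels(tab$label)
  stopifnot(nlevels(y) == 2)
  outer <- stratified_folds(y, k, derive_seed(seed, 1))
  leak_rank <- NULL
  if (leak_selection) {
    st_all <- standardize(x)
    leak_rank <- route_ranking(route, st_all$train, y, derive_seed(seed, 2))
  }
  run_eval(x, y, groups = NULL, outer, route, classifiers, grids,
           n_feat_grid, inner_k, seed, regimes, leak_rank,
           scenario = "recordings", pooled_primary = FALSE)
}

#' Leave-one-group-out evaluation over one-minute segments (scenario 2)
#'
#' One outer split per patient: all of a patient's segments are held out
#' together, so no speaker contributes to both sides of any split. The inner
#' loop tunes on the remaining groups with group-aware folds. Reported
#' accuracy is segment-pooled over all outer splits (primary) with the
#' group-level mean as secondary.
#'
#' @inheritParams nested_kfold
#' @param tab a `voc_features` table of one-minute segments with `group_id`
#' @param inner_k group-aware inner folds (default 3)
#' @return a `voc_eval` report
#' @export
logout_eval <- function(tab, route = "rfe",
                        classifiers = names(default_grids()),
                        grids = default_grids(),
                        n_feat_grid = c(9, 22, 51),
                        inner_k = 3, seed = 1,
                        regimes = "selected",
                        leak_selection = FALSE) {
  feats <- feature_columns(tab)
  x <- as.matrix(tab[, feats]); y <- droplevels(tab$label)
  g <- tab$group_id
  stopifnot(nlevels(y) == 2, length(unique(g)) >= 3)
  groups <- sort(unique(g))
  outer <- match(g, groups)          # split id = group index
  leak_rank <- NULL
  if (leak_selection) {
    st_all <- standardize(x)
    leak_rank <- route_ranking(route, st_all$train, y, derive_seed(seed, 2))
  }
  run_eval(x, y, groups = g, outer, route, classifiers, grids,
           n_feat_grid, inner_k, seed, regimes, leak_rank,
           scenario = "segments", pooled_primary = TRUE)
}

## shared outer loop
run_eval <- function(x, y, groups, outer, route, classifiers, grids,
                     n_feat_grid, inner_k, seed, regimes, leak_rank,
                     scenario, pooled_primary) {
  splits <- sort(unique(outer))
  per_fold <- list()   # [[clf]][[regime]] accuracy vector
  preds <- list()      # pooled predictions
  for (f in splits) {
    tr <- outer != f; te <- !tr
    if (length(unique(y[tr])) < 2 || sum(te) == 0) next
    st <- standardize(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    fseed <- derive_seed(seed, 100 + f)
    # the ranking is fitted once per split, on the outer-training rows only;
    # inner folds tune the retained count and hyper-parameters against it
    out_rank <- leak_rank %||%
      route_ranking(route, st$train, y[tr], fseed)
    inner <- if (is.null(groups))
      stratified_folds(y[tr], inner_k, fseed)
    else group_folds(groups[tr], as.character(y[tr]), inner_k, fseed)
    sel_best <- if ("selected" %in% regimes)
      inner_select(x[tr, , drop = FALSE], y[tr], inner, route, classifiers,
                   grids, n_feat_grid, fseed,
                   ranking_override = leak_rank %||% out_rank)
    else NULL
    all_best <- if ("all" %in% regimes)
      inner_select(x[tr, , drop = FALSE], y[tr], inner, "none", classifiers,
                   grids, ncol(x), fseed,
                   ranking_override = colnames(x))
    else NULL
    for (clf in classifiers) {
      for (rg in regimes) {
        best <- if (rg == "selected") sel_best[[clf]] else all_best[[clf]]
        keep <- if (rg == "selected") utils::head(out_rank, best$n_feat)
                else colnames(x)
        m <- fit_classifier(clf, st$train[, keep, drop = FALSE], y[tr],
                            best$params, seed = fseed)
        pr <- predict(m, st$apply[, keep, drop = FALSE])
        key <- paste(clf, rg, sep = ".")
        per_fold[[key]] <- c(per_fold[[key]], mean(pr == y[te]))
        preds[[key]] <- rbind(preds[[key]], data.frame(
          fold = f, truth = as.character(y[te]), pred = as.character(pr),
          group = if (is.null(groups)) NA_character_ else groups[te],
          stringsAsFactors = FALSE))
        nsel <- length(keep)
        attr(per_fold[[key]], "n_selected") <-
          c(attr(per_fold[[key]], "n_selected"), nsel)
      }
    }
  }
  rows <- do.call(rbind, lapply(names(per_fold), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    a <- per_fold[[key]]
    pooled <- mean(preds[[key]]$pred == preds[[key]]$truth)
    data.frame(classifier = parts[1], regime = parts[2],
               mean_accuracy = if (pooled_primary) pooled else mean(a),
               sd_accuracy = sd(a),
               group_mean_accuracy = mean(a),
               n_selected = round(median(attr(a, "n_selected"))),
               stringsAsFactors = FALSE)
  }))
  eval_report(scenario, route, rows, preds, outer, seed)
}

#' Pooled sensitivity and specificity of an evaluation report
#'
#' Sensitivity is the ND (positive-class) recall and specificity the FMD
#' recall, pooled over all outer test folds.
#'
#' @param report a `voc_eval`
#' @return data frame with one row per classifier and regime
#' @export
confusion_metrics <- function(report) {
  do.call(rbind, lapply(names(report$predictions), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    p <- report$predictions[[key]]
    nd <- p$truth == "ND"; fmd <- p$truth == "FMD"
    data.frame(classifier = parts[1], regime = parts[2],
               sensitivity = if (any(nd)) mean(p$pred[nd] == "ND") else NA,
               specificity = if (any(fmd)) mean(p$pred[fmd] == "FMD")
                             else NA,
               stringsAsFactors = FALSE)
  }))
}
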