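#' Run configuration
#'
#' A single object describing a full reproducible run: cohort generation,
#' feature extraction, selection route and evaluation. Serializable to YAML;
#' a run is fully reconstructible from (config, seed).
#'
#' @param seed master seed
#' @param n_per_class recordings per class
#' @param effect_scale class-separation multiplier
#' @param scenarios subset of c("recordings", "segments")
#' @param route selection route ("rfe", "embedded", "utest" or "none")
#' @param classifiers classifier subset, see [default_grids()]
#' @param n_feat_grid candidate feature counts for the inner loop
#' @param k,inner_k,logout_inner_k fold counts
#' @param analysis named list of [voc_config()] overrides
#' @param cohort_params optional generator parameter table overriding the
#'   class-conditional defaults (see `cohort_defaults`)
#' @return a `voc_run_config`
#' @export
run_config <- function(seed = 1, n_per_class = 15, effect_scale = 1,
                       scenarios = c("recordings", "segments"),
                       route = "rfe",
                       classifiers = names(default_grids()),
                       n_feat_grid = c(9, 22, 51),
                       k = 5, inner_k = 5, logout_inner_k = 3,
                       analysis = list(), cohort_params = NULL) {
  structure(list(seed = seed, n_per_class = n_per_class,
                 effect_scale = effect_scale, scenarios = scenarios,
                 route = route, classifiers = classifiers,
                 n_feat_grid = n_feat_grid, k = k, inner_k = inner_k,
                 logout_inner_k = logout_inner_k, analysis = analysis,
                 cohort_params = cohort_params),
            class = "voc_run_config")
}

#' Write / read a run configuration as YAML
#' @param cfg a `voc_run_config`
#' @param path file path
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

## md5 of the serialized configuration (provenance)
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Execute the full pipeline on a synthetic cohort
#'
#' Synthesis, patient isolation, 51-feature extraction, selection and
#' leakage-controlled evaluation in one reproducible call. Scenario 1
#' (per-recording rows) is evaluated by nested stratified k-fold with both
#' the all-features and selected regimes; scenario 2 (one-minute segments)
#' by leave-one-group-out with the selected regime.
#'
#' @param cfg a [run_config()]
#' @return a `voc_run`: feature tables, one `voc_eval` per scenario and a
#'   provenance record (config hash, seeds, feature names)
#' @export
run_all <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "voc_run_config"))
  acfg <- do.call(voc_config, cfg$analysis)
  cs <- cohort_spec(n_per_class = cfg$n_per_class, seed = cfg$seed,
                    effect_scale = cfg$effect_scale,
                    params = cfg$cohort_params %||% cohort_defaults())
  tabs <- cohort_feature_tables(cs, acfg, scenarios = cfg$scenarios)
  reports <- list()
  if ("recordings" %in% cfg$scenarios)
    reports$recordings <- nested_kfold(
      tabs$recordings, k = cfg$k, route = cfg$route,
      classifiers = cfg$classifiers, n_feat_grid = cfg$n_feat_grid,
      inner_k = cfg$inner_k, seed = cfg$seed)
  if ("segments" %in% cfg$scenarios)
    reports$segments <- logout_eval(
      tabs$segments, route = cfg$route, classifiers = cfg$classifiers,
      n_feat_grid = cfg$n_feat_grid, inner_k = cfg$logout_inner_k,
      seed = cfg$seed)
  structure(list(config = cfg,
                 features = tabs[intersect(names(tabs),
                                           c("recordings", "segments"))],
                 reports = reports,
                 provenance = list(
                   config_md5 = config_hash(cfg),
                   seed = cfg$seed,
                   feature_names = feature_names(acfg),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "voc_run")
}

#' @export
print.voc_run <- function(x, ...) {
  cat("<voc_run> seed", x$config$seed, "route", x$config$route, "\n")
  for (nm in names(x$reports)) { cat("--", nm, "--\n"); print(x$reports[[nm]]) }
  invisible(x)
}

#' Write a feature table as CSV
#' @param tab a `voc_features` table
#' @param path output path
#' @export
write_feature_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  feature_table(as.matrix(df[, setdiff(names(df), c("label", "group_id")),
                             drop = FALSE]),
                df$label, df$group_id)
}
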