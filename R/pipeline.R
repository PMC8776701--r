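#' End-to-end run configuration
#'
#' A fully serializable description of one reproducible analysis run:
#' cohort, ventilation metric(s), split scheme and tuner budget. A stored
#' configuration re-executes to identical outputs.
#'
#' @param n_patients cohort size.
#' @param metric `"hu"`, `"jacobian"` or `"both"`; validated here, before
#'   any computation.
#' @param label_model,incidence_target,ranges passed to [cohort_spec()].
#' @param label_metric metric whose features drive the label model.
#' @param scheme a [split_scheme()].
#' @param control a [tune_control()].
#' @param feature_sets named list of feature sets (default the four nested
#'   sets).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_patients = 20L,
                       metric = "hu",
                       label_model = list(coefficients = c(fV20 = 2),
                                          intercept = NULL),
                       incidence_target = 0.247,
                       ranges = default_cohort_ranges(),
                       label_metric = "hu",
                       scheme = split_scheme(n_repeats = 10L, inner_folds = 3L),
                       control = tune_control(budget = 15L),
                       feature_sets = default_feature_sets(),
                       seed = 1L) {
  if (!metric %in% c("hu", "jacobian", "both"))
    stop(sprintf("unknown metric '%s': expected 'hu', 'jacobian' or 'both'", metric))
  if (!label_metric %in% c("hu", "jacobian"))
    stop(sprintf("unknown label metric '%s'", label_metric))
  structure(list(n_patients = as.integer(n_patients), metric = metric,
                 label_model = label_model, incidence_target = incidence_target,
                 ranges = ranges, label_metric = label_metric,
                 scheme = scheme, control = control,
                 feature_sets = feature_sets, seed = as.integer(seed)),
            class = "run_config")
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

ft_to_df <- function(ft)
  cbind(data.frame(patient_id = ft$patient_id), ft$features,
        data.frame(rp_label = ft$label))

#' Run the full pipeline: simulate, ventilate, extract, model, report
#'
#' Generates the phantom cohort, computes ventilation-based features for the
#' configured metric(s), runs the repeated-split SVM experiment per metric
#' (metrics share identical splits, so their results are paired by repeat),
#' and writes all artifacts to `out_dir`: per-metric feature, run, summary,
#' univariate-screen and correlation CSVs, the configuration JSON, and a
#' manifest listing every written file with its md5 hash. Idempotent for a
#' fixed configuration.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list with the per-metric `rp_experiment` objects, the
#'   cohort, and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  if (!config$metric %in% c("hu", "jacobian", "both"))
    stop(sprintf("unknown metric '%s'", config$metric))
  metrics <- if (config$metric == "both") c("hu", "jacobian") else config$metric
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cspec <- cohort_spec(config$n_patients, config$label_model,
                       config$incidence_target, config$seed, config$ranges)
  cohort <- tryCatch(
    make_cohort(cspec, metric = config$label_metric, feature_metrics = metrics),
    error = function(e) stop(sprintf("stage simulate: %s", conditionMessage(e))))

  files <- character(0)
  experiments <- list()
  for (m in metrics) {
    ft <- cohort$tables[[m]]
    files <- c(files, write_csv_plain(ft_to_df(ft),
                                      file.path(out_dir, sprintf("features_%s.csv", m))))
    exp_m <- tryCatch(
      run_experiment(ft, config$feature_sets, config$scheme, config$control),
      error = function(e) stop(sprintf("stage train (%s): %s", m, conditionMessage(e))))
    experiments[[m]] <- exp_m
    s <- summary(exp_m)
    files <- c(files,
               write_csv_plain(exp_m$runs, file.path(out_dir, sprintf("runs_%s.csv", m))),
               write_csv_plain(s$table, file.path(out_dir, sprintf("summary_%s.csv", m))),
               write_csv_plain(as.data.frame(s$pairwise_p),
                               file.path(out_dir, sprintf("pairwise_p_%s.csv", m))),
               write_csv_plain(data.frame(feature = names(univariate_screen(ft)),
                                          p_value = unname(univariate_screen(ft))),
                               file.path(out_dir, sprintf("univariate_%s.csv", m))),
               write_csv_plain(as.data.frame(correlation_matrix(ft)),
                               file.path(out_dir, sprintf("correlation_%s.csv", m))))
  }

  cfg_path <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(serialize_config(config), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, cfg_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("rpvent")),
    seed = config$seed,
    metrics = as.list(metrics),
    achieved_incidence = cohort$achieved_incidence,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(experiments = experiments, cohort = cohort,
                 manifest = manifest, files = c(files, manifest_path)))
}

serialize_config <- function(config) {
  list(n_patients = config$n_patients, metric = config$metric,
       label_metric = config$label_metric,
       label_model = list(coefficients = as.list(config$label_model$coefficients),
                          intercept = config$label_model$intercept),
       incidence_target = config$incidence_target,
       scheme = unclass(config$scheme), control = unclass(config$control),
       feature_sets = config$feature_sets, seed = config$seed)
}
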