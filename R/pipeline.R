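# Orchestration: the shared trial-table schema and its readers/writers,
# the search-accuracy exclusion filter, and the end-to-end pipeline
# (design -> simulate -> exclude -> summarize -> fit -> geometry).

.schema_columns <- c(
  "subject_id", "experiment", "trial_index", "trial_kind",
  "target_distractor_distance", "distractor_direction",
  "foil_distance", "foil_direction", "salient_direction",
  "target_hue", "distractor_hue", "foil_hue",
  "target_position", "set_size", "foil_side",
  "choice", "search_correct")

.schema_vocab <- list(
  experiment = .experiments,
  trial_kind = c("combined", "search_report", "similarity_report"),
  distractor_direction = .distractor_directions,
  foil_direction = .foil_directions,
  salient_direction = c(.distractor_directions, "none"),
  foil_side = c("left", "right"),
  choice = c("target", "foil"))

#' Validate a trial table against the shared schema
#'
#' Checks column presence, categorical vocabularies, hue ranges and the
#' geometric invariants linking hues to the condition fields.
#'
#' @param data Data frame to validate.
#' @param require_responses Also require `subject_id`, `choice`,
#'   `search_correct`.
#' @return `data`, invisibly; errors describe the first violation found.
#' @export
validate_trials <- function(data, require_responses = FALSE) {
  need <- setdiff(.schema_columns,
                  if (require_responses) character(0)
                  else c("subject_id", "choice", "search_correct"))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  }
  for (col in intersect(names(.schema_vocab), names(data))) {
    bad <- setdiff(unique(stats::na.omit(data[[col]])), .schema_vocab[[col]])
    if (length(bad) > 0) {
      stop("column '", col, "' contains values outside its vocabulary: ",
           paste(bad, collapse = ", "))
    }
  }
  if (any(data$target_hue < 0 | data$target_hue >= 360)) {
    stop("target_hue must lie in [0, 360)")
  }
  ok_d <- is.na(data$distractor_hue) |
    abs(angular_distance(data$target_hue, data$distractor_hue) -
          data$target_distractor_distance) < 1e-8
  if (!all(ok_d)) stop("distractor_hue inconsistent with the condition's distance")
  has_foil <- !is.na(data$foil_hue)
  ok_f <- abs(angular_distance(data$target_hue[has_foil],
                               data$foil_hue[has_foil]) -
                data$foil_distance[has_foil]) < 1e-8
  if (!all(ok_f)) stop("foil_hue inconsistent with the condition's foil distance")
  invisible(data)
}

#' Write / read a trial table as CSV
#'
#' The on-disk format is plain CSV in the shared schema; reading validates
#' it, so a written table always round-trips.
#'
#' @param data Trial table.
#' @param path File path.
#' @param require_responses Passed to [validate_trials()] on read.
#' @return `read_trials()` returns the validated data frame.
#' @export
write_trials <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, require_responses = FALSE) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if ("search_correct" %in% names(data)) {
    data$search_correct <- as.integer(data$search_correct)
  }
  validate_trials(data, require_responses = require_responses)
  data
}

#' Read an externally formatted trial table via a column mapping
#'
#' Adapter for trial data exported by other software (e.g. a public data
#' deposit): a mapping list renames columns and recodes categorical values
#' into the shared schema, after which the table is validated. No network
#' access: the file must be local.
#'
#' @param path CSV file.
#' @param mapping A list (or path to a JSON file) with elements `columns`
#'   (named list: schema name -> source name) and optionally `values`
#'   (named list of named lists: schema column -> (schema value <- source
#'   value)).
#' @param require_responses Passed to [validate_trials()].
#' @return Validated trial table.
#' @export
read_trials_mapped <- function(path, mapping, require_responses = TRUE) {
  if (is.character(mapping)) mapping <- jsonlite::read_json(mapping)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  out <- raw
  cols <- mapping$columns
  if (!is.null(cols)) {
    for (ours in names(cols)) {
      src <- cols[[ours]]
      if (!src %in% names(raw)) stop("mapped source column not found: ", src)
      out[[ours]] <- raw[[src]]
    }
  }
  vals <- mapping$values
  if (!is.null(vals)) {
    for (col in names(vals)) {
      rec <- unlist(vals[[col]])
      x <- as.character(out[[col]])
      hit <- x %in% names(rec)
      x[hit] <- unname(rec[x[hit]])
      out[[col]] <- x
    }
  }
  out <- out[, intersect(.schema_columns, names(out)), drop = FALSE]
  if ("search_correct" %in% names(out)) {
    out$search_correct <- as.integer(out$search_correct)
  }
  validate_trials(out, require_responses = require_responses)
  out
}

#' Exclude subjects with poor visual-search accuracy
#'
#' Removes subjects whose mean search accuracy falls below the experiment's
#' threshold before any 2AFC analysis: 70% for E1-E3 and 40% for E4 (the
#' harder 7-item balanced-distractor search).
#'
#' @param data Trial table with `subject_id` and `search_correct`.
#' @param thresholds Named vector of per-experiment thresholds; a single
#'   unnamed number applies to all experiments.
#' @return List with `data` (filtered table) and `report` (one row per
#'   subject: accuracy, threshold, excluded flag).
#' @examples
#' d <- design_experiment("E1", seed = 1)
#' sim <- simulate_dataset(d, observer_params(
#'   search_accuracy = c("15" = .9, "30" = .9, "45" = .9, "60" = .9,
#'                       "90" = .9, "180" = .9)), seed = 1)
#' apply_exclusions(sim)$report
#' @export
apply_exclusions <- function(data,
                             thresholds = c(E1 = 0.70, E2 = 0.70,
                                            E3 = 0.70, E4 = 0.40)) {
  if (!all(c("subject_id", "search_correct") %in% names(data))) {
    stop("data must contain subject_id and search_correct")
  }
  if (is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(thresholds[1], 4), .experiments)
  }
  acc <- stats::aggregate(search_correct ~ subject_id + experiment,
                          data = data, FUN = mean, na.rm = TRUE)
  names(acc)[names(acc) == "search_correct"] <- "search_accuracy"
  acc$threshold <- unname(thresholds[acc$experiment])
  if (any(is.na(acc$threshold))) stop("no exclusion threshold for experiment")
  acc$excluded <- acc$search_accuracy < acc$threshold
  keep <- acc$subject_id[!acc$excluded]
  list(data = data[data$subject_id %in% keep, , drop = FALSE],
       report = acc[order(acc$subject_id), , drop = FALSE])
}

#' Pipeline run configuration
#'
#' @param experiment Which design to generate (`"E1"`..`"E4"`).
#' @param n_observers Cohort size.
#' @param observer A [cohort_distribution()] or [observer_params()].
#' @param seed Master seed; every stochastic stage derives from it.
#' @param exclusion_thresholds Per-experiment search-accuracy cutoffs.
#' @param fit Logical: fit the bias model to the (pooled) surviving data.
#' @param fit_args Extra arguments for [fit_bias_model()].
#' @param geometry Logical: run the population-geometry stage.
#' @param geometry_spec,geometry_gain [population_spec()] / [gain_profile()]
#'   for that stage.
#' @param input Optional path to an existing trial CSV (schema or mapped);
#'   when given, the design/simulate stages are skipped.
#' @param input_mapping Optional mapping (list or JSON path) for `input`.
#' @param out_dir Output directory for all artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(experiment = "E1", n_observers = 1,
                       observer = observer_params(), seed = 1L,
                       exclusion_thresholds = c(E1 = 0.70, E2 = 0.70,
                                                E3 = 0.70, E4 = 0.40),
                       fit = TRUE, fit_args = list(),
                       geometry = FALSE,
                       geometry_spec = population_spec(),
                       geometry_gain = gain_profile(attended_hue = 20),
                       input = NULL, input_mapping = NULL,
                       out_dir = tempfile("attnwarp_run_")) {
  experiment <- match.arg(experiment, .experiments)
  structure(list(
    experiment = experiment, n_observers = n_observers, observer = observer,
    seed = as.integer(seed), exclusion_thresholds = exclusion_thresholds,
    fit = fit, fit_args = fit_args, geometry = geometry,
    geometry_spec = geometry_spec, geometry_gain = geometry_gain,
    input = input, input_mapping = input_mapping, out_dir = out_dir),
    class = "run_config")
}

#' Run the full pipeline
#'
#' Design -> simulate (or ingest an existing table) -> exclusion filter ->
#' condition summaries -> bias-model fit -> optional population-geometry
#' stage. Every artifact is written under `config$out_dir` (trials CSV,
#' exclusion report, summary CSV, fit JSON, geometry JSON, run log with
#' package version, seed and config hash). Rerunning with the same config
#' and seed reproduces the simulate/fit artifacts bit for bit.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts (`trials`,
#'   `exclusions`, `summaries`, `fit`, `geometry`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    trials = file.path(config$out_dir, "trials.csv"),
    exclusions = file.path(config$out_dir, "exclusions.csv"),
    summaries = file.path(config$out_dir, "condition_summary.csv"),
    fit = file.path(config$out_dir, "fit.json"),
    geometry = file.path(config$out_dir, "geometry.json"),
    config = file.path(config$out_dir, "config.json"),
    log = file.path(config$out_dir, "run_log.json"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  trials <- stage("ingest", {
    if (!is.null(config$input)) {
      if (!is.null(config$input_mapping)) {
        read_trials_mapped(config$input, config$input_mapping)
      } else {
        read_trials(config$input, require_responses = TRUE)
      }
    } else {
      design <- design_experiment(config$experiment, seed = config$seed)
      simulate_cohort(config$n_observers, design, config$observer,
                      seed = config$seed)
    }
  })
  write_trials(trials, paths$trials)

  excl <- stage("exclusions",
                apply_exclusions(trials, config$exclusion_thresholds))
  utils::write.csv(excl$report, paths$exclusions, row.names = FALSE)

  summaries <- stage("summarize", condition_summary(excl$data))
  utils::write.csv(summaries, paths$summaries, row.names = FALSE)

  fit <- NULL
  if (isTRUE(config$fit)) {
    fit <- stage("fit", do.call(fit_bias_model,
                                c(list(summaries), config$fit_args)))
    jsonlite::write_json(list(
      estimates = as.list(fit$estimates), loglik = fit$loglik,
      n_params = fit$n_params, aic = fit$aic, converged = fit$converged,
      boundary = fit$boundary, predicted = fit$predicted),
      paths$fit, auto_unbox = TRUE, digits = NA)
  }

  geometry <- NULL
  if (isTRUE(config$geometry)) {
    geometry <- stage("geometry", {
      geo <- representational_geometry(config$geometry_spec,
                                       config$geometry_gain)
      asym <- if (config$geometry_gain$amplitude > 0) {
        asymmetry_index(config$geometry_spec, config$geometry_gain)
      } else 1.0
      list(result = geo, asymmetry_index = asym)
    })
    jsonlite::write_json(list(
      asymmetry_index = geometry$asymmetry_index,
      radii_cv = geometry$result$radii_cv,
      expansion_hue = geometry$result$expansion_hue,
      embedding = data.frame(hue = geometry$result$grid,
                             x = geometry$result$embedding[, 1],
                             y = geometry$result$embedding[, 2])),
      paths$geometry, auto_unbox = TRUE, digits = NA)
  }

  cfg_json <- list(
    experiment = config$experiment, n_observers = config$n_observers,
    seed = config$seed,
    exclusion_thresholds = as.list(config$exclusion_thresholds),
    fit = config$fit, geometry = config$geometry,
    input = config$input)
  jsonlite::write_json(cfg_json, paths$config, auto_unbox = TRUE)

  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("attnwarp")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(paths$config)),
    n_subjects_excluded = sum(excl$report$excluded),
    fit_converged = if (is.null(fit)) NA else fit$converged,
    timestamp_utc = format(Sys.time(), tz = "UTC")),
    paths$log, auto_unbox = TRUE)

  invisible(list(trials = trials, exclusions = excl, summaries = summaries,
                 fit = fit, geometry = geometry, paths = paths))
}
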