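#' Configuration for a full crosswalk study run
#'
#' @param majority A majority-population cohort data frame to be split into
#'   training and validation arms, or `"simulate"` to draw the default
#'   majority training and validation presets directly (in which case no
#'   split is performed and the preset sizes are used as the arm sizes).
#' @param minority A minority-population cohort data frame, `"simulate"` for
#'   the default minority preset, or `NULL` to skip the minority arm.
#' @param fraction Training fraction for the split (used only when
#'   `majority` is a data frame).
#' @param seed Integer seed controlling the split and/or simulation.
#' @param smooth Apply log-linear presmoothing before equating (default
#'   `TRUE`); with `FALSE` the raw observed distributions are equated, which
#'   leaves the conversion undefined beyond the observed score range.
#' @param degree Fixed presmoothing degree, or `NULL` to select by AIC over
#'   `candidates`.
#' @param candidates Candidate degrees for AIC selection (default `2:6`).
#' @param rounding Crosswalk rounding rule (see [equate_equipercentile()]).
#' @param output_dir Optional directory; when given, the crosswalk CSV, the
#'   cohort CSVs and the validation-report JSONs are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(majority = "simulate", minority = "simulate",
                       fraction = 0.7, seed = 1L, smooth = TRUE,
                       degree = NULL, candidates = 2:6,
                       rounding = "half_up", output_dir = NULL) {
  if (!(is.data.frame(majority) || identical(majority, "simulate"))) {
    abort("`majority` must be a cohort data frame or \"simulate\"",
          class = "equicross_config_error")
  }
  if (!(is.null(minority) || is.data.frame(minority) ||
        identical(minority, "simulate"))) {
    abort("`minority` must be a cohort data frame, \"simulate\", or NULL",
          class = "equicross_config_error")
  }
  structure(list(majority = majority, minority = minority,
                 fraction = fraction, seed = as.integer(seed),
                 smooth = isTRUE(smooth), degree = degree,
                 candidates = candidates, rounding = rounding,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full crosswalk study
#'
#' Executes the complete workflow: obtain (or split off) a training cohort,
#' presmooth both tests' score distributions, equate RUDAS to MMSE by the
#' equipercentile method, round the equated function into an integer
#' crosswalk, and validate that crosswalk on the majority validation arm and
#' (if provided) on the minority arm. The minority cohort is validation-only
#' and never contributes to the equating. Every stage is seeded, and each
#' validation report records the provenance of the crosswalk it was computed
#' against.
#'
#' @param config A [run_config()].
#' @return An object of class `study_run`: the training and validation
#'   cohorts, both `loglinear_fit`s, the `equating_result`, the `crosswalk`,
#'   the majority and (optional) minority `validation_report`s, and the
#'   config.
#' @examples
#' run <- run_study(run_config(seed = 11))
#' run$crosswalk
#' glance(run$report_majority)
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  stage <- "data"
  result <- tryCatch({
    if (is.data.frame(config$majority)) {
      pool <- as_cohort(config$majority)
      parts <- split_train_validation(pool, fraction = config$fraction,
                                      seed = seed)
      training <- parts$training
      validation <- parts$validation
    } else {
      presets <- default_configs()
      training <- simulate_cohort(presets$majority_training, seed = seed)
      validation <- simulate_cohort(presets$majority_validation,
                                    seed = seed + 1L)
    }
    minority <- NULL
    if (is.data.frame(config$minority)) {
      minority <- as_cohort(config$minority)
    } else if (identical(config$minority, "simulate")) {
      minority <- simulate_cohort(default_configs()$minority, seed = seed + 2L)
    }

    stage <- "smoothing"
    dist_r <- score_distribution(training$rudas)
    dist_m <- score_distribution(training$mmse)
    if (!config$smooth) {
      fit_r <- dist_r
      fit_m <- dist_m
    } else if (is.null(config$degree)) {
      fit_r <- select_degree(dist_r, config$candidates)
      fit_m <- select_degree(dist_m, config$candidates)
    } else {
      fit_r <- fit_loglinear(dist_r, config$degree)
      fit_m <- fit_loglinear(dist_m, config$degree)
    }

    stage <- "equating"
    equating <- equate_equipercentile(fit_r, fit_m, rounding = config$rounding)
    table <- equating$crosswalk

    stage <- "validation"
    report_majority <- validate_crosswalk(validation, table)
    report_minority <- if (!is.null(minority)) {
      validate_crosswalk(minority, table)
    }

    structure(
      list(training = training, validation = validation, minority = minority,
           fit_rudas = fit_r, fit_mmse = fit_m, equating = equating,
           crosswalk = table, report_majority = report_majority,
           report_minority = report_minority, config = config, seed = seed),
      class = "study_run"
    )
  }, error = function(e) {
    abort(paste0("study run failed at stage '", stage, "': ",
                 conditionMessage(e)),
          class = "equicross_pipeline_error", stage = stage, parent = e)
  })

  if (!is.null(config$output_dir)) write_study_run(result, config$output_dir)
  result
}

write_study_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_crosswalk(run$crosswalk, file.path(dir, "crosswalk.csv"))
  write_cohort(run$training, file.path(dir, "training.csv"))
  write_cohort(run$validation, file.path(dir, "validation_majority.csv"))
  if (!is.null(run$minority)) {
    write_cohort(run$minority, file.path(dir, "validation_minority.csv"))
  }
  export_report_json(run$report_majority,
                     file.path(dir, "report_majority.json"))
  if (!is.null(run$report_minority)) {
    export_report_json(run$report_minority,
                       file.path(dir, "report_minority.json"))
  }
  settings <- list(
    seed = run$seed, fraction = run$config$fraction,
    degree_rudas = run$fit_rudas$degree %||% NA,
    degree_mmse = run$fit_mmse$degree %||% NA,
    rounding = run$config$rounding,
    crosswalk_provenance = attr(run$crosswalk, "provenance"),
    n_training = nrow(run$training), n_validation = nrow(run$validation),
    n_minority = if (!is.null(run$minority)) nrow(run$minority)
  )
  writeLines(jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA),
             file.path(dir, "settings.json"))
  invisible(run)
}

#' @export
print.study_run <- function(x, ...) {
  cat("Crosswalk study run (seed ", x$seed, ")\n", sep = "")
  cat("  training n = ", nrow(x$training),
      if (inherits(x$fit_rudas, "loglinear_fit")) {
        paste0(", presmoothing degrees ", x$fit_rudas$degree, "/",
               x$fit_mmse$degree)
      } else ", unsmoothed",
      "\n", sep = "")
  print(x$report_majority)
  if (!is.null(x$report_minority)) print(x$report_minority)
  invisible(x)
}

#' @export
glance.study_run <- function(x, ...) {
  maj <- x$report_majority$overall
  out <- tibble(
    seed = x$seed, n_training = nrow(x$training),
    degree_rudas = x$fit_rudas$degree %||% NA_integer_,
    degree_mmse = x$fit_mmse$degree %||% NA_integer_,
    icc_majority = maj$icc, pct_within_1_majority = maj$pct_within_1,
    pct_within_2_majority = maj$pct_within_2
  )
  if (!is.null(x$report_minority)) {
    min_ <- x$report_minority$overall
    out$icc_minority <- min_$icc
    out$pct_within_1_minority <- min_$pct_within_1
    out$pct_within_2_minority <- min_$pct_within_2
  }
  out
}
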