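#' Run the full analysis pipeline
#'
#' End-to-end execution: obtain trial data (from a CSV, an in-memory table,
#' or by simulating a cohort), filter invalid fixations, apply the observer
#' exclusion rules, compute every proportion metric with BCa bootstrap CIs,
#' emit the analytic prediction table, the logit-additivity test on the
#' ambiguous (CC) conditions, and the trial-order trend regression. A
#' manifest records the master seed, package version and the counts at every
#' filtering stage; on a partial failure the manifest written so far is
#' saved before the error propagates.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{experiment}{1, 2 or 3.}
#'     \item{input}{Path to a trial CSV (optional).}
#'     \item{column_map}{Optional list with `columns` / `values` entries for
#'       [column_map()], applied when reading `input`.}
#'     \item{trials}{An in-memory trial table (optional).}
#'     \item{simulate}{Self-contained mode: a list with `n_observers`,
#'       `observer` (an [observer_params()] or the name of a preset:
#'       `"foveal_trust"`, `"filling_in"`, `"perceptual_gap"`,
#'       `"photopic_veridical"`), optional `lightings` (default both sessions
#'       for experiments 1-2), and `seed`.}
#'     \item{bootstrap}{List with `n_samples`, `confidence`, `seed`, `unit`.}
#'     \item{outdir}{Output directory (optional; nothing is written when
#'       absent).}
#'   }
#' @return A results bundle (list): `proportions`, `predictions`,
#'   `additivity`, `trend`, `exclusions`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$experiment))
  experiment <- check_experiment(config$experiment)
  boot_cfg <- do.call(bootstrap_config, config$bootstrap %||% list())
  master_seed <- config$simulate$seed %||% boot_cfg$seed %||% 1L

  manifest <- list(
    package = "scotovis",
    version = as.character(utils::packageVersion("scotovis")),
    experiment = experiment,
    master_seed = master_seed,
    bootstrap = unclass(boot_cfg),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  save_manifest <- function() {
    if (!is.null(outdir)) {
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  on.exit(save_manifest())

  # --- acquire trials -------------------------------------------------------
  if (!is.null(config$trials)) {
    trials <- validate_trials(config$trials)
    manifest$source <- "in-memory table"
  } else if (!is.null(config$input)) {
    map <- if (!is.null(config$column_map)) {
      column_map(columns = unlist(config$column_map$columns),
                 values = lapply(config$column_map$values, unlist))
    }
    trials <- read_trials(config$input, map)
    manifest$source <- config$input
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    params <- sim$observer %||% "foveal_trust"
    if (is.character(params)) {
      params <- switch(params,
        foveal_trust = foveal_trust_observer(),
        filling_in = filling_in_observer(),
        perceptual_gap = perceptual_gap_observer(),
        photopic_veridical = photopic_veridical_observer(),
        stop("unknown observer preset: ", params, call. = FALSE)
      )
    }
    cohort <- observer_cohort(sim$n_observers %||% 22L, params)
    lightings <- sim$lightings %||%
      (if (experiment == 3L) "photopic" else c("scotopic", "photopic"))
    schedule <- dplyr::bind_rows(lapply(lightings, function(lt) {
      build_schedule(experiment, seed = master_seed, lighting = lt)
    }))
    trials <- simulate_experiment(schedule, cohort, master_seed = master_seed)
    manifest$source <- "simulation"
    manifest$n_simulated_observers <- length(cohort)
  } else {
    stop("config must provide `trials`, `input` or `simulate`", call. = FALSE)
  }
  manifest$n_input_trials <- nrow(trials)
  manifest$n_input_observers <- length(unique(trials$observer_id))

  # --- validity and exclusions ---------------------------------------------
  flt <- filter_valid(trials)
  manifest$n_valid_trials <- flt$n_valid
  manifest$n_rejected_trials <- flt$n_rejected
  excl <- apply_exclusions(flt$valid, experiment)
  manifest$n_retained_observers <- length(excl$retained)
  manifest$n_excluded_observers <- excl$report$n_excluded
  kept <- excl$trials

  # --- metrics --------------------------------------------------------------
  props <- list()
  if (experiment %in% c(1L, 3L)) {
    if (experiment == 1L) {
      props$correct <- proportion_correct(kept, boot_cfg)
    }
    props$less_ecc <- proportion_less_ecc(kept, "reported_continuous",
                                          config = boot_cfg)
  } else {
    props$less_ecc <- proportion_less_ecc(kept, "selected", config = boot_cfg)
    props$less_ecc_avg <- proportion_less_ecc(kept, "selected",
                                              sequence_averaged = TRUE,
                                              config = boot_cfg)
    props$appearance <- proportion_appearance(kept, config = boot_cfg)
  }
  proportions <- dplyr::bind_rows(props)

  predictions <- if (experiment %in% c(1L, 2L)) {
    prediction_table(experiment)
  }

  # --- additivity on the ambiguous (CC) conditions -------------------------
  metric_col <- if (experiment == 2L) "selected_less" else "chose_less"
  cc <- kept %>%
    dplyr::filter(!.data$is_same_ecc, .data$grouped_types == "CC") %>%
    dplyr::group_by(.data$lighting, .data$grouped_ecc, .data$observer_id) %>%
    dplyr::summarise(p = mean(.data[[metric_col]]), .groups = "drop")
  additivity <- lapply(split(cc, cc$lighting), function(df) {
    wide <- tidyr::pivot_wider(df, names_from = "grouped_ecc",
                               values_from = "p")
    if (!all(c("0|4", "4|8", "0|8") %in% names(wide)) ||
        anyNA(wide[c("0|4", "4|8", "0|8")]) || nrow(wide) < 2) {
      return(NULL)
    }
    additivity_test(wide[["0|4"]], wide[["4|8"]], wide[["0|8"]], boot_cfg)
  })
  additivity <- Filter(Negate(is.null), additivity)

  # --- trial-order trend ----------------------------------------------------
  series <- trial_series(kept, metric = metric_col)
  trend <- trend_regression(series)

  manifest$status <- "complete"
  results <- list(proportions = proportions, predictions = predictions,
                  additivity = additivity, trend = trend,
                  exclusions = excl[c("retained", "excluded", "report")],
                  manifest = manifest)

  if (!is.null(outdir)) {
    readr::write_csv(proportions, file.path(outdir, "proportions.csv"))
    if (!is.null(predictions)) {
      readr::write_csv(predictions, file.path(outdir, "predictions.csv"))
    }
    jsonlite::write_json(
      list(retained = excl$retained,
           excluded = excl$excluded,
           report = excl$report),
      file.path(outdir, "exclusions.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      lapply(additivity, function(a)
        a[c("mean_difference", "ci_low", "ci_high", "covers_zero",
            "n_observers")]),
      file.path(outdir, "additivity.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(
      tibble::tibble(slope = trend$slope, intercept = trend$intercept,
                     slope_ci_low = trend$slope_ci[1],
                     slope_ci_high = trend$slope_ci[2]),
      file.path(outdir, "trend.csv"))
  }
  results
}

`%||%` <- function(x, y) if (is.null(x)) y else x
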