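#' Split trials into valid and rejected by fixation deviation
#'
#' A trial is invalid when the fixation deviated strictly more than 2 degrees
#' of visual angle during the stimulus window; a deviation of exactly 2
#' degrees is valid. Trial tables carrying only a precomputed `valid` flag
#' are honoured as-is.
#'
#' @param trials Trial-record tibble with a `max_fixation_deviation` column
#'   (degrees) or a logical `valid` column.
#' @return A list with elements `valid`, `rejected` (tibbles) and the counts
#'   `n_valid`, `n_rejected`.
#' @export
filter_valid <- function(trials) {
  if ("max_fixation_deviation" %in% names(trials)) {
    dev <- trials$max_fixation_deviation
    stopifnot(all(dev >= 0, na.rm = TRUE))
    ok <- dev <= FIXATION_LIMIT_DEG
  } else if ("valid" %in% names(trials)) {
    ok <- trials$valid
  } else {
    stop("trials carry neither `max_fixation_deviation` nor `valid`",
         call. = FALSE)
  }
  list(valid = trials[ok, , drop = FALSE],
       rejected = trials[!ok, , drop = FALSE],
       n_valid = sum(ok), n_rejected = sum(!ok))
}

# Attach grouped-condition columns and recoded responses to a trial table.
add_grouping <- function(trials) {
  norm <- normalize_condition(trials$ecc_first, trials$ecc_second,
                              trials$type_first, trials$type_second,
                              fixation_pos = trials$fixation_pos)
  trials <- dplyr::bind_cols(trials, norm)
  trials$retinal_first <- abs(trials$ecc_first - trials$fixation_pos)
  trials$retinal_second <- abs(trials$ecc_second - trials$fixation_pos)

  if ("response_comparison" %in% names(trials)) {
    stopifnot(all(trials$response_comparison %in% c("first", "second")))
    chosen <- ifelse(trials$response_comparison == "first", 1L, 2L)
    # recode discontinuity-instructed responses to "which appeared continuous"
    cont <- ifelse(trials$instruction == "continuity", chosen, 3L - chosen)
    trials$reported_cont_interval <- cont
    cont_type <- ifelse(cont == 1L, trials$type_first, trials$type_second)
    trials$correct <- cont_type == "C"
    less_first <- trials$retinal_first < trials$retinal_second
    trials$chose_less <- ifelse(trials$is_same_ecc, NA,
                                (cont == 1L) == less_first)
  }
  if ("response_selection" %in% names(trials)) {
    stopifnot(all(trials$response_selection %in% c("first", "second")))
    sel <- ifelse(trials$response_selection == "first", 1L, 2L)
    less_first <- trials$retinal_first < trials$retinal_second
    trials$selected_less <- ifelse(trials$is_same_ecc, NA,
                                   (sel == 1L) == less_first)
    trials$selected_ecc <- ifelse(sel == 1L, trials$retinal_first,
                                  trials$retinal_second)
    trials$selected_type <- ifelse(sel == 1L, trials$type_first,
                                   trials$type_second)
    if ("response_appearance" %in% names(trials)) {
      stopifnot(all(trials$response_appearance %in%
                      c("continuous", "discontinuous")))
      trials$reported_continuous <-
        trials$response_appearance == "continuous"
      trials$appearance_correct <- trials$reported_continuous ==
        (trials$selected_type == "C")
    }
  }
  trials
}

# Grouped-condition key used by the trial-count exclusion rule.
grouped_key <- function(trials, experiment) {
  if (experiment %in% c(1L, 2L)) {
    paste(trials$lighting, trials$grouped_ecc, trials$grouped_types)
  } else {
    paste(trials$lighting, trials$condition_id)  # experiment 3: ungrouped
  }
}

#' Apply the observer-exclusion rules
#'
#' Works on validity-filtered trials. Observers are excluded when:
#'
#' * the number of valid trials in any grouped condition falls below half of
#'   the scheduled repetitions: fewer than 12 trials (experiments 1 and 2;
#'   experiment 2 keeps the same absolute floor of 12 despite more
#'   repetitions) or fewer than 6 trials in any ungrouped condition
#'   (experiment 3);
#' * task accuracy is at or below 75% in any unambiguous same-eccentricity
#'   condition (experiment 1; the 0-degree scotopic condition is exempt,
#'   discrimination there being impossible inside the scotoma), in any
#'   appearance-task condition (experiment 2; a discontinuous stimulus at 0
#'   degrees scotopic is exempt), or overall across unambiguous trials
#'   (experiment 3).
#'
#' @param trials Valid trials (see [filter_valid()]).
#' @param experiment Experiment number; defaults to the one in `trials`.
#' @return A list: `trials` (rows of retained observers, with grouping
#'   columns attached), `retained`, `excluded` (tibble of observer_id +
#'   reason), and `report` (counts). An empty retained set is allowed with a
#'   warning.
#' @export
apply_exclusions <- function(trials, experiment = trials$experiment[1]) {
  experiment <- check_experiment(experiment)
  trials <- add_grouping(trials)
  trials$.group <- grouped_key(trials, experiment)
  min_trials <- if (experiment == 3L) 6L else 12L

  counts <- trials %>%
    dplyr::count(.data$observer_id, .data$.group)
  low_count <- counts %>%
    dplyr::group_by(.data$observer_id) %>%
    dplyr::summarise(low = any(.data$n < min_trials), .groups = "drop") %>%
    dplyr::filter(.data$low)
  # a grouped condition with zero valid trials never appears in `counts`;
  # detect it through the number of distinct grouped conditions per observer
  n_groups <- length(unique(trials$.group))
  missing_grp <- counts %>%
    dplyr::count(.data$observer_id, name = "present") %>%
    dplyr::filter(.data$present < n_groups)
  excluded <- tibble::tibble(
    observer_id = union(low_count$observer_id, missing_grp$observer_id),
    reason = "valid trials below minimum in a grouped condition"
  )

  acc <- NULL
  if (experiment == 1L && "correct" %in% names(trials)) {
    acc <- trials %>%
      dplyr::filter(.data$is_same_ecc,
                    !(.data$lighting == "scotopic" & .data$retinal_first == 0)) %>%
      dplyr::group_by(.data$observer_id, .data$lighting, .data$retinal_first) %>%
      dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
  } else if (experiment == 2L && "appearance_correct" %in% names(trials)) {
    acc <- trials %>%
      dplyr::filter(!(.data$lighting == "scotopic" & .data$selected_ecc == 0 &
                        .data$selected_type == "D")) %>%
      dplyr::group_by(.data$observer_id, .data$lighting, .data$selected_ecc,
                      .data$selected_type) %>%
      dplyr::summarise(accuracy = mean(.data$appearance_correct),
                       .groups = "drop")
  } else if (experiment == 3L && "correct" %in% names(trials)) {
    acc <- trials %>%
      dplyr::filter(.data$grouped_types != "CC") %>%
      dplyr::group_by(.data$observer_id) %>%
      dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
  }
  if (!is.null(acc)) {
    low_acc <- acc %>% dplyr::filter(.data$accuracy <= 0.75)
    new <- setdiff(unique(low_acc$observer_id), excluded$observer_id)
    if (length(new)) {
      excluded <- dplyr::bind_rows(
        excluded,
        tibble::tibble(observer_id = new,
                       reason = "accuracy at or below 75% in a control condition")
      )
    }
  }

  retained <- setdiff(unique(trials$observer_id), excluded$observer_id)
  if (length(retained) == 0) {
    warning("all observers excluded; retained set is empty")
  }
  kept <- trials %>%
    dplyr::filter(.data$observer_id %in% retained) %>%
    dplyr::select(-".group")
  list(trials = kept, retained = retained, excluded = excluded,
       report = list(n_input_observers = length(unique(trials$observer_id)),
                     n_retained = length(retained),
                     n_excluded = nrow(excluded),
                     min_trials = min_trials))
}

# Mean across observers of per-observer proportions, with a BCa CI.
summarise_estimates <- function(per_obs, config) {
  groups <- dplyr::group_vars(per_obs)
  out <- per_obs %>%
    dplyr::summarise(
      point = mean(.data$p),
      n_observers = dplyr::n(),
      n_trials = sum(.data$n),
      .p = list(.data$p),
      .groups = "drop"
    )
  cis <- lapply(seq_len(nrow(out)), function(i) {
    vals <- out$.p[[i]]
    if (length(vals) < 2) return(c(ci_low = NA_real_, ci_high = NA_real_))
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + i  # group-specific stream
    suppressWarnings(bca_ci(vals, cfg))
  })
  out$ci_low <- vapply(cis, `[[`, numeric(1), 1)
  out$ci_high <- vapply(cis, `[[`, numeric(1), 2)
  out %>%
    dplyr::select(dplyr::all_of(groups), "point", "ci_low", "ci_high",
                  "n_observers", "n_trials")
}

#' Proportion correct in same-eccentricity conditions
#'
#' For each lighting and eccentricity, the proportion of trials in which the
#' interval reported as continuous actually contained the continuous
#' stimulus (discontinuity-instructed responses are recoded first). CD and DC
#' sequences are pooled per eccentricity; the point estimate is the mean
#' across observers of per-observer proportions.
#'
#' @param trials Valid trials of retained observers (experiment 1).
#' @param config A [bootstrap_config()] for the CIs.
#' @return A tibble with one row per lighting x eccentricity: `metric`,
#'   `point`, `ci_low`, `ci_high`, `n_observers`, `n_trials`.
#' @export
proportion_correct <- function(trials, config = bootstrap_config()) {
  if (!"correct" %in% names(trials)) trials <- add_grouping(trials)
  per_obs <- trials %>%
    dplyr::filter(.data$is_same_ecc) %>%
    dplyr::group_by(.data$lighting, ecc = .data$retinal_first,
                    .data$observer_id) %>%
    dplyr::summarise(p = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::group_by(.data$lighting, .data$ecc)
  summarise_estimates(per_obs, config) %>%
    dplyr::mutate(metric = "correct", .before = 1)
}

#' Proportion of less-eccentric stimuli reported continuous or selected
#'
#' After normalizing reversed sequences and merging screen sides, computes
#' per grouped different-eccentricity condition the per-observer proportion
#' of trials in which the less-eccentric stimulus was reported as continuous
#' (comparison task, experiments 1/3) or selected for judgment (selection
#' task, experiment 2), then averages across observers.
#'
#' With `sequence_averaged = TRUE` the two mixed-type conditions of each
#' eccentricity pair (continuous-less/discontinuous-more and vice versa) are
#' pooled before the per-observer proportion is formed, cancelling
#' stimulus-type preferences; the pooled rows are labelled `"CD+DC"`.
#'
#' @param trials Valid trials of retained observers.
#' @param metric `"reported_continuous"` (comparison response) or
#'   `"selected"` (selection response).
#' @param sequence_averaged Pool the two mixed-type conditions per pair.
#' @param config A [bootstrap_config()].
#' @return A tibble with one row per lighting x grouped pair x stimulus-type
#'   assignment.
#' @export
proportion_less_ecc <- function(trials,
                                metric = c("reported_continuous", "selected"),
                                sequence_averaged = FALSE,
                                config = bootstrap_config()) {
  metric <- match.arg(metric)
  col <- if (metric == "reported_continuous") "chose_less" else "selected_less"
  if (!col %in% names(trials)) trials <- add_grouping(trials)
  df <- trials %>% dplyr::filter(!.data$is_same_ecc)
  if (sequence_averaged) {
    df <- df %>%
      dplyr::mutate(grouped_types = ifelse(.data$grouped_types == "CC",
                                           "CC", "CD+DC"))
  }
  per_obs <- df %>%
    dplyr::group_by(.data$lighting, .data$grouped_ecc, .data$grouped_types,
                    .data$observer_id) %>%
    dplyr::summarise(p = mean(.data[[col]]), n = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::group_by(.data$lighting, .data$grouped_ecc, .data$grouped_types)
  summarise_estimates(per_obs, config) %>%
    dplyr::mutate(metric = paste0("less_ecc_",
                                  if (metric == "selected") "selected"
                                  else "continuous"),
                  .before = 1)
}

#' Proportion of selected stimuli reported continuous (appearance task)
#'
#' For each lighting, eccentricity and true type of the selected stimulus,
#' the proportion of appearance reports of "continuous". Because the
#' observer's own selection bias determines how many trials feed each cell,
#' observer-condition cells with fewer than `min_trials` contributing trials
#' (default 14) are excluded from the analysis.
#'
#' @param trials Valid trials of retained observers (experiment 2).
#' @param min_trials Minimum contributing trials per observer-condition cell.
#' @param config A [bootstrap_config()].
#' @return A tibble with one row per lighting x selected eccentricity x
#'   selected type.
#' @export
proportion_appearance <- function(trials, min_trials = 14,
                                  config = bootstrap_config()) {
  if (!"reported_continuous" %in% names(trials)) trials <- add_grouping(trials)
  per_obs <- trials %>%
    dplyr::group_by(.data$lighting, .data$selected_ecc, .data$selected_type,
                    .data$observer_id) %>%
    dplyr::summarise(p = mean(.data$reported_continuous), n = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::filter(.data$n >= min_trials) %>%
    dplyr::group_by(.data$lighting, .data$selected_ecc, .data$selected_type)
  summarise_estimates(per_obs, config) %>%
    dplyr::mutate(metric = "reported_continuous", .before = 1)
}

#' Across-observer response series by within-condition trial number
#'
#' Orders the valid trials of each observer and grouped condition by their
#' position in the session, numbers them within the condition, and averages
#' the response metric across observers and conditions at each trial number.
#' Feed the result to [trend_regression()].
#'
#' @param trials Valid trials of retained observers.
#' @param metric Column to average (`"chose_less"`, `"selected_less"`, ...).
#' @return A tibble `trial_number`, `mean_value`, `n`.
#' @export
trial_series <- function(trials, metric = "chose_less") {
  if (!metric %in% names(trials)) trials <- add_grouping(trials)
  trials %>%
    dplyr::filter(!is.na(.data[[metric]])) %>%
    dplyr::group_by(.data$observer_id, .data$lighting, .data$grouped_ecc,
                    .data$grouped_types) %>%
    dplyr::arrange(.data$trial_index, .by_group = TRUE) %>%
    dplyr::mutate(trial_number = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$trial_number) %>%
    dplyr::summarise(mean_value = mean(.data[[metric]]), n = dplyr::n(),
                     .groups = "drop")
}
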