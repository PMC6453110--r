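#' Condition sets of the three experiments
#'
#' Enumerates the interleaved conditions of one experimental session, before
#' repetition, screen-side and orientation counterbalancing.
#'
#' Experiment 1 crosses 3 same-eccentricity conditions (0, 4, 8 degrees; CD and
#' DC temporal sequences) with 9 different-eccentricity conditions (pairs
#' 0|4, 0|8, 4|8; stimulus-type sequences CC, CD, DC) in both location orders,
#' giving 24 conditions. Experiment 2 keeps only the 18 different-eccentricity
#' conditions. Experiment 3 crosses 3 initial fixation positions (-4, 0, 4
#' degrees from screen centre) with 2 signed retinal eccentricity pairs
#' (0|4, 0|-4), 3 type sequences and 2 location orders, giving 36 conditions.
#' DD pairs never occur.
#'
#' @param experiment Integer 1, 2 or 3.
#' @param lighting `"scotopic"` or `"photopic"`. Experiment 3 was run under
#'   photopic viewing only.
#' @return A tibble with one row per condition: `experiment`, `lighting`,
#'   `ecc_first`, `ecc_second` (unsigned eccentricities for experiments 1-2,
#'   signed screen positions for experiment 3), `fixation_pos`, `type_first`,
#'   `type_second` and a `condition_id` label that collapses repetitions,
#'   sides and orientations.
#' @export
#' @examples
#' nrow(conditions_table(1))  # 24
conditions_table <- function(experiment,
                             lighting = if (identical(as.integer(experiment), 3L))
                               "photopic" else "scotopic") {
  experiment <- check_experiment(experiment)
  lighting <- match.arg(lighting, c("scotopic", "photopic"))
  if (experiment == 3L && lighting != "photopic") {
    stop("experiment 3 was run under photopic viewing only", call. = FALSE)
  }

  type_pairs <- tibble::tibble(
    types = c("CC", "CD", "DC"),
    type_first = c("C", "C", "D"),
    type_second = c("C", "D", "C")
  )

  if (experiment %in% c(1L, 2L)) {
    pairs <- rbind(c(0, 4), c(4, 0), c(0, 8), c(8, 0), c(4, 8), c(8, 4))
    diff <- tidyr::expand_grid(
      pair = seq_len(nrow(pairs)),
      types = type_pairs$types
    ) %>%
      dplyr::left_join(type_pairs, by = "types") %>%
      dplyr::mutate(
        ecc_first = pairs[.data$pair, 1],
        ecc_second = pairs[.data$pair, 2],
        fixation_pos = 0
      ) %>%
      dplyr::select(-"pair", -"types")
    conds <- diff
    if (experiment == 1L) {
      same <- tidyr::expand_grid(
        ecc = ECCENTRICITIES,
        types = c("CD", "DC")
      ) %>%
        dplyr::left_join(type_pairs, by = "types") %>%
        dplyr::mutate(
          ecc_first = .data$ecc, ecc_second = .data$ecc,
          fixation_pos = 0
        ) %>%
        dplyr::select(-"ecc", -"types")
      conds <- dplyr::bind_rows(same, diff)
    }
  } else {
    retinal <- rbind(c(0, 4), c(4, 0), c(0, -4), c(-4, 0))
    conds <- tidyr::expand_grid(
      fixation_pos = c(-4, 0, 4),
      pair = seq_len(nrow(retinal)),
      types = type_pairs$types
    ) %>%
      dplyr::left_join(type_pairs, by = "types") %>%
      dplyr::mutate(
        # screen position = fixation + signed retinal eccentricity
        ecc_first = .data$fixation_pos + retinal[.data$pair, 1],
        ecc_second = .data$fixation_pos + retinal[.data$pair, 2]
      ) %>%
      dplyr::select(-"pair", -"types")
  }

  conds %>%
    dplyr::mutate(
      experiment = experiment,
      lighting = lighting,
      condition_id = condition_id(experiment, .data$ecc_first, .data$ecc_second,
                                  .data$fixation_pos, .data$type_first,
                                  .data$type_second)
    ) %>%
    dplyr::select("experiment", "lighting", "ecc_first", "ecc_second",
                  "fixation_pos", "type_first", "type_second", "condition_id")
}

condition_id <- function(experiment, ecc_first, ecc_second, fixation_pos,
                         type_first, type_second) {
  if (all(experiment %in% c(1L, 2L))) {
    sprintf("%g|%g:%s%s", abs(ecc_first), abs(ecc_second),
            type_first, type_second)
  } else {
    sprintf("fix%+g:%g|%g:%s%s", fixation_pos,
            ecc_first - fixation_pos, ecc_second - fixation_pos,
            type_first, type_second)
  }
}

check_experiment <- function(experiment) {
  if (length(experiment) != 1L || !experiment %in% 1:3) {
    stop("`experiment` must be 1, 2 or 3, got: ",
         paste(experiment, collapse = ", "), call. = FALSE)
  }
  as.integer(experiment)
}

#' Build a randomized trial schedule for one session
#'
#' Expands the condition set of [conditions_table()] by its repetition,
#' screen-side and orientation counterbalancing and shuffles the trial order.
#' Experiment 1: 24 conditions x (3 repetitions x 2 sides x 2 orientations)
#' = 288 trials; experiment 2: 18 x 16 = 288; experiment 3: 36 x (6
#' repetitions x 2 orientations) = 432 (no side factor; the signed retinal
#' pair already encodes the side of fixation). The shuffle is a full
#' permutation of the trial list, deterministic given `seed`.
#'
#' @param experiment Integer 1, 2 or 3.
#' @param seed Integer seed controlling the trial order.
#' @param lighting Session lighting; see [conditions_table()].
#' @param observer_id Identifier stamped on every trial.
#' @return A tibble with columns `observer_id`, `experiment`, `lighting`,
#'   `trial_index`, `ecc_first`, `ecc_second` (signed screen positions),
#'   `fixation_pos`, `type_first`, `type_second`, `side`, `orientation`,
#'   `condition_id`, `seed`.
#' @export
#' @examples
#' sched <- build_schedule(1, seed = 7)
#' nrow(sched)  # 288
build_schedule <- function(experiment, seed,
                           lighting = if (identical(as.integer(experiment), 3L))
                             "photopic" else "scotopic",
                           observer_id = "obs01") {
  experiment <- check_experiment(experiment)
  conds <- conditions_table(experiment, lighting)

  if (experiment %in% c(1L, 2L)) {
    reps <- if (experiment == 1L) 3L else 4L
    grid <- tidyr::expand_grid(
      rep = seq_len(reps),
      side = c("left", "right"),
      orientation = c("vertical", "horizontal"),
      condition_id = conds$condition_id
    ) %>%
      dplyr::left_join(conds, by = "condition_id") %>%
      dplyr::mutate(
        sign = ifelse(.data$side == "left", -1, 1),
        ecc_first = .data$sign * .data$ecc_first,
        ecc_second = .data$sign * .data$ecc_second
      ) %>%
      dplyr::select(-"sign")
  } else {
    grid <- tidyr::expand_grid(
      rep = 1:6,
      orientation = c("vertical", "horizontal"),
      condition_id = conds$condition_id
    ) %>%
      dplyr::left_join(conds, by = "condition_id") %>%
      dplyr::mutate(side = NA_character_)
  }

  ord <- withr::with_seed(seed, sample.int(nrow(grid)))
  grid[ord, ] %>%
    dplyr::mutate(
      observer_id = observer_id,
      trial_index = dplyr::row_number(),
      seed = as.integer(seed)
    ) %>%
    dplyr::select("observer_id", "experiment", "lighting", "trial_index",
                  "ecc_first", "ecc_second", "fixation_pos", "type_first",
                  "type_second", "side", "orientation", "condition_id", "seed")
}

#' Normalize a condition to its lower-eccentricity-first grouping
#'
#' Conditions with the same retinal eccentricities but reversed temporal
#' sequences (for example 0|4 and 4|0) are merged into one grouped condition,
#' labelled with the smaller absolute retinal eccentricity first. Screen sides
#' are merged by taking absolute retinal eccentricities (retinal eccentricity
#' = screen position - fixation position). The interval choice is recoded to
#' whether the stimulus at the smaller absolute eccentricity was chosen.
#' Same-eccentricity conditions map to themselves with an `NA` recoded choice.
#'
#' @param ecc_first,ecc_second Signed screen positions (degrees) of the first
#'   and second stimulus.
#' @param type_first,type_second Stimulus types, `"C"` or `"D"`.
#' @param choice Optional interval choice, `"first"` or `"second"`.
#' @param fixation_pos Fixation position (degrees from screen centre);
#'   0 except in experiment 3.
#' @return A tibble with `grouped_ecc` (e.g. `"0|4"`), `type_less`,
#'   `type_more` (stimulus types at the smaller / larger eccentricity;
#'   `grouped_types` is their concatenation), `is_same_ecc`, and (when
#'   `choice` is given) `choice` recoded to `"less-ecc"` / `"more-ecc"`.
#' @export
#' @examples
#' normalize_condition(4, 0, "C", "D", choice = "second")  # 0|4, less-ecc
normalize_condition <- function(ecc_first, ecc_second, type_first, type_second,
                                choice = NULL, fixation_pos = 0) {
  r1 <- abs(ecc_first - fixation_pos)
  r2 <- abs(ecc_second - fixation_pos)
  same <- r1 == r2
  less_is_first <- r1 < r2
  lo <- pmin(r1, r2)
  hi <- pmax(r1, r2)
  out <- tibble::tibble(
    grouped_ecc = sprintf("%g|%g", lo, hi),
    type_less = ifelse(same, NA_character_,
                       ifelse(less_is_first, type_first, type_second)),
    type_more = ifelse(same, NA_character_,
                       ifelse(less_is_first, type_second, type_first)),
    is_same_ecc = same
  )
  out$grouped_types <- ifelse(out$is_same_ecc, "CD+DC",
                              paste0(out$type_less, out$type_more))
  if (!is.null(choice)) {
    stopifnot(all(choice %in% c("first", "second")))
    chose_first <- choice == "first"
    out$choice <- ifelse(same, NA_character_,
                         ifelse(chose_first == less_is_first,
                                "less-ecc", "more-ecc"))
  }
  out
}

#' Write a schedule to tidy CSV
#'
#' @param schedule A schedule from [build_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(path)
}
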