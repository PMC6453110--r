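#' Column mapping for foreign trial-data schemas
#'
#' The deposited raw data of the study are consumed through a user-editable
#' mapping from the canonical trial-record field names to the source file's
#' column names, plus per-field value recodings (e.g. response intervals
#' coded 1/2 instead of "first"/"second").
#'
#' @param columns Named character vector: canonical name -> source column
#'   name. Canonical fields not listed are taken verbatim if present.
#' @param values Named list: canonical field -> named vector mapping source
#'   values (as character) to canonical values.
#' @return A list of class `column_map`.
#' @export
#' @examples
#' column_map(columns = c(observer_id = "subject"),
#'            values = list(response_comparison = c(`1` = "first",
#'                                                  `2` = "second")))
column_map <- function(columns = character(), values = list()) {
  stopifnot(is.character(columns), is.list(values))
  structure(list(columns = columns, values = values), class = "column_map")
}

trial_required_cols <- function(experiment) {
  base <- c("observer_id", "experiment", "lighting", "trial_index",
            "ecc_first", "ecc_second", "fixation_pos", "type_first",
            "type_second")
  resp <- if (experiment == 2L) c("response_selection", "response_appearance")
  else c("instruction", "response_comparison")
  c(base, resp)
}

#' Read a tidy trial-record CSV, optionally through a column map
#'
#' Reads trial-level data (UTF-8, comma separated, header row, "." decimal,
#' degrees as signed floats), applies the [column_map()] if given, and
#' validates the canonical invariants: known experiment, lighting, stimulus
#' types, response codes, and a non-negative fixation deviation (or a logical
#' validity flag). Rows violating value constraints are reported with their
#' row numbers.
#'
#' @param path CSV file path.
#' @param map Optional [column_map()].
#' @return A validated trial-record tibble.
#' @export
read_trials <- function(path, map = NULL) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(map)) {
    stopifnot(inherits(map, "column_map"))
    missing <- setdiff(unname(map$columns), names(df))
    if (length(missing)) {
      stop("mapped source column(s) not found in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (canonical in names(map$columns)) {
      names(df)[names(df) == map$columns[[canonical]]] <- canonical
    }
    for (field in names(map$values)) {
      if (!field %in% names(df)) next
      rec <- map$values[[field]]
      src <- as.character(df[[field]])
      unknown <- !src %in% names(rec) & !is.na(src)
      if (any(unknown)) {
        stop("unmappable value(s) in `", field, "` at row(s): ",
             paste(head(which(unknown), 10), collapse = ", "), call. = FALSE)
      }
      df[[field]] <- unname(rec[src])
    }
  }
  validate_trials(df)
}

validate_trials <- function(df) {
  if (!"experiment" %in% names(df)) {
    stop("trial table lacks an `experiment` column", call. = FALSE)
  }
  experiment <- check_experiment(unique(df$experiment))
  need <- trial_required_cols(experiment)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("trial table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!any(c("max_fixation_deviation", "valid") %in% names(df))) {
    stop("trial table carries neither `max_fixation_deviation` nor `valid`",
         call. = FALSE)
  }
  bad_rows <- function(ok, what) {
    if (!all(ok)) {
      stop("invalid ", what, " at row(s): ",
           paste(head(which(!ok), 10), collapse = ", "), call. = FALSE)
    }
  }
  bad_rows(df$lighting %in% c("scotopic", "photopic"), "lighting")
  bad_rows(df$type_first %in% c("C", "D") & df$type_second %in% c("C", "D"),
           "stimulus type")
  if ("response_comparison" %in% names(df)) {
    bad_rows(df$response_comparison %in% c("first", "second"),
             "comparison response")
    bad_rows(df$instruction %in% c("continuity", "discontinuity"),
             "instruction")
  }
  if ("response_selection" %in% names(df)) {
    bad_rows(df$response_selection %in% c("first", "second"),
             "selection response")
    bad_rows(df$response_appearance %in% c("continuous", "discontinuous"),
             "appearance response")
  }
  if ("max_fixation_deviation" %in% names(df)) {
    bad_rows(!is.na(df$max_fixation_deviation) &
               df$max_fixation_deviation >= 0, "fixation deviation")
  }
  df$experiment <- as.integer(df$experiment)
  if ("trial_index" %in% names(df)) df$trial_index <- as.integer(df$trial_index)
  if ("seed" %in% names(df)) df$seed <- as.integer(df$seed)
  if (!"condition_id" %in% names(df)) {
    df$condition_id <- condition_id(experiment, df$ecc_first, df$ecc_second,
                                    df$fixation_pos, df$type_first,
                                    df$type_second)
  }
  tibble::as_tibble(df)
}

#' Write a trial-record table to tidy CSV
#'
#' @param trials Trial-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}
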