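#' Analytic predicted proportion for one grouped condition
#'
#' Exact predicted proportions of the competing hypotheses, derived by
#' enumerating the decision rules over percept combinations (no simulation),
#' so every value is 0, 0.5 or 1.
#'
#' * `perceptual_gap` (scotopic only): the observer is aware of the foveal
#'   scotoma and bases decisions on the peripheral stimulus alone. In the
#'   comparison task a foveal stimulus is chosen as continuous always when
#'   the peripheral stimulus is discontinuous and never when it is
#'   continuous; in the selection task foveal stimuli are never selected.
#'   Pairs without the fovea (4|8) behave veridically.
#' * `filling_in` (scotopic only): the scotoma is filled in and the inferred
#'   percept is trusted like a veridical one. Any foveal stimulus is
#'   perceived as continuous; equally continuous percepts are chosen equally
#'   often. In the selection task no preference arises in any condition.
#' * `photopic_veridical` (photopic only): all percepts veridical and equally
#'   weighted; the correct stimulus is reported, and two continuous stimuli
#'   are chosen (or selected) equally often.
#'
#' @param hypothesis `"perceptual_gap"`, `"filling_in"` or
#'   `"photopic_veridical"`.
#' @param experiment 1 (comparison metric: less-eccentric stimulus reported
#'   continuous) or 2 (selection metric: less-eccentric stimulus selected).
#' @param lighting `"scotopic"` or `"photopic"`; must match the hypothesis.
#' @param grouped_ecc Grouped eccentricity pair, `"0|4"`, `"0|8"` or `"4|8"`.
#' @param grouped_types Types at the (less, more) eccentric position:
#'   `"CC"`, `"CD"` or `"DC"`.
#' @return The predicted proportion (0, 0.5 or 1).
#' @export
#' @examples
#' predicted_proportion("perceptual_gap", 1, "scotopic", "0|4", "DC")  # 0
predicted_proportion <- function(hypothesis, experiment, lighting,
                                 grouped_ecc, grouped_types) {
  hypothesis <- match.arg(hypothesis, c("perceptual_gap", "filling_in",
                                        "photopic_veridical"))
  lighting <- match.arg(lighting, c("scotopic", "photopic"))
  if (!experiment %in% c(1, 2)) {
    stop("predictions are defined for experiments 1 and 2 only",
         call. = FALSE)
  }
  if (hypothesis == "photopic_veridical" && lighting != "photopic") {
    stop("photopic_veridical is a prediction for photopic viewing",
         call. = FALSE)
  }
  if (hypothesis != "photopic_veridical" && lighting != "scotopic") {
    stop(hypothesis, " is a prediction for scotopic viewing", call. = FALSE)
  }
  if (!grouped_ecc %in% c("0|4", "0|8", "4|8")) {
    stop("unknown grouped eccentricity pair: ", grouped_ecc, call. = FALSE)
  }
  if (!grouped_types %in% c("CC", "CD", "DC")) {
    stop("grouped stimulus types must be CC, CD or DC (DD never occurs), got: ",
         grouped_types, call. = FALSE)
  }

  has_fovea <- grouped_ecc %in% c("0|4", "0|8")
  type_less <- substr(grouped_types, 1, 1)
  type_more <- substr(grouped_types, 2, 2)

  if (experiment == 2) {
    # Selection task: filling-in and photopic observers have no preference;
    # the perceptual-gap observer avoids the fovea.
    if (hypothesis == "perceptual_gap" && has_fovea) return(0)
    return(0.5)
  }

  # Comparison task: probability the less-eccentric stimulus is reported
  # continuous.
  veridical <- function(tl, tm) {
    if (tl == "C" && tm == "C") 0.5 else if (tl == "C") 1 else 0
  }
  if (hypothesis == "photopic_veridical" || !has_fovea) {
    return(veridical(type_less, type_more))
  }
  if (hypothesis == "perceptual_gap") {
    # decision rests on the peripheral (more eccentric) stimulus
    return(if (type_more == "C") 0 else 1)
  }
  # filling_in: foveal percept is continuous whatever was shown
  veridical("C", type_more)
}

#' Full prediction table for an experiment
#'
#' Enumerates every grouped different-eccentricity condition of the
#' comparison (experiment 1) or selection (experiment 2) task and the
#' predicted proportion of each applicable hypothesis: `perceptual_gap` and
#' `filling_in` under scotopic viewing, `photopic_veridical` under photopic
#' viewing.
#'
#' @param experiment 1 or 2.
#' @return A tibble: `experiment`, `hypothesis`, `lighting`, `grouped_ecc`,
#'   `grouped_types`, `predicted`.
#' @export
prediction_table <- function(experiment) {
  if (!experiment %in% c(1, 2)) {
    stop("predictions are defined for experiments 1 and 2 only",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    hypothesis = c("perceptual_gap", "filling_in", "photopic_veridical"),
    grouped_ecc = c("0|4", "0|8", "4|8"),
    grouped_types = c("CC", "CD", "DC")
  ) %>%
    dplyr::mutate(lighting = ifelse(.data$hypothesis == "photopic_veridical",
                                    "photopic", "scotopic"))
  grid$predicted <- vapply(seq_len(nrow(grid)), function(i) {
    predicted_proportion(grid$hypothesis[i], experiment, grid$lighting[i],
                         grid$grouped_ecc[i], grid$grouped_types[i])
  }, numeric(1))
  grid %>%
    dplyr::mutate(experiment = as.integer(experiment)) %>%
    dplyr::select("experiment", "hypothesis", "lighting", "grouped_ecc",
                  "grouped_types", "predicted")
}
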