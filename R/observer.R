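#' Generative observer parameters
#'
#' Bundles the parameters of the generative observer model that stands in for
#' a human participant:
#'
#' * `accuracy`: probability of a veridical centre-surround percept, per
#'   lighting and eccentricity. Inside the scotopic foveal scotoma (0 degrees,
#'   scotopic) the percept is governed by `p_fill` instead.
#' * `p_fill`: probability that a stimulus inside the scotopic foveal scotoma
#'   is perceived as continuous regardless of its true type; with probability
#'   `1 - p_fill` the observer perceives a gap (a distinguished GAP percept
#'   carrying no stimulus evidence). `p_fill = 0` is the perceptual-gap
#'   observer, `p_fill = 1` the fully filled-in observer.
#' * `reliability`: real-valued reliability score r(e) per eccentricity.
#'   When percepts tie, the lower-eccentricity stimulus is chosen with
#'   probability `plogis(r(e_low) - r(e_high))`, so biases are logit-additive
#'   across eccentricity pairs by construction.
#' * `tie_bias`: extra tie-break log-odds toward the lower-eccentricity
#'   stimulus, per grouped pair (`"0|4"`, `"0|8"`, `"4|8"`). Non-zero values
#'   break logit additivity; used to generate non-additive data.
#' * `lapse`: probability of a uniformly random response (applied at the
#'   decision stage, so same-eccentricity accuracy stays interpretable).
#' * `type_pref`: log-odds bonus for selecting a perceived-continuous
#'   stimulus in the selection task (experiment 2).
#' * `p_break`: per-trial probability of a fixation deviation beyond 2
#'   degrees (the trial-invalidation threshold).
#' * `instruction`: whether this observer reports which interval appeared
#'   continuous or which appeared discontinuous (assigned per observer, as in
#'   the comparison task).
#'
#' @param accuracy Named list with elements `photopic` and `scotopic`, each a
#'   vector named by eccentricity (`"0"`, `"4"`, `"8"`); or a single number
#'   used everywhere.
#' @param p_fill,reliability,tie_bias,lapse,type_pref,p_break,instruction
#'   See above.
#' @param label Observer label.
#' @return An object of class `observer_params`.
#' @export
#' @examples
#' observer_params(accuracy = 1, p_fill = 1, lapse = 0)
observer_params <- function(accuracy = list(
                              photopic = c(`0` = 0.99, `4` = 0.99, `8` = 0.99),
                              scotopic = c(`0` = 0.5, `4` = 0.95, `8` = 0.966)
                            ),
                            p_fill = 0.95,
                            reliability = c(`0` = 0, `4` = 0, `8` = 0),
                            lapse = 0,
                            type_pref = 0,
                            p_break = 0,
                            tie_bias = c(`0|4` = 0, `0|8` = 0, `4|8` = 0),
                            instruction = c("continuity", "discontinuity"),
                            label = "observer") {
  if (is.numeric(accuracy) && length(accuracy) == 1L) {
    acc <- stats::setNames(rep(accuracy, 3), as.character(ECCENTRICITIES))
    accuracy <- list(photopic = acc, scotopic = acc)
  }
  stopifnot(
    is.list(accuracy), all(c("photopic", "scotopic") %in% names(accuracy)),
    all(unlist(accuracy) >= 0), all(unlist(accuracy) <= 1),
    p_fill >= 0, p_fill <= 1,
    lapse >= 0, lapse <= 0.5,
    p_break >= 0, p_break <= 1,
    is.numeric(reliability)
  )
  reliability <- fill_named(reliability, as.character(ECCENTRICITIES), 0)
  tie_bias <- fill_named(tie_bias, c("0|4", "0|8", "4|8"), 0)
  instruction <- match.arg(instruction)
  structure(
    list(accuracy = accuracy, p_fill = p_fill, reliability = reliability,
         lapse = lapse, type_pref = type_pref, p_break = p_break,
         tie_bias = tie_bias, instruction = instruction, label = label),
    class = "observer_params"
  )
}

fill_named <- function(x, keys, default) {
  out <- stats::setNames(rep(default, length(keys)), keys)
  if (is.null(names(x)) && length(x) == length(keys)) {
    names(x) <- keys
  }
  out[names(x)] <- x
  out
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params> ", x$label, " (", x$instruction, " instruction)\n",
      sep = "")
  cat("  p_fill: ", x$p_fill, ", lapse: ", x$lapse,
      ", type_pref: ", x$type_pref, ", p_break: ", x$p_break, "\n", sep = "")
  cat("  reliability r(e): ",
      paste(names(x$reliability), round(x$reliability, 3),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

acc_of <- function(params, lighting, ecc) {
  key <- as.character(abs(ecc))
  out <- numeric(length(key))
  for (lt in unique(lighting)) {
    sel <- lighting == lt
    out[sel] <- params$accuracy[[lt]][key[sel]]
  }
  unname(out)
}

#' Idealized observers of the competing hypotheses
#'
#' Convenience constructors for the generative observers used to cross-check
#' the analytic predictions and to emulate the study cohort:
#'
#' * `perceptual_gap_observer()`: perceives a gap at the scotopic foveal
#'   scotoma (`p_fill = 0`), weighs all eccentricities equally otherwise.
#' * `filling_in_observer()`: fills in the scotoma (`p_fill = 1`) and trusts
#'   the inferred percept as much as peripheral percepts (equal reliability).
#' * `photopic_veridical_observer()`: perfect accuracy, no biases; meaningful
#'   for photopic sessions.
#' * `foveal_trust_observer()`: the logit-additive foveal-trust observer.
#'   Its default reliabilities (1.43, 0.54, 0 at 0, 4, 8 degrees) and
#'   accuracies reproduce the magnitude of the empirically reported central
#'   biases through `plogis(r(e_low) - r(e_high))`.
#'
#' @param accuracy,reliability,lapse,p_fill,... Passed to [observer_params()].
#' @return An `observer_params` object.
#' @export
perceptual_gap_observer <- function(accuracy = 1, lapse = 0, ...) {
  observer_params(accuracy = accuracy, p_fill = 0,
                  reliability = c(0, 0, 0), lapse = lapse,
                  label = "perceptual-gap", ...)
}

#' @rdname perceptual_gap_observer
#' @export
filling_in_observer <- function(accuracy = 1, lapse = 0, ...) {
  observer_params(accuracy = accuracy, p_fill = 1,
                  reliability = c(0, 0, 0), lapse = lapse,
                  label = "filling-in (equal trust)", ...)
}

#' @rdname perceptual_gap_observer
#' @export
photopic_veridical_observer <- function(lapse = 0, ...) {
  observer_params(accuracy = 1, p_fill = 1, reliability = c(0, 0, 0),
                  lapse = lapse, label = "photopic-veridical", ...)
}

#' @rdname perceptual_gap_observer
#' @export
foveal_trust_observer <- function(reliability = c(`0` = 1.43, `4` = 0.54,
                                                  `8` = 0),
                                  p_fill = 0.95, lapse = 0.02, ...) {
  observer_params(reliability = reliability, p_fill = p_fill, lapse = lapse,
                  p_break = 0.05, label = "foveal-trust", ...)
}

#' A cohort of identically parameterized observers
#'
#' Builds `n` observers sharing the same generative parameters, with labels
#' `obs01, obs02, ...` and the report instruction alternating between the
#' continuity and discontinuity framing (half of the cohort each, as in the
#' comparison task).
#'
#' @param n Number of observers.
#' @param params Template `observer_params`.
#' @return A named list of `observer_params`.
#' @export
observer_cohort <- function(n, params = foveal_trust_observer()) {
  stopifnot(n >= 1)
  ids <- sprintf("obs%02d", seq_len(n))
  out <- lapply(seq_len(n), function(i) {
    p <- params
    p$label <- ids[i]
    p$instruction <- if (i %% 2 == 1) "continuity" else "discontinuity"
    p
  })
  stats::setNames(out, ids)
}

#' Draw percepts for presented stimuli
#'
#' At the scotopic foveal scotoma (scotopic viewing, retinal eccentricity 0)
#' the percept is `"C"` (continuous) with probability `p_fill` and `"GAP"`
#' otherwise, irrespective of the true stimulus type. Elsewhere the percept
#' matches the true type with probability `accuracy(lighting, ecc)` and is the
#' opposite type otherwise.
#'
#' @param params An [observer_params()] object.
#' @param lighting `"scotopic"` or `"photopic"` (recycled).
#' @param retinal_ecc Retinal eccentricities in degrees; absolute values must
#'   be 0, 4 or 8.
#' @param true_type True stimulus types, `"C"` or `"D"`.
#' @return Character vector of percepts in `c("C", "D", "GAP")`.
#' @export
perceive <- function(params, lighting, retinal_ecc, true_type) {
  n <- max(length(retinal_ecc), length(true_type), length(lighting))
  lighting <- rep_len(lighting, n)
  retinal_ecc <- rep_len(retinal_ecc, n)
  true_type <- rep_len(true_type, n)
  ae <- abs(retinal_ecc)
  if (!all(ae %in% ECCENTRICITIES)) {
    stop("retinal eccentricity outside the calibrated set {0, 4, 8}: ",
         paste(unique(ae[!ae %in% ECCENTRICITIES]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(true_type %in% c("C", "D")))
  out <- character(n)
  u <- runif(n)
  scotoma <- lighting == "scotopic" & ae == 0
  out[scotoma] <- ifelse(u[scotoma] < params$p_fill, "C", "GAP")
  el <- !scotoma
  hit <- u[el] < acc_of(params, lighting[el], ae[el])
  out[el] <- ifelse(hit, true_type[el],
                    ifelse(true_type[el] == "C", "D", "C"))
  out
}

# Tie-break log-odds in favour of the FIRST interval for a pair of absolute
# retinal eccentricities: reliability difference plus any pair-specific bias
# oriented toward the lower-eccentricity stimulus.
tie_logit_first <- function(params, ecc_first, ecc_second) {
  r <- params$reliability
  base <- r[as.character(abs(ecc_first))] - r[as.character(abs(ecc_second))]
  lo <- pmin(abs(ecc_first), abs(ecc_second))
  hi <- pmax(abs(ecc_first), abs(ecc_second))
  pair <- sprintf("%g|%g", lo, hi)
  b <- ifelse(pair %in% names(params$tie_bias), params$tie_bias[pair], 0)
  direction <- sign(abs(ecc_second) - abs(ecc_first))  # +1 if first is lower
  unname(base + b * direction)
}

# Which interval looks (more convincingly) continuous. GAP percepts carry no
# evidence: with one GAP, a continuous other percept wins; a discontinuous
# other percept leaves the GAP interval as the better exemplar of
# "continuous" (forced choice). Ties resolve by the logistic reliability rule.
continuous_looking <- function(params, percept_first, percept_second,
                               ecc_first, ecc_second) {
  n <- length(percept_first)
  cont <- integer(n)
  both_gap <- percept_first == "GAP" & percept_second == "GAP"
  g1 <- percept_first == "GAP" & !both_gap
  g2 <- percept_second == "GAP" & !both_gap
  cont[g1] <- ifelse(percept_second[g1] == "C", 2L, 1L)
  cont[g2] <- ifelse(percept_first[g2] == "C", 1L, 2L)
  nog <- !g1 & !g2 & !both_gap
  uniq <- nog & ((percept_first == "C") != (percept_second == "C"))
  cont[uniq] <- ifelse(percept_first[uniq] == "C", 1L, 2L)
  tie <- nog & !uniq
  if (any(tie)) {
    lg <- tie_logit_first(params, ecc_first[tie], ecc_second[tie])
    cont[tie] <- ifelse(runif(sum(tie)) < plogis(lg), 1L, 2L)
  }
  if (any(both_gap)) {
    cont[both_gap] <- sample(1:2, sum(both_gap), replace = TRUE)
  }
  attr(cont, "both_gap") <- both_gap
  cont
}

#' Comparison-task decision (which interval matches the instruction)
#'
#' The observer first judges which interval appeared continuous: a unique
#' continuous percept wins; GAP percepts are never the instructed target (the
#' decision falls to the other stimulus); ties between identical percepts
#' resolve toward the lower-eccentricity stimulus with probability
#' `plogis(r(e_low) - r(e_high) + tie_bias)`. The response is that interval
#' under the continuity instruction and the other interval under the
#' discontinuity instruction, so both instruction groups yield identical
#' grouped-condition proportions after recoding. With probability `lapse` the
#' response is uniformly random. Trials where both percepts are GAP resolve
#' uniformly and are flagged in the `"both_gap"` attribute.
#'
#' @inheritParams perceive
#' @param percept_first,percept_second Percepts from [perceive()].
#' @param ecc_first,ecc_second Retinal eccentricities of the two intervals.
#' @param instruction `"continuity"` or `"discontinuity"`; defaults to the
#'   observer's own instruction.
#' @return Integer vector of chosen intervals (1 or 2).
#' @export
decide_comparison <- function(params, percept_first, percept_second,
                              ecc_first, ecc_second,
                              instruction = params$instruction) {
  cont <- continuous_looking(params, percept_first, percept_second,
                             ecc_first, ecc_second)
  choice <- if (instruction == "continuity") as.integer(cont) else 3L - cont
  choice <- apply_lapse(choice, params$lapse)
  attr(choice, "both_gap") <- attr(cont, "both_gap")
  choice
}

#' Selection-task decision (which interval to judge)
#'
#' The first interval is selected with probability
#' `plogis(r(e1) - r(e2) + tie_bias + type_pref * (C1 - C2))` where `C`
#' indicates a perceived-continuous stimulus. A GAP percept is never selected
#' when the other interval yielded a percept; two GAP percepts resolve
#' uniformly (flagged). Lapses replace the selection with a uniform draw.
#'
#' @inheritParams decide_comparison
#' @return Integer vector of selected intervals (1 or 2).
#' @export
decide_selection <- function(params, percept_first, percept_second,
                             ecc_first, ecc_second) {
  n <- length(percept_first)
  lg <- tie_logit_first(params, ecc_first, ecc_second) +
    params$type_pref * ((percept_first == "C") - (percept_second == "C"))
  sel <- ifelse(runif(n) < plogis(lg), 1L, 2L)
  both_gap <- percept_first == "GAP" & percept_second == "GAP"
  sel[percept_first == "GAP" & !both_gap] <- 2L
  sel[percept_second == "GAP" & !both_gap] <- 1L
  if (any(both_gap)) {
    sel[both_gap] <- sample(1:2, sum(both_gap), replace = TRUE)
  }
  sel <- apply_lapse(sel, params$lapse)
  attr(sel, "both_gap") <- both_gap
  sel
}

#' Appearance report for the selected stimulus
#'
#' Reports the percept with probability `1 - lapse` and a uniform guess
#' otherwise. A GAP percept does not appear continuous and is reported as
#' discontinuous (subject to the same lapse), so a partially filled-in
#' observer reports a foveal scotopic stimulus as continuous at rate
#' `p_fill * (1 - lapse) + lapse / 2`.
#'
#' @inheritParams decide_comparison
#' @param percept Percepts of the selected stimuli.
#' @return Character vector, `"continuous"` or `"discontinuous"`.
#' @export
report_appearance <- function(params, percept) {
  n <- length(percept)
  out <- ifelse(percept == "C", "continuous", "discontinuous")
  lap <- runif(n) < params$lapse
  if (any(lap)) {
    out[lap] <- sample(c("continuous", "discontinuous"), sum(lap),
                       replace = TRUE)
  }
  out
}

apply_lapse <- function(choice, lapse) {
  if (lapse <= 0) return(choice)
  lap <- runif(length(choice)) < lapse
  choice[lap] <- sample(1:2, sum(lap), replace = TRUE)
  choice
}

#' Simulate a full experiment for a cohort of observers
#'
#' Runs every observer through a trial schedule and records trial-level
#' responses with the statistical structure the analysis chain assumes:
#' percepts drawn by [perceive()], comparison or selection/appearance
#' responses by the decision rules, and a per-trial maximum fixation
#' deviation whose exceedance of 2 degrees (probability `p_break`) marks the
#' trial invalid. One RNG stream per observer is derived from `master_seed`,
#' so results are fully reproducible.
#'
#' @param schedule A schedule from [build_schedule()], or several sessions
#'   row-bound together (e.g. scotopic and photopic).
#' @param observers A single `observer_params` or a (named) list of them,
#'   e.g. from [observer_cohort()].
#' @param master_seed Integer master seed.
#' @return A tidy trial-record tibble: the schedule columns plus
#'   `observer_id`, `instruction`, `response_comparison` (experiments 1/3) or
#'   `response_selection` + `response_appearance` (experiment 2),
#'   `max_fixation_deviation` and `valid`.
#' @export
simulate_experiment <- function(schedule, observers, master_seed = 1) {
  if (inherits(observers, "observer_params")) observers <- list(observers)
  if (length(observers) == 0) {
    stop("`observers` must contain at least one observer", call. = FALSE)
  }
  ids <- names(observers)
  if (is.null(ids)) {
    ids <- vapply(seq_along(observers), function(i) {
      lbl <- observers[[i]]$label
      if (identical(lbl, "observer")) sprintf("obs%02d", i) else lbl
    }, character(1))
  }
  seeds <- withr::with_seed(master_seed,
                            sample.int(2147483646L, length(observers)))
  experiment <- schedule$experiment[1]
  r1 <- abs(schedule$ecc_first - schedule$fixation_pos)
  r2 <- abs(schedule$ecc_second - schedule$fixation_pos)
  n <- nrow(schedule)

  out <- lapply(seq_along(observers), function(i) {
    p <- observers[[i]]
    withr::with_seed(seeds[i], {
      pc1 <- perceive(p, schedule$lighting, r1, schedule$type_first)
      pc2 <- perceive(p, schedule$lighting, r2, schedule$type_second)
      tr <- schedule
      tr$observer_id <- ids[i]
      tr$instruction <- p$instruction
      if (experiment %in% c(1, 3)) {
        ch <- decide_comparison(p, pc1, pc2, r1, r2)
        tr$response_comparison <- c("first", "second")[ch]
      } else {
        sel <- decide_selection(p, pc1, pc2, r1, r2)
        tr$response_selection <- c("first", "second")[sel]
        tr$response_appearance <-
          report_appearance(p, ifelse(sel == 1L, pc1, pc2))
      }
      breaks <- runif(n) < p$p_break
      tr$max_fixation_deviation <- ifelse(breaks,
                                          FIXATION_LIMIT_DEG + runif(n, 0.1, 4),
                                          runif(n, 0, FIXATION_LIMIT_DEG * 0.95))
      tr$valid <- !breaks
      tr
    })
  })
  dplyr::bind_rows(out)
}
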