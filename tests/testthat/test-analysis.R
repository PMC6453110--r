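make_toy_trials <- function(correct_per_obs, n_per_obs = 4) {
  # same-eccentricity photopic trials at 4 deg, continuity instruction,
  # C shown first: responding "first" is correct
  obs <- rep(sprintf("obs%02d", seq_along(correct_per_obs)), each = n_per_obs)
  k <- unlist(lapply(correct_per_obs, function(k)
    c(rep("first", k), rep("second", n_per_obs - k))))
  tibble::tibble(
    observer_id = obs, experiment = 1L, lighting = "photopic",
    trial_index = rep(seq_len(n_per_obs), length(correct_per_obs)),
    ecc_first = 4, ecc_second = 4, fixation_pos = 0,
    type_first = "C", type_second = "D",
    side = "right", orientation = "vertical",
    instruction = "continuity", response_comparison = k,
    max_fixation_deviation = 0.5
  )
}

test_that("fixation deviations beyond 2 degrees invalidate a trial", {
  tr <- make_toy_trials(c(2))[1:3, ]
  tr$max_fixation_deviation <- c(2.5, 0, 2.0)  # strictly-greater-than rule
  flt <- filter_valid(tr)
  expect_equal(flt$n_rejected, 1L)
  expect_equal(flt$valid$max_fixation_deviation, c(0, 2.0))
  expect_error(filter_valid(tr[, setdiff(names(tr), "max_fixation_deviation")]),
               "neither")
  # a precomputed validity flag is honoured
  tr2 <- tr[, setdiff(names(tr), "max_fixation_deviation")]
  tr2$valid <- c(FALSE, TRUE, TRUE)
  expect_equal(filter_valid(tr2)$n_valid, 2L)
})

test_that("proportion correct averages per-observer proportions", {
  tr <- make_toy_trials(c(4, 2, 3))
  est <- proportion_correct(tr, suppressWarnings(bootstrap_config(500, seed = 1)))
  expect_equal(est$point, 0.75)  # mean of 1, 0.5, 0.75
  expect_equal(est$n_observers, 3L)
  expect_equal(est$n_trials, 12L)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
})

test_that("discontinuity-instructed responses are recoded before pooling", {
  tr <- make_toy_trials(c(4))
  tr$instruction <- "discontinuity"
  # with C first, the correct discontinuity response is "second"
  tr$response_comparison <- "second"
  est <- proportion_correct(tr, suppressWarnings(bootstrap_config(500, seed = 1)))
  expect_equal(est$point, 1)
})

test_that("observers are excluded by trial counts and control accuracy", {
  sched <- dplyr::bind_rows(build_schedule(1, 31, "scotopic"),
                            build_schedule(1, 31, "photopic"))
  cohort <- observer_cohort(3, observer_params(accuracy = 1, p_fill = 1))
  tr <- simulate_experiment(sched, cohort, master_seed = 41)

  grp <- normalize_condition(tr$ecc_first, tr$ecc_second,
                             tr$type_first, tr$type_second,
                             fixation_pos = tr$fixation_pos)
  key <- paste(tr$lighting, grp$grouped_ecc, grp$grouped_types)

  # obs01: 13 of the 24 trials of one grouped condition become invalid,
  # leaving 11 valid trials (< 12) -> excluded
  hit <- which(tr$observer_id == "obs01" &
                 key == "scotopic 0|4 CC")[1:13]
  tr$max_fixation_deviation[hit] <- 3
  tr$valid[hit] <- FALSE

  # obs02: exactly 75% correct in the photopic 4-deg same-eccentricity
  # condition -> excluded ("less or equal to 75%")
  same4 <- which(tr$observer_id == "obs02" & key == "photopic 4|4 CD+DC")
  flip <- same4[1:6]  # 6 of 24 wrong -> 18/24 = 75%
  target <- ifelse(tr$instruction[flip] == "continuity", "C", "D")
  # answer with the interval that does not hold the instructed target
  tr$response_comparison[flip] <- ifelse(tr$type_first[flip] == target,
                                         "second", "first")

  flt <- filter_valid(tr)
  ex <- apply_exclusions(flt$valid, 1)
  expect_setequal(ex$excluded$observer_id, c("obs01", "obs02"))
  expect_equal(ex$retained, "obs03")
})

test_that("chance scotopic foveal accuracy never excludes an observer", {
  sched <- build_schedule(1, 33, "scotopic")
  # fully filled-in observer: same-eccentricity accuracy at 0 deg is at
  # chance, yet the 0-deg scotopic condition is exempt from the 75% rule
  tr <- simulate_experiment(sched, observer_cohort(2, filling_in_observer()),
                            master_seed = 43)
  ex <- apply_exclusions(tr, 1)
  expect_equal(nrow(ex$excluded), 0L)
  pc <- proportion_correct(ex$trials,
                           suppressWarnings(bootstrap_config(500, seed = 2)))
  p0 <- pc$point[pc$ecc == 0]
  expect_lt(abs(p0 - 0.5), 4 * sqrt(0.25 / 48))
})

test_that("validity filtering and exclusions commute with prefiltering", {
  sched <- build_schedule(1, 35, "scotopic")
  tr <- simulate_experiment(sched,
                            observer_cohort(4, foveal_trust_observer()),
                            master_seed = 45)
  once <- apply_exclusions(filter_valid(tr)$valid, 1)
  twice <- apply_exclusions(filter_valid(filter_valid(tr)$valid)$valid, 1)
  expect_identical(once$retained, twice$retained)
  expect_identical(once$trials, twice$trials)
})

test_that("grouped proportions merge reversed sequences and sides", {
  sched <- build_schedule(1, 37, "scotopic")
  tr <- simulate_experiment(sched, observer_cohort(6, filling_in_observer()),
                            master_seed = 47)
  est <- proportion_less_ecc(apply_exclusions(tr, 1)$trials,
                             config = suppressWarnings(bootstrap_config(500, seed = 3)))
  expect_equal(nrow(est), 9L)  # 3 pairs x 3 type assignments
  expect_true(all(est$n_trials == 24 * 6))
  expect_true(all(est$point >= 0 & est$point <= 1))
  expect_true(all(est$ci_low <= est$point & est$point <= est$ci_high))
  # every choice of the less-eccentric stimulus gives exactly 1
  tr2 <- tr
  tr2$instruction <- "continuity"
  less_first <- abs(tr2$ecc_first) < abs(tr2$ecc_second)
  diff_ecc <- abs(tr2$ecc_first) != abs(tr2$ecc_second)
  # same-eccentricity control conditions keep veridical responses so the
  # accuracy exclusion rule stays satisfied
  tr2$response_comparison[diff_ecc] <- ifelse(less_first[diff_ecc],
                                              "first", "second")
  tr2$response_comparison[!diff_ecc] <-
    ifelse(tr2$type_first[!diff_ecc] == "C", "first", "second")
  est2 <- proportion_less_ecc(apply_exclusions(tr2, 1)$trials,
                              config = suppressWarnings(bootstrap_config(500, seed = 4)))
  expect_true(all(est2$point == 1))
})

test_that("the bias estimate matches the logistic reliability difference", {
  obs <- observer_params(accuracy = 1, p_fill = 1,
                         reliability = c(`0` = 0.9, `4` = 0, `8` = 0))
  sched <- build_schedule(1, 39, "scotopic")
  tr <- simulate_experiment(sched, observer_cohort(30, obs), master_seed = 49)
  est <- proportion_less_ecc(apply_exclusions(tr, 1)$trials,
                             config = suppressWarnings(bootstrap_config(500, seed = 5)))
  cc04 <- est[est$grouped_ecc == "0|4" & est$grouped_types == "CC", ]
  truth <- plogis(0.9)  # 0.711
  expect_lt(abs(cc04$point - truth),
            4 * sqrt(truth * (1 - truth) / cc04$n_trials))
})

test_that("selection metrics pool mixed-type sequences when averaged", {
  obs <- observer_params(accuracy = 1, p_fill = 1, type_pref = 1.0,
                         reliability = c(`0` = 0.6, `4` = 0.2, `8` = 0))
  sched <- build_schedule(2, 41, "scotopic")
  tr <- simulate_experiment(sched, observer_cohort(20, obs), master_seed = 51)
  kept <- apply_exclusions(tr, 2)$trials
  cfg <- suppressWarnings(bootstrap_config(500, seed = 6))
  plain <- proportion_less_ecc(kept, "selected", config = cfg)
  avg <- proportion_less_ecc(kept, "selected", sequence_averaged = TRUE,
                             config = cfg)
  expect_equal(nrow(plain), 9L)
  expect_equal(nrow(avg), 6L)  # CC + pooled CD+DC per pair
  pooled <- avg[avg$grouped_ecc == "0|4" & avg$grouped_types == "CD+DC", ]
  expect_equal(pooled$n_trials, 64 * 20)
  # pooling averages out the type preference (foveal stimuli are filled in,
  # so the oracle supplies the exact mixed-type expectation)
  truth <- (oracle_select_prob(obs, "scotopic", 0, 4, "C", "D") +
              oracle_select_prob(obs, "scotopic", 0, 4, "D", "C")) / 2
  expect_lt(abs(pooled$point - truth),
            4 * sqrt(truth * (1 - truth) / pooled$n_trials))
})

test_that("appearance analysis honours the minimum-trial rule", {
  obs <- observer_params(accuracy = 1, p_fill = 0.9, lapse = 0,
                         reliability = c(`0` = 2, `4` = 0, `8` = 0))
  sched <- build_schedule(2, 43, "scotopic")
  tr <- simulate_experiment(sched, observer_cohort(8, obs), master_seed = 53)
  kept <- apply_exclusions(tr, 2)$trials
  app <- proportion_appearance(kept,
                               config = suppressWarnings(bootstrap_config(500, seed = 7)))
  # per-observer cells below 14 trials never contribute
  expect_true(all(app$n_trials >= 14 * app$n_observers |
                    app$n_observers == 0))
  d0 <- app[app$selected_ecc == 0 & app$selected_type == "D", ]
  if (nrow(d0) == 1) {
    truth <- oracle_appearance_prob(obs, "scotopic", 0, "D")
    expect_lt(abs(d0$point - truth), 0.1)
  }
})

test_that("within-condition trial series are flat for stationary observers", {
  sched <- build_schedule(1, 45, "scotopic")
  tr <- simulate_experiment(sched,
                            observer_cohort(12, filling_in_observer()),
                            master_seed = 55)
  series <- trial_series(apply_exclusions(tr, 1)$trials, "chose_less")
  expect_equal(nrow(series), 24L)  # 24 trials per grouped diff-ecc condition
  fit <- trend_regression(series)
  expect_true(fit$slope_ci[1] <= 0 && 0 <= fit$slope_ci[2])
})
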