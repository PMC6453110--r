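# Closed-form expected proportions by enumeration over percept combinations.
# Deliberately independent of the package's decision functions: everything is
# computed from the observer-parameter fields alone, so these serve as
# oracles for the simulation and analysis paths.

oracle_percept_dist <- function(params, lighting, ecc, type) {
  if (lighting == "scotopic" && ecc == 0) {
    return(c(C = params$p_fill, D = 0, GAP = 1 - params$p_fill))
  }
  a <- params$accuracy[[lighting]][[as.character(ecc)]]
  if (type == "C") c(C = a, D = 1 - a, GAP = 0) else c(C = 1 - a, D = a, GAP = 0)
}

oracle_tie_logit_less <- function(params, e_less, e_more) {
  pair <- sprintf("%g|%g", e_less, e_more)
  b <- if (pair %in% names(params$tie_bias)) params$tie_bias[[pair]] else 0
  params$reliability[[as.character(e_less)]] -
    params$reliability[[as.character(e_more)]] + b
}

# P(less-eccentric stimulus reported continuous) in the comparison task.
oracle_cont_prob <- function(params, lighting, e_less, e_more, t_less, t_more) {
  dl <- oracle_percept_dist(params, lighting, e_less, t_less)
  dm <- oracle_percept_dist(params, lighting, e_more, t_more)
  p_tie <- plogis(oracle_tie_logit_less(params, e_less, e_more))
  p <- 0
  for (pl in names(dl)) for (pm in names(dm)) {
    w <- dl[[pl]] * dm[[pm]]
    if (w == 0) next
    v <- if (pl == "GAP" && pm == "GAP") 0.5
    else if (pl == "GAP") (if (pm == "C") 0 else 1)
    else if (pm == "GAP") (if (pl == "C") 1 else 0)
    else if (pl == "C" && pm != "C") 1
    else if (pm == "C" && pl != "C") 0
    else p_tie
    p <- p + w * v
  }
  (1 - params$lapse) * p + params$lapse / 2
}

# P(correct) in a same-eccentricity condition (one C and one D stimulus).
oracle_correct_same <- function(params, lighting, ecc) {
  dc <- oracle_percept_dist(params, lighting, ecc, "C")
  dd <- oracle_percept_dist(params, lighting, ecc, "D")
  p <- 0
  for (pc in names(dc)) for (pd in names(dd)) {
    w <- dc[[pc]] * dd[[pd]]
    if (w == 0) next
    v <- if (pc == "GAP" && pd == "GAP") 0.5
    else if (pc == "GAP") (if (pd == "C") 0 else 1)
    else if (pd == "GAP") (if (pc == "C") 1 else 0)
    else if (pc == "C" && pd == "D") 1
    else if (pc == "D" && pd == "C") 0
    else 0.5
    p <- p + w * v
  }
  (1 - params$lapse) * p + params$lapse / 2
}

# P(less-eccentric stimulus selected) in the selection task.
oracle_select_prob <- function(params, lighting, e_less, e_more,
                               t_less, t_more) {
  dl <- oracle_percept_dist(params, lighting, e_less, t_less)
  dm <- oracle_percept_dist(params, lighting, e_more, t_more)
  base <- oracle_tie_logit_less(params, e_less, e_more)
  p <- 0
  for (pl in names(dl)) for (pm in names(dm)) {
    w <- dl[[pl]] * dm[[pm]]
    if (w == 0) next
    v <- if (pl == "GAP" && pm == "GAP") 0.5
    else if (pl == "GAP") 0
    else if (pm == "GAP") 1
    else plogis(base + params$type_pref * ((pl == "C") - (pm == "C")))
    p <- p + w * v
  }
  (1 - params$lapse) * p + params$lapse / 2
}

# P(report "continuous") for a stimulus of a given type and eccentricity.
oracle_appearance_prob <- function(params, lighting, ecc, type) {
  d <- oracle_percept_dist(params, lighting, ecc, type)
  (1 - params$lapse) * d[["C"]] + params$lapse / 2
}

# Simulate one cohort session (both lightings optional) and return the
# validity-filtered trials of retained observers.
simulate_cohort_trials <- function(experiment, n_obs, params, lightings,
                                   master_seed) {
  sched <- dplyr::bind_rows(lapply(lightings, function(lt) {
    scotovis::build_schedule(experiment, seed = master_seed, lighting = lt)
  }))
  cohort <- scotovis::observer_cohort(n_obs, params)
  trials <- scotovis::simulate_experiment(sched, cohort,
                                          master_seed = master_seed)
  flt <- scotovis::filter_valid(trials)
  scotovis::apply_exclusions(flt$valid, experiment)$trials
}
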