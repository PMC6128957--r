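#' Configuration for the synthetic COPD cohort simulator
#'
#' Bundles every knob of the simulator: cohort size and trial length, the
#' population marginals patients are drawn from (calibrated to a moderate
#' COPD outpatient population: baseline 6-minute walk distance ~ N(356, 98) m
#' truncated above 150 m, FEV1 %predicted ~ N(58.6, 15.8), CAT ~ N(15.6, 7.8),
#' age ~ N(64, 8)), the latent patient-response parameters, and the additive
#' treatment effects injected into visit outcomes at V2 (week 6) and V3
#' (week 12).
#'
#' @param n_per_arm Patients per trial arm (default 28).
#' @param weeks Trial length in weeks (default 12).
#' @param seed Integer seed fixing every draw of [simulate_cohort()].
#' @param n_sites Number of recruiting hospitals (default 4).
#' @param effects Named list per arm, each a list with numeric vectors
#'   `cat` and `sixmwt` holding additive V2/V3 effects. Defaults give the
#'   intervention arms a CAT decrease already at V2 and a 6MWT gain at V3,
#'   and leave the control arm flat.
#' @param outcome_noise Residual SDs of the visit outcomes
#'   (`cat`, `sixmwt`).
#' @param patient Latent patient-response defaults: `borg_gain` (Borg units
#'   per unit relative intensity), `borg_noise_sd`, `desat_propensity`
#'   (SpO2 percentage points lost per unit relative intensity),
#'   `baseline_spo2`, `adherence_prob` (per-day probability of exercising),
#'   `training_rate` (fractional capacity gain per completed session),
#'   `dropout_hazard` (per-week probability, default ~20% over 12 weeks),
#'   `rest_hr` (bpm).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = 28, weeks = 12, seed = 1L, n_sites = 4,
                          effects = list(
                            "fixed" = list(cat = c(V2 = -3, V3 = -3),
                                           sixmwt = c(V2 = 25, V3 = 50)),
                            "fixed-interactive" = list(cat = c(V2 = -2, V3 = -4),
                                                       sixmwt = c(V2 = 25, V3 = 50)),
                            "control" = list(cat = c(V2 = 0, V3 = 0),
                                             sixmwt = c(V2 = 0, V3 = 0))
                          ),
                          outcome_noise = list(cat = 3, sixmwt = 30),
                          patient = list()) {
  if (n_per_arm < 1 || n_per_arm != round(n_per_arm)) {
    abort("`n_per_arm` must be a positive integer.")
  }
  if (weeks < 1 || weeks != round(weeks)) abort("`weeks` must be a positive integer.")
  patient_defaults <- list(
    borg_gain = 4.5, borg_noise_sd = 0.5, desat_propensity = 5,
    baseline_spo2 = 96, adherence_prob = 0.8, training_rate = 0.001,
    dropout_hazard = 0.0185, rest_hr = 75
  )
  patient <- utils::modifyList(patient_defaults, patient)
  if (patient$adherence_prob < 0 || patient$adherence_prob > 1 ||
      patient$dropout_hazard < 0 || patient$dropout_hazard > 1) {
    abort("Probabilities must lie in [0, 1].")
  }
  if (patient$baseline_spo2 > 100) abort("`baseline_spo2` must be <= 100.")
  structure(
    list(
      n_per_arm = as.integer(n_per_arm), weeks = as.integer(weeks),
      seed = as.integer(seed), n_sites = as.integer(n_sites),
      arms = c("fixed", "fixed-interactive", "control"),
      effects = effects, outcome_noise = outcome_noise, patient = patient,
      population = list(mwt_mean = 356, mwt_sd = 98, mwt_min = 150,
                        fev1_mean = 58.6, fev1_sd = 15.8,
                        cat_mean = 15.6, cat_sd = 7.8,
                        age_mean = 64, age_sd = 8,
                        male_prob = 0.82,
                        mmrc_probs = c(0.01, 0.39, 0.44, 0.14, 0.02))
    ),
    class = "cohort_config"
  )
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
  }
  x
}

#' Draw a synthetic patient roster with latent response parameters
#'
#' Draws `3 * n_per_arm` patients from the configured population marginals.
#' The latent sustainable walking speed (`capacity`, m/s) is the baseline
#' 6MWT distance divided by the 360 s test duration; per-patient Borg gain,
#' adherence and desaturation propensity are jittered around the configured
#' defaults. Draws use the current RNG state; seed it (or call via
#' [simulate_cohort()], which seeds from `config$seed`) for reproducibility.
#'
#' @param config A [cohort_config()].
#' @param n Number of patients; defaults to `3 * config$n_per_arm`.
#' @return A tibble with identifiers (`patient_id`, `site`), demographics and
#'   baseline measures (`age`, `sex`, `fev1_pct_pred`, `cat`, `mmrc`,
#'   `sixmwt_distance`), and latent simulator parameters (`capacity`,
#'   `borg_gain`, `borg_noise_sd`, `desat_propensity`, `baseline_spo2`,
#'   `adherence_prob`, `training_rate`, `dropout_hazard`, `rest_hr`).
#' @export
draw_patients <- function(config = cohort_config(), n = 3 * config$n_per_arm) {
  stopifnot(inherits(config, "cohort_config"))
  pop <- config$population
  pt <- config$patient
  mwt <- rnorm_trunc(n, pop$mwt_mean, pop$mwt_sd, lower = pop$mwt_min)
  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    site = sprintf("S%d", sample.int(config$n_sites, n, replace = TRUE)),
    age = round(rnorm_trunc(n, pop$age_mean, pop$age_sd, lower = 21)),
    sex = ifelse(runif(n) < pop$male_prob, "M", "F"),
    fev1_pct_pred = pmin(79.9, round(rnorm_trunc(n, pop$fev1_mean, pop$fev1_sd,
                                                 lower = 20, upper = 80), 1)),
    cat = pmin(40L, pmax(0L, as.integer(round(rnorm(n, pop$cat_mean, pop$cat_sd))))),
    mmrc = sample(0:4, n, replace = TRUE, prob = pop$mmrc_probs),
    sixmwt_distance = mwt,
    capacity = mwt / 360,
    borg_gain = pt$borg_gain * exp(rnorm(n, 0, 0.05)),
    borg_noise_sd = pt$borg_noise_sd,
    desat_propensity = pt$desat_propensity * exp(rnorm(n, 0, 0.2)),
    baseline_spo2 = pt$baseline_spo2,
    adherence_prob = pt$adherence_prob,
    training_rate = pt$training_rate,
    dropout_hazard = pt$dropout_hazard,
    rest_hr = pt$rest_hr
  )
}

#' Simulate one walking session for a synthetic patient
#'
#' The achieved speed is the prescribed speed capped by the patient's noisy
#' capacity; the reported modified Borg score is a linear response to
#' relative intensity (prescribed speed / capacity), `round(borg_gain *
#' relative_intensity + noise)` clamped to \[0, 10\]; SpO2 samples sit at
#' `baseline_spo2 - desat_propensity * relative_intensity` plus noise,
#' clamped to \[70, 100\]; heart rate rises with intensity around the
#' resting rate. Uses the current RNG state.
#'
#' @param patient One roster row (list or one-row data frame) as produced by
#'   [draw_patients()].
#' @param prescribed_speed Prescribed walking speed, m/s (> 0).
#' @param duration Session duration in seconds (default 1800).
#' @param session_date Calendar date of the session.
#' @param sample_interval Telemetry sampling interval in seconds (default 30).
#' @return A one-row tibble: `patient_id`, `session_date`, `distance`,
#'   `duration`, `borg`, and a `samples` list-column holding a tibble of
#'   (`elapsed_seconds`, `spo2`, `heart_rate`).
#' @export
simulate_session <- function(patient, prescribed_speed, duration = 1800,
                             session_date = Sys.Date(), sample_interval = 30) {
  if (!is.numeric(prescribed_speed) || length(prescribed_speed) != 1 ||
      !is.finite(prescribed_speed) || prescribed_speed <= 0) {
    abort("`prescribed_speed` must be a single positive number.")
  }
  if (duration <= 0) abort("`duration` must be positive.")
  p <- as.list(patient)
  rel <- prescribed_speed / p$capacity
  achieved <- min(prescribed_speed, p$capacity * (1 + rnorm(1, 0, 0.05)))
  achieved <- max(achieved, 0.1)
  borg <- min(10, max(0, round(p$borg_gain * rel + rnorm(1, 0, p$borg_noise_sd))))
  t <- seq(sample_interval, duration, by = sample_interval)
  spo2 <- pmin(100, pmax(70, round(
    p$baseline_spo2 - p$desat_propensity * rel + rnorm(length(t), 0, 0.7)
  )))
  hr <- pmax(40, round(p$rest_hr + 40 * rel + rnorm(length(t), 0, 3)))
  tibble::tibble(
    patient_id = p$patient_id %||% NA_character_,
    session_date = as.Date(session_date),
    distance = achieved * duration,
    duration = duration,
    borg = borg,
    samples = list(tibble::tibble(elapsed_seconds = t, spo2 = spo2,
                                  heart_rate = hr))
  )
}

# noiseless 6MWT at the patient's current capacity: constant splits
sim_6mwt <- function(capacity) sixmwt_result(split_speeds = rep(capacity, 6))

#' Simulate a patient's full trial trajectory on one arm
#'
#' Walks a synthetic patient through the trial day by day: weekly dropout
#' draws, daily adherence draws, regimen selection by [schedule_arm()]
#' (fixed arm throughout; fixed then interactive from week 7 on the
#' fixed-interactive arm; nothing on control), session simulation with
#' [simulate_session()], and regimen-state updates through [update_fixed()] /
#' [update_interactive()], including the 6MWT at the start of the interactive
#' phase and top-level re-tests. Capacity grows by `training_rate` per
#' completed session. Visit outcomes at weeks 0/6/12 are the baseline scores
#' plus the configured arm effects plus Gaussian noise (missing after
#' dropout). Uses the current RNG state; see [simulate_cohort()] for seeding.
#'
#' @param patient One roster row from [draw_patients()].
#' @param arm `"fixed"`, `"fixed-interactive"` or `"control"`.
#' @param config A [cohort_config()].
#' @param start_date First trial day (default 2024-01-01).
#' @param fixed_table,interactive_table Regimen level tables.
#' @return A list: `sessions` tibble, `history` tibble of regimen events,
#'   `outcomes` tibble (one row per visit V1/V2/V3), final `state` (or NULL
#'   on the control arm), and `dropout_week` (NA if completed).
#' @export
simulate_trajectory <- function(patient, arm, config = cohort_config(),
                                start_date = as.Date("2024-01-01"),
                                fixed_table = fixed_level_table(),
                                interactive_table = interactive_level_table()) {
  arm <- match.arg(arm, config$arms)
  p <- as.list(patient)
  capacity <- p$capacity
  state <- NULL
  sessions <- list()
  dropout_week <- NA_integer_
  n_days <- config$weeks * 7L
  for (day in seq_len(n_days)) {
    week <- ((day - 1L) %/% 7L) + 1L
    if ((day - 1L) %% 7L == 0L && week > 1L &&
        runif(1) < p$dropout_hazard) {
      dropout_week <- week
      break
    }
    kind <- schedule_arm(arm, week, n_weeks = config$weeks)
    if (is.na(kind)) next
    if (kind == "fixed" && (is.null(state) || state$regimen != "fixed")) {
      state <- init_fixed(fixed_table)
    }
    if (kind == "interactive" &&
        (is.null(state) || state$regimen != "interactive")) {
      state <- init_interactive(sim_6mwt(capacity), interactive_table)
    }
    if (runif(1) >= p$adherence_prob) next
    date <- start_date + day - 1L
    p$capacity <- capacity
    if (kind == "fixed") {
      speed <- 0.85 * capacity
      target <- current_target(state)
      dur <- min(target / speed * 1.02, 7200)
      ses <- simulate_session(p, speed, duration = dur, session_date = date)
      state <- update_fixed(state, ses)
    } else {
      if (isTRUE(state$retest_pending)) {
        state <- apply_retest(state, sim_6mwt(capacity), date = date)
      }
      speed <- current_target(state)
      ses <- simulate_session(
        p, speed, duration = interactive_table$session_minutes * 60,
        session_date = date
      )
      state <- update_interactive(state, ses$borg, date = date)
    }
    sessions[[length(sessions) + 1L]] <- ses
    capacity <- capacity * (1 + p$training_rate)
  }
  eff <- config$effects[[arm]]
  noise <- config$outcome_noise
  visit_week <- c(V1 = 0, V2 = 6, V3 = 12)
  outcomes <- purrr::map_dfr(names(visit_week), function(v) {
    missing <- !is.na(dropout_week) && visit_week[[v]] >= dropout_week
    if (missing) {
      return(tibble::tibble(patient_id = p$patient_id, visit = v,
                            cat = NA_integer_, mmrc = NA_integer_,
                            sixmwt_distance = NA_real_))
    }
    if (v == "V1") {
      cat_v <- p$cat
      mwt_v <- p$sixmwt_distance
    } else {
      cat_v <- min(40L, max(0L, as.integer(round(
        p$cat + eff$cat[[v]] + rnorm(1, 0, noise$cat)
      ))))
      mwt_v <- max(0, p$sixmwt_distance + eff$sixmwt[[v]] +
                     rnorm(1, 0, noise$sixmwt))
    }
    tibble::tibble(patient_id = p$patient_id, visit = v,
                   cat = as.integer(cat_v), mmrc = as.integer(p$mmrc),
                   sixmwt_distance = as.numeric(mwt_v))
  })
  list(
    sessions = if (length(sessions)) dplyr::bind_rows(sessions) else
      tibble::tibble(patient_id = character(), session_date = as.Date(character()),
                     distance = numeric(), duration = numeric(),
                     borg = numeric(), samples = list()),
    history = if (is.null(state)) empty_history() else state$history,
    outcomes = outcomes,
    state = state,
    dropout_week = dropout_week
  )
}

#' Simulate a full synthetic trial cohort
#'
#' Seeds the RNG from `config$seed`, draws a roster with [draw_patients()],
#' assigns arms 1:1:1 with stratified permuted-block [randomize()]
#' (stratified by site, FEV1 %predicted and CAT), and simulates every
#' patient's trajectory. Identical configs (including seed) give
#' byte-identical output.
#'
#' @param config A [cohort_config()].
#' @param start_date First trial day.
#' @return A list of tibbles: `roster`, `assignments`, `sessions` (with the
#'   per-session `samples` list-column), `outcomes`, `history` (regimen
#'   events per patient), plus `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            start_date = as.Date("2024-01-01")) {
  stopifnot(inherits(config, "cohort_config"))
  withr::local_seed(config$seed)
  roster <- draw_patients(config)
  assignments <- randomize(roster, arms = config$arms, seed = NULL)
  traj <- purrr::map(seq_len(nrow(roster)), function(i) {
    simulate_trajectory(roster[i, ], assignments$arm[i], config,
                        start_date = start_date)
  })
  list(
    roster = roster,
    assignments = assignments,
    sessions = purrr::map_dfr(traj, "sessions"),
    outcomes = purrr::map_dfr(traj, "outcomes"),
    history = purrr::map_dfr(seq_along(traj), function(i) {
      dplyr::mutate(traj[[i]]$history, patient_id = roster$patient_id[i],
                    .before = 1)
    }),
    dropout_week = purrr::map_int(traj, "dropout_week"),
    config = config
  )
}
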