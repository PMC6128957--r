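test_that("identical configs give identical cohorts", {
  cfg <- cohort_config(n_per_arm = 4, weeks = 3, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$roster, b$roster)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$history, b$history)
  # a different seed gives a different cohort
  c2 <- simulate_cohort(cohort_config(n_per_arm = 4, weeks = 3, seed = 6))
  expect_false(identical(a$roster, c2$roster))
})

test_that("baseline 6MWT distances are truncated above 150 m", {
  withr::with_seed(2, {
    pts <- draw_patients(cohort_config(), n = 500)
    expect_true(all(pts$sixmwt_distance > 150))
    expect_true(all(pts$capacity > 0))
    expect_true(all(pts$fev1_pct_pred < 80))
    expect_true(all(pts$age > 20))
  })
})

test_that("the Borg response model hits both extremes without noise", {
  p <- quiet_patient(capacity = 1, borg_gain = 4.5)
  withr::with_seed(1, {
    easy <- simulate_session(p, prescribed_speed = 0.3)
    expect_lte(easy$borg, 3)
    hard <- simulate_session(p, prescribed_speed = 1.8)
    expect_gte(hard$borg, 7)
    expect_error(simulate_session(p, prescribed_speed = 0), "positive")
  })
})

test_that("a high desaturation propensity produces sub-90% samples and alerts", {
  p <- quiet_patient(capacity = 1, desat = 15)
  withr::with_seed(3, {
    ses <- simulate_session(p, prescribed_speed = 0.9)
    smp <- ses$samples[[1]]
    # direct evaluation of the SpO2 model: 96 - 15 * 0.9 = 82.5, far below 90
    expect_lt(min(smp$spo2), 90)
    expect_true(all(smp$spo2 >= 70 & smp$spo2 <= 100))
    expect_gt(nrow(monitor_spo2(smp)), 0)
  })
})

test_that("zero adherence yields an empty session log and intact outcomes", {
  p <- quiet_patient(adherence = 0)
  withr::with_seed(4, {
    tr <- simulate_trajectory(p, "fixed", cohort_config(weeks = 4))
  })
  expect_equal(nrow(tr$sessions), 0L)
  expect_equal(tr$state$level, 1L)
  expect_equal(nrow(tr$outcomes), 3L)
})

test_that("an always-qualifying fixed-arm patient levels up exactly every 14 days", {
  p <- quiet_patient(capacity = 3, adherence = 1)
  withr::with_seed(5, {
    tr <- simulate_trajectory(p, "fixed", cohort_config(weeks = 12))
  })
  ups <- tr$history[tr$history$event == "level_up", ]
  expect_equal(nrow(ups), 5L) # 600 -> 3600 over 70 qualifying days
  expect_equal(as.numeric(diff(ups$date)), rep(14, 4))
  expect_equal(tr$state$level, 6L)
})

test_that("a high-capacity interactive patient reaches the top level and re-tests", {
  # low Borg gain keeps every session at Borg <= 3, so the level climbs to 12
  p <- quiet_patient(capacity = 1.2, borg_gain = 2, adherence = 1)
  withr::with_seed(6, {
    tr <- simulate_trajectory(p, "fixed-interactive", cohort_config(weeks = 12))
  })
  expect_true("retest_scheduled" %in% tr$history$event)
  expect_true("retest_applied" %in% tr$history$event)
  # engine replay oracle over the recorded Borg stream of the interactive phase
  borg <- tr$sessions$borg[tr$sessions$session_date >= as.Date("2024-01-01") + 42]
  orc <- oracle_interactive_replay(borg)
  expect_true(orc$retest_pending)
})

test_that("dropout truncates the session log and blanks later visits", {
  p <- quiet_patient(adherence = 1)
  p$dropout_hazard <- 1 # drops at the start of week 2
  withr::with_seed(8, {
    tr <- simulate_trajectory(p, "fixed", cohort_config(weeks = 12))
  })
  expect_equal(tr$dropout_week, 2L)
  expect_lte(max(as.Date(tr$sessions$session_date)), as.Date("2024-01-07"))
  oc <- tr$outcomes
  expect_false(is.na(oc$cat[oc$visit == "V1"]))
  expect_true(all(is.na(oc$cat[oc$visit != "V1"])))
})

test_that("regressing simulated Borg on relative intensity recovers the gain", {
  p <- quiet_patient(capacity = 1, borg_gain = 4.5)
  p$borg_noise_sd <- 0.5
  withr::with_seed(9, {
    rel <- runif(1000, 0.3, 1.5)
    borg <- vapply(rel, function(r) simulate_session(p, r)$borg, numeric(1))
  })
  slope <- coef(lm(borg ~ rel))[["rel"]]
  expect_lt(abs(slope - 4.5) / 4.5, 0.10)
})

test_that("the noise-free feedback loop settles between the Borg thresholds", {
  for (gain in c(4, 4.5, 5, 6)) {
    capacity <- 1
    tab <- interactive_level_table()
    st <- init_interactive(sixmwt_result(split_speeds = rep(capacity, 6)), tab)
    levels <- integer(80)
    for (i in 1:80) {
      borg <- min(10, max(0, round(gain * current_target(st) / capacity)))
      if (st$retest_pending) st <- apply_retest(st, sixmwt_result(rep(capacity, 6)))
      st <- update_interactive(st, borg)
      levels[i] <- st$level
    }
    final_borg <- min(10, max(0, round(gain * current_target(st) / capacity)))
    expect_gt(final_borg, tab$borg_up_threshold)
    expect_lt(final_borg, tab$borg_down_threshold)
    # once settled the level is constant
    expect_equal(length(unique(tail(levels, 10))), 1L)
  }
})

test_that("outcome effects are injected per arm at V2/V3", {
  cfg <- cohort_config(
    n_per_arm = 20, weeks = 12, seed = 31,
    effects = list(
      "fixed" = list(cat = c(V2 = -8, V3 = -8), sixmwt = c(V2 = 0, V3 = 0)),
      "fixed-interactive" = list(cat = c(V2 = -8, V3 = -8), sixmwt = c(V2 = 0, V3 = 0)),
      "control" = list(cat = c(V2 = 0, V3 = 0), sixmwt = c(V2 = 0, V3 = 0))
    ),
    patient = list(dropout_hazard = 0, adherence_prob = 0)
  )
  co <- simulate_cohort(cfg)
  oc <- dplyr::left_join(co$outcomes, co$assignments, by = "patient_id") |>
    tidyr::pivot_wider(id_cols = c("patient_id", "arm"), names_from = "visit",
                       values_from = "cat")
  chg <- oc |>
    dplyr::group_by(arm) |>
    dplyr::summarise(d2 = mean(V2 - V1), .groups = "drop")
  expect_lt(chg$d2[chg$arm == "fixed"], -4)
  expect_gt(chg$d2[chg$arm == "control"], -2)
})
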