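`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles, written directly from the regimen rules
# and classical formulas; they never call the engine internals they check.

# Interactive regimen: replay a Borg sequence naively. Returns the level
# after each score, the streak counters, and whether a re-test came due
# (after which remaining scores are ignored, as the app blocks updates).
oracle_interactive_replay <- function(borg_seq, n_levels = 12,
                                      up = 3, down = 7, streak = 3,
                                      start_level = 1) {
  level <- start_level
  lo <- 0
  hi <- 0
  pending <- FALSE
  levels <- integer(0)
  for (b in borg_seq) {
    if (pending) break
    if (b <= up) {
      lo <- lo + 1
      hi <- 0
    } else if (b >= down) {
      hi <- hi + 1
      lo <- 0
    } else {
      lo <- 0
      hi <- 0
    }
    if (lo == streak) {
      if (level < n_levels) level <- level + 1
      if (level == n_levels) pending <- TRUE
      lo <- 0
      hi <- 0
    } else if (hi == streak) {
      if (level > 1) level <- level - 1
      lo <- 0
      hi <- 0
    }
    levels <- c(levels, level)
  }
  list(levels = levels, final_level = level, low = lo, high = hi,
       retest_pending = pending)
}

# Fixed regimen: replay daily distance totals naively.
oracle_fixed_replay <- function(daily_totals,
                                distances = c(600, 1200, 1800, 2400, 3000, 3600),
                                required = 14) {
  level <- 1
  ach <- 0
  for (tot in daily_totals) {
    if (tot >= distances[level]) {
      ach <- ach + 1
      if (ach == required) {
        ach <- 0
        if (level < length(distances)) level <- level + 1
      }
    }
  }
  list(level = level, achievements = ach)
}

# Feed an engine state a Borg sequence, stopping at a pending re-test the
# way the oracle does.
engine_interactive_replay <- function(borg_seq, table = interactive_level_table()) {
  st <- init_interactive(sixmwt_result(split_speeds = rep(1.25, 6)), table)
  for (b in borg_seq) {
    if (isTRUE(st$retest_pending)) break
    st <- update_interactive(st, b)
  }
  st
}

# SpO2 alerting: literal restatement of the contract (first sample below
# threshold alerts; repeats within one below-threshold run are suppressed for
# `debounce` seconds; recovery re-arms).
oracle_spo2_alerts <- function(t, s, threshold = 90, debounce = 30) {
  alert_at <- numeric(0)
  below_run <- FALSE
  for (i in seq_along(t)) {
    if (s[i] < threshold) {
      armed <- !below_run ||
        (length(alert_at) > 0 && t[i] - alert_at[length(alert_at)] >= debounce)
      if (armed) alert_at <- c(alert_at, t[i])
      below_run <- TRUE
    } else {
      below_run <- FALSE
    }
  }
  alert_at
}

# One-way ANOVA from first principles.
oracle_oneway_F <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_between <- 0
  ss_within <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  df1 <- length(unique(groups)) - 1
  df2 <- length(values) - length(unique(groups))
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Small simulated null outcome set for RM-ANOVA calibration: three identical
# arms, subject random effects, no visit or arm effect.
sim_null_outcomes <- function(n_per_arm = 10) {
  arms <- c("fixed", "fixed-interactive", "control")
  purrr::map_dfr(seq_along(arms), function(a) {
    purrr::map_dfr(seq_len(n_per_arm), function(i) {
      subj <- rnorm(1, 15, 6)
      tibble::tibble(
        patient_id = sprintf("%s-%02d", arms[a], i),
        arm = arms[a],
        visit = c("V1", "V2", "V3"),
        cat = subj + rnorm(3, 0, 3)
      )
    })
  })
}

# Roster stub for randomization tests.
make_roster <- function(n, n_sites = 4, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    site = sprintf("S%d", sample.int(n_sites, n, replace = TRUE)),
    fev1_pct_pred = runif(n, 25, 79),
    cat = sample(0:40, n, replace = TRUE)
  ))
}

# A zero-noise patient for deterministic simulator checks.
quiet_patient <- function(capacity = 1, borg_gain = 4.5, desat = 5,
                          adherence = 1, dropout = 0, training = 0) {
  tibble::tibble(
    patient_id = "PT", site = "S1", age = 64, sex = "M",
    fev1_pct_pred = 58, cat = 15, mmrc = 2,
    sixmwt_distance = capacity * 360, capacity = capacity,
    borg_gain = borg_gain, borg_noise_sd = 0,
    desat_propensity = desat, baseline_spo2 = 96,
    adherence_prob = adherence, training_rate = training,
    dropout_hazard = dropout, rest_hr = 75
  )
}
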