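#' @rdname init_fixed
#' @export
print.regimen_state <- function(x, ...) {
  cat("<regimen_state> ", x$regimen, " regimen, level ", x$level, sep = "")
  if (x$regimen == "fixed") {
    cat(" (target ", current_target(x), " m, ", x$achievements, "/",
        x$table$achievements_required, " qualifying days)", sep = "")
  } else {
    cat(" (prescribed ", round(current_target(x), 3), " m/s",
        if (x$retest_pending) ", 6MWT re-test pending" else "", ")", sep = "")
  }
  cat("; ", nrow(x$history), " logged events\n", sep = "")
  invisible(x)
}

empty_history <- function() {
  tibble::tibble(
    step = integer(), date = as.Date(character()),
    event = character(), level = integer(), detail = character()
  )
}

log_event <- function(state, event, detail = "", date = as.Date(NA)) {
  state$history <- dplyr::bind_rows(
    state$history,
    tibble::tibble(
      step = nrow(state$history) + 1L, date = as.Date(date),
      event = event, level = as.integer(state$level), detail = detail
    )
  )
  state
}

#' Initialize the fixed walking regimen
#'
#' Starts a patient at level 1 of the fixed-distance regimen, i.e. a daily
#' target of the first table entry (600 m with the default table).
#'
#' @param table A [fixed_level_table()].
#' @return A `regimen_state` with fields `regimen`, `level`, `achievements`,
#'   the level table, and an append-only `history` tibble of events.
#' @export
#' @examples
#' st <- init_fixed(fixed_level_table())
#' current_target(st) # 600 m
init_fixed <- function(table = fixed_level_table()) {
  if (!inherits(table, "fixed_level_table")) {
    abort("`table` must be a fixed_level_table().")
  }
  state <- structure(
    list(
      regimen = "fixed", level = 1L, achievements = 0L,
      table = table, last_date = as.Date(NA), history = empty_history()
    ),
    class = "regimen_state"
  )
  log_event(state, "init",
            detail = paste0("target ", table$distances[1], " m"))
}

#' Current prescription of a regimen state
#'
#' For a fixed-regimen state, the daily distance target in meters; for an
#' interactive-regimen state, the prescribed walking speed in m/s
#' (base speed times the level's speed fraction).
#'
#' @param state A `regimen_state`.
#' @return A single number.
#' @export
current_target <- function(state) {
  stopifnot(inherits(state, "regimen_state"))
  if (state$regimen == "fixed") {
    state$table$distances[state$level]
  } else {
    state$base_speed * state$table$speed_fractions[state$level]
  }
}

#' Advance the fixed regimen by one day of sessions
#'
#' All walking sessions of one calendar day are aggregated; if their summed
#' distance reaches the current level's target, one qualifying day
#' ("achievement") is credited — at most one per date. After
#' `achievements_required` qualifying days (14 by default, not necessarily
#' consecutive) the level increases by one, capped at the top level, and the
#' achievement counter resets.
#'
#' @param state A fixed `regimen_state`.
#' @param sessions Data frame of that day's sessions with columns
#'   `session_date` (one distinct date) and `distance` (meters, >= 0).
#' @return The updated `regimen_state`. Days must be fed in strictly
#'   increasing date order so each date is credited at most once.
#' @export
#' @examples
#' st <- init_fixed(fixed_level_table())
#' day <- tibble::tibble(session_date = as.Date("2024-01-01"),
#'                       distance = c(300, 320))
#' update_fixed(st, day)$achievements # 1: 620 m >= 600 m target
update_fixed <- function(state, sessions) {
  stopifnot(inherits(state, "regimen_state"))
  if (state$regimen != "fixed") abort("`state` is not on the fixed regimen.")
  if (!is.data.frame(sessions) ||
      !all(c("session_date", "distance") %in% names(sessions))) {
    abort("`sessions` needs columns `session_date` and `distance`.")
  }
  if (nrow(sessions) == 0) return(state)
  dates <- as.Date(sessions$session_date)
  if (anyNA(dates)) abort("`session_date` contains unparseable dates.")
  if (length(unique(dates)) != 1) {
    abort("All sessions passed to update_fixed() must share one calendar date.")
  }
  if (any(sessions$distance < 0)) abort("`distance` must be >= 0.")
  day <- dates[1]
  if (!is.na(state$last_date) && day <= state$last_date) {
    abort("Days must be applied in strictly increasing date order.")
  }
  state$last_date <- day
  total <- sum(sessions$distance)
  target <- current_target(state)
  if (total >= target) {
    state$achievements <- state$achievements + 1L
    state <- log_event(state, "achievement", date = day,
                       detail = paste0(total, " m >= ", target, " m (",
                                       state$achievements, "/",
                                       state$table$achievements_required, ")"))
    if (state$achievements >= state$table$achievements_required) {
      state$achievements <- 0L
      top <- length(state$table$distances)
      if (state$level < top) {
        state$level <- state$level + 1L
        state <- log_event(state, "level_up", date = day,
                           detail = paste0("new target ",
                                           current_target(state), " m"))
      } else {
        state <- log_event(state, "level_cap", date = day,
                           detail = "already at top level")
      }
    }
  }
  state
}

#' Initialize the interactive walking regimen from a 6MWT
#'
#' Sets the base walking speed to 80% of the maximum walking speed recorded
#' in a 6-minute walk test and starts the patient at level 1, so the
#' prescribed speed is `0.8 * max_speed * speed_fractions[1]`.
#'
#' @param result A [sixmwt_result()].
#' @param table An [interactive_level_table()].
#' @return A `regimen_state` for the interactive regimen.
#' @export
#' @examples
#' res <- sixmwt_result(split_speeds = rep(1.5, 6))
#' st <- init_interactive(res)
#' st$base_speed # 1.2 m/s
init_interactive <- function(result, table = interactive_level_table()) {
  if (!inherits(result, "sixmwt_result")) {
    abort("`result` must be a sixmwt_result().")
  }
  if (!inherits(table, "interactive_level_table")) {
    abort("`table` must be an interactive_level_table().")
  }
  if (!is.finite(result$max_speed) || result$max_speed <= 0) {
    abort("6MWT maximum walking speed must be positive.")
  }
  state <- structure(
    list(
      regimen = "interactive", level = 1L,
      base_speed = 0.80 * result$max_speed,
      low_borg_streak = 0L, high_borg_streak = 0L,
      retest_pending = FALSE, table = table, history = empty_history()
    ),
    class = "regimen_state"
  )
  log_event(state, "init",
            detail = sprintf("base speed %.3f m/s (80%% of 6MWT max %.3f m/s)",
                             state$base_speed, result$max_speed))
}

#' Advance the interactive regimen by one session's Borg score
#'
#' Applies the modified Borg (0-10) feedback rule: a score at or below the
#' up-threshold (3) extends the low-Borg streak; at or above the
#' down-threshold (7) extends the high-Borg streak; strictly between the
#' thresholds resets both. A completed streak of `streak_length` (3) moves
#' the level up or down by one (floor at level 1) and clears both streaks.
#' Reaching the top level (12) flags a pending 6MWT re-test; further updates
#' are refused until [apply_retest()] is called.
#'
#' @param state An interactive `regimen_state`.
#' @param borg Modified Borg score on the grid \{0, 0.5, ..., 10\}.
#' @param date Optional session date recorded with logged events.
#' @return The updated `regimen_state`.
#' @export
#' @examples
#' st <- init_interactive(sixmwt_result(split_speeds = rep(1.2, 6)))
#' for (b in c(2, 2, 2)) st <- update_interactive(st, b)
#' st$level # 2
update_interactive <- function(state, borg, date = as.Date(NA)) {
  stopifnot(inherits(state, "regimen_state"))
  if (state$regimen != "interactive") {
    abort("`state` is not on the interactive regimen.")
  }
  if (isTRUE(state$retest_pending)) {
    abort("A 6MWT re-test is pending; call apply_retest() before further sessions.")
  }
  if (!is_borg(borg)) {
    abort("`borg` must be a modified Borg score on {0, 0.5, ..., 10}.")
  }
  tab <- state$table
  if (borg <= tab$borg_up_threshold) {
    state$low_borg_streak <- state$low_borg_streak + 1L
    state$high_borg_streak <- 0L
  } else if (borg >= tab$borg_down_threshold) {
    state$high_borg_streak <- state$high_borg_streak + 1L
    state$low_borg_streak <- 0L
  } else {
    state$low_borg_streak <- 0L
    state$high_borg_streak <- 0L
  }
  if (state$low_borg_streak >= tab$streak_length) {
    state$low_borg_streak <- 0L
    state$high_borg_streak <- 0L
    if (state$level < tab$n_levels) {
      state$level <- state$level + 1L
      state <- log_event(state, "level_up", date = date,
                         detail = sprintf("Borg <= %g on %d consecutive sessions",
                                          tab$borg_up_threshold, tab$streak_length))
      if (state$level == tab$n_levels) {
        state$retest_pending <- TRUE
        state <- log_event(state, "retest_scheduled", date = date,
                           detail = "top level reached; 6MWT re-test required")
      }
    }
  } else if (state$high_borg_streak >= tab$streak_length) {
    state$low_borg_streak <- 0L
    state$high_borg_streak <- 0L
    if (state$level > 1L) {
      state$level <- state$level - 1L
      state <- log_event(state, "level_down", date = date,
                         detail = sprintf("Borg >= %g on %d consecutive sessions",
                                          tab$borg_down_threshold, tab$streak_length))
    }
  }
  state
}

#' Re-base the interactive regimen after a top-level 6MWT re-test
#'
#' When the top interactive level has been reached the patient repeats the
#' 6-minute walk test; the base speed is recomputed as 80% of the new maximum
#' walking speed and the level is reset to the table's `reset_level`
#' (7 by default). Streak counters and the pending-re-test flag are cleared.
#'
#' @param state An interactive `regimen_state` with `retest_pending = TRUE`.
#' @param result The new [sixmwt_result()].
#' @param date Optional date recorded with the logged event.
#' @return The updated `regimen_state`.
#' @export
apply_retest <- function(state, result, date = as.Date(NA)) {
  stopifnot(inherits(state, "regimen_state"))
  if (state$regimen != "interactive") {
    abort("`state` is not on the interactive regimen.")
  }
  if (!isTRUE(state$retest_pending)) {
    abort("No 6MWT re-test is pending for this state.")
  }
  if (!inherits(result, "sixmwt_result")) {
    abort("`result` must be a sixmwt_result().")
  }
  if (!is.finite(result$max_speed) || result$max_speed <= 0) {
    abort("6MWT maximum walking speed must be positive.")
  }
  state$base_speed <- 0.80 * result$max_speed
  state$level <- state$table$reset_level
  state$low_borg_streak <- 0L
  state$high_borg_streak <- 0L
  state$retest_pending <- FALSE
  log_event(state, "retest_applied", date = date,
            detail = sprintf("re-based to %.3f m/s, level reset to %d",
                             state$base_speed, state$level))
}

#' Metronome cadence guiding a prescribed walking speed
#'
#' The apps pace the patient with a metronome; the beat frequency is the
#' prescribed speed divided by the stride length, in steps per minute.
#'
#' @param prescribed_speed Walking speed in m/s (> 0).
#' @param stride_length Stride length in meters (> 0, default 0.70).
#' @return Cadence in steps per minute.
#' @export
#' @examples
#' metronome_cadence(1.2, 0.72) # 100 steps/min
metronome_cadence <- function(prescribed_speed, stride_length = 0.70) {
  if (!is.numeric(prescribed_speed) || any(!is.finite(prescribed_speed)) ||
      any(prescribed_speed <= 0)) {
    abort("`prescribed_speed` must be positive.")
  }
  if (!is.numeric(stride_length) || any(!is.finite(stride_length)) ||
      any(stride_length <= 0)) {
    abort("`stride_length` must be positive.")
  }
  prescribed_speed / stride_length * 60
}

#' Active regimen for a trial arm at a given week
#'
#' The fixed arm walks the fixed regimen for all 12 weeks; the
#' fixed-interactive arm walks the fixed regimen for weeks 1-6 and the
#' interactive regimen for weeks 7-12; the control arm has no prescribed
#' regimen.
#'
#' @param arm One of `"fixed"`, `"fixed-interactive"`, `"control"`.
#' @param week Trial week, integer in 1..12.
#' @param switch_week First week of the interactive phase on the
#'   fixed-interactive arm (default 7).
#' @param n_weeks Trial length in weeks (default 12).
#' @return `"fixed"`, `"interactive"`, or `NA_character_` for the control arm.
#' @export
#' @examples
#' schedule_arm("fixed-interactive", 7) # "interactive"
schedule_arm <- function(arm, week, switch_week = 7, n_weeks = 12) {
  arm <- match.arg(arm, c("fixed", "fixed-interactive", "control"))
  if (!is.numeric(week) || length(week) != 1 || is.na(week) ||
      week != round(week) || week < 1 || week > n_weeks) {
    abort(sprintf("`week` must be an integer in [1, %d].", n_weeks))
  }
  switch(arm,
    "fixed" = "fixed",
    "fixed-interactive" = if (week < switch_week) "fixed" else "interactive",
    "control" = NA_character_
  )
}

#' Replay a session log through a regimen state machine
#'
#' Convenience driver: groups a session log by calendar date, feeds each day
#' to [update_fixed()] (fixed regimen) or each session's Borg score to
#' [update_interactive()] (interactive regimen, re-tests applied with
#' `retest_result` when the top level is reached), and returns the full event
#' history.
#'
#' @param sessions Data frame of sessions with `session_date`, `distance`,
#'   and (for the interactive regimen) `borg`.
#' @param state Initial `regimen_state` from [init_fixed()] or
#'   [init_interactive()].
#' @param retest_result Optional function called with no arguments to obtain
#'   a [sixmwt_result()] whenever a re-test falls due; if `NULL`, replay
#'   stops updating at a pending re-test.
#' @return A list with the final `state` and its `history` tibble.
#' @export
run_regimen <- function(sessions, state, retest_result = NULL) {
  stopifnot(inherits(state, "regimen_state"))
  if (nrow(sessions) == 0) return(list(state = state, history = state$history))
  sessions <- dplyr::arrange(sessions, .data$session_date)
  if (state$regimen == "fixed") {
    for (day_df in split(sessions, as.Date(sessions$session_date))) {
      state <- update_fixed(state, day_df)
    }
  } else {
    for (i in seq_len(nrow(sessions))) {
      if (isTRUE(state$retest_pending)) {
        if (is.null(retest_result)) break
        state <- apply_retest(state, retest_result(),
                              date = as.Date(sessions$session_date[i]))
      }
      if (!is.na(sessions$borg[i])) {
        state <- update_interactive(state, sessions$borg[i],
                                    date = as.Date(sessions$session_date[i]))
      }
    }
  }
  list(state = state, history = state$history)
}
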