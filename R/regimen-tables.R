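#' Level table for the fixed walking regimen
#'
#' The fixed regimen prescribes a daily walking-distance target drawn from an
#' ordered table of levels. The defaults are the six clinical levels used by
#' the platform: 600, 1200, 1800, 2400, 3000 and 3600 m, with a level-up after
#' the target has been achieved on 14 (not necessarily consecutive) days.
#'
#' @param distances Numeric vector of strictly increasing level target
#'   distances in meters.
#' @param achievements_required Number of qualifying days (daily cumulative
#'   distance at or above the target) needed to advance one level.
#' @return An object of class `fixed_level_table`.
#' @seealso [init_fixed()], [update_fixed()]
#' @export
#' @examples
#' fixed_level_table()
fixed_level_table <- function(distances = c(600, 1200, 1800, 2400, 3000, 3600),
                              achievements_required = 14) {
  if (length(distances) < 1 || anyNA(distances)) {
    abort("`distances` must be a nonempty numeric vector without NA.")
  }
  if (any(distances <= 0) || any(diff(distances) <= 0)) {
    abort("`distances` must be positive and strictly increasing.")
  }
  if (length(achievements_required) != 1 || is.na(achievements_required) ||
      achievements_required < 1 || achievements_required != round(achievements_required)) {
    abort("`achievements_required` must be a single integer >= 1.")
  }
  structure(
    list(
      distances = as.numeric(distances),
      achievements_required = as.integer(achievements_required)
    ),
    class = "fixed_level_table"
  )
}

#' Level table for the interactive walking regimen
#'
#' The interactive regimen prescribes a walking speed rather than a distance.
#' Intensity is initialized from a 6-minute walk test (80% of the maximum
#' walking speed) and then stepped through `n_levels` levels under modified
#' Borg scale (0-10) feedback: a Borg score at or below `borg_up_threshold`
#' on `streak_length` consecutive sessions moves the level up by one; a score
#' at or above `borg_down_threshold` sustained over the same streak moves it
#' down by one. Reaching the top level schedules a 6MWT re-test, after which
#' intensity is re-based and the level resets to `reset_level`.
#'
#' The per-level speed multipliers are applied to the base speed; the default
#' table rises from 1.00 at level 1 by 0.02 per level to 1.22 at level 12,
#' with a fixed 30-minute session at every level.
#'
#' @param n_levels Number of levels (default 12).
#' @param speed_fractions Nondecreasing positive multipliers of the base
#'   speed, one per level.
#' @param session_minutes Prescribed walk duration per session, minutes.
#' @param reset_level Level assigned after a top-level re-test (default 7).
#' @param borg_up_threshold Borg score at or below which a session counts
#'   toward a level-up streak (default 3).
#' @param borg_down_threshold Borg score at or above which a session counts
#'   toward a level-down streak (default 7).
#' @param streak_length Consecutive qualifying sessions required to change
#'   level (default 3).
#' @return An object of class `interactive_level_table`.
#' @seealso [init_interactive()], [update_interactive()], [apply_retest()]
#' @export
#' @examples
#' interactive_level_table()
interactive_level_table <- function(n_levels = 12,
                                    speed_fractions = 1 + 0.02 * (seq_len(n_levels) - 1),
                                    session_minutes = 30,
                                    reset_level = 7,
                                    borg_up_threshold = 3,
                                    borg_down_threshold = 7,
                                    streak_length = 3) {
  if (n_levels < 1 || n_levels != round(n_levels)) {
    abort("`n_levels` must be a positive integer.")
  }
  if (length(speed_fractions) != n_levels) {
    abort("`speed_fractions` must have one entry per level.")
  }
  if (any(speed_fractions <= 0) || any(diff(speed_fractions) < 0)) {
    abort("`speed_fractions` must be positive and nondecreasing.")
  }
  if (reset_level < 1 || reset_level > n_levels) {
    abort("`reset_level` must lie in [1, n_levels].")
  }
  if (!is_borg(borg_up_threshold) || !is_borg(borg_down_threshold)) {
    abort("Borg thresholds must be on the modified Borg grid {0, 0.5, ..., 10}.")
  }
  if (borg_down_threshold <= borg_up_threshold) {
    abort("`borg_down_threshold` must exceed `borg_up_threshold`.")
  }
  if (streak_length < 1 || streak_length != round(streak_length)) {
    abort("`streak_length` must be a positive integer.")
  }
  if (session_minutes <= 0) abort("`session_minutes` must be positive.")
  structure(
    list(
      n_levels = as.integer(n_levels),
      speed_fractions = as.numeric(speed_fractions),
      session_minutes = as.numeric(session_minutes),
      reset_level = as.integer(reset_level),
      borg_up_threshold = borg_up_threshold,
      borg_down_threshold = borg_down_threshold,
      streak_length = as.integer(streak_length)
    ),
    class = "interactive_level_table"
  )
}

# modified Borg grid: 0, 0.5, 1, ..., 10
is_borg <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x >= 0 && x <= 10 && isTRUE(all.equal(x * 2, round(x * 2)))
}

#' @export
print.fixed_level_table <- function(x, ...) {
  cat("<fixed_level_table> ", length(x$distances), " levels: ",
      paste(x$distances, collapse = ", "), " m; ",
      x$achievements_required, " qualifying days per level-up\n", sep = "")
  invisible(x)
}

#' @export
print.interactive_level_table <- function(x, ...) {
  cat("<interactive_level_table> ", x$n_levels, " levels; speed fractions ",
      x$speed_fractions[1], "-", x$speed_fractions[x$n_levels],
      "; Borg up <=", x$borg_up_threshold, " / down >=", x$borg_down_threshold,
      " over ", x$streak_length, " sessions; re-test resets to level ",
      x$reset_level, "\n", sep = "")
  invisible(x)
}
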