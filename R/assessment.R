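#' 6-minute walk test result
#'
#' Container for a 6MWT: the six per-minute mean walking speeds, the total
#' distance (integral of speed over the 360 s test) and the maximum walking
#' speed (largest of the six split speeds), which seeds the interactive
#' regimen's base intensity.
#'
#' @param split_speeds Six per-minute mean speeds in m/s.
#' @param distance Total distance in meters; computed from the splits when
#'   omitted.
#' @return An object of class `sixmwt_result` with fields `distance`,
#'   `split_speeds` and `max_speed`.
#' @seealso [compute_6mwt()] to derive one from a raw speed trace.
#' @export
#' @examples
#' sixmwt_result(split_speeds = c(1.2, 1, 1, 1, 1, 1))
sixmwt_result <- function(split_speeds, distance = sum(split_speeds) * 60) {
  if (length(split_speeds) != 6 || anyNA(split_speeds) || any(split_speeds < 0)) {
    abort("`split_speeds` must be six nonnegative per-minute speeds.")
  }
  if (!is.finite(distance) || distance < 0) abort("`distance` must be >= 0.")
  structure(
    list(
      distance = as.numeric(distance),
      split_speeds = as.numeric(split_speeds),
      max_speed = max(split_speeds)
    ),
    class = "sixmwt_result"
  )
}

#' @export
print.sixmwt_result <- function(x, ...) {
  cat(sprintf("<sixmwt_result> %.1f m in 6 min; max split speed %.3f m/s\n",
              x$distance, x$max_speed))
  invisible(x)
}

#' Compute a 6MWT result from a walking-speed trace
#'
#' Reduces an instantaneous speed trace covering the full 6-minute test to
#' the six one-minute split speeds (time-weighted means under linear
#' interpolation between samples), the walked distance (the integral of the
#' interpolated speed over \[0, 360\] s) and the maximum split speed.
#'
#' @param samples Data frame with numeric columns `elapsed_seconds`
#'   (strictly increasing, spanning at least \[0, 360\]) and `speed` (m/s,
#'   >= 0).
#' @return A [sixmwt_result()].
#' @export
#' @examples
#' tr <- tibble::tibble(elapsed_seconds = c(0, 360), speed = c(1, 1))
#' compute_6mwt(tr)$distance # 360 m
compute_6mwt <- function(samples) {
  if (!is.data.frame(samples) ||
      !all(c("elapsed_seconds", "speed") %in% names(samples)) ||
      nrow(samples) < 2) {
    abort("`samples` needs >= 2 rows with columns `elapsed_seconds` and `speed`.")
  }
  t <- samples$elapsed_seconds
  v <- samples$speed
  if (anyNA(t) || anyNA(v)) abort("Speed samples must not contain NA.")
  if (any(diff(t) <= 0)) abort("`elapsed_seconds` must be strictly increasing.")
  if (any(v < 0)) abort("`speed` must be >= 0.")
  if (min(t) > 0 || max(t) < 360) {
    abort("The speed trace must cover the full [0, 360] s test window.")
  }
  # piecewise-linear speed: exact integral = trapezoid over the knot grid
  # augmented with the minute boundaries
  grid <- sort(unique(c(t[t >= 0 & t <= 360], seq(0, 360, by = 60))))
  vg <- approx(t, v, xout = grid)$y
  seg_area <- diff(grid) * (head(vg, -1) + tail(vg, -1)) / 2
  seg_mid <- (head(grid, -1) + tail(grid, -1)) / 2
  minute <- pmin(floor(seg_mid / 60) + 1, 6)
  split_dist <- vapply(1:6, function(k) sum(seg_area[minute == k]), numeric(1))
  sixmwt_result(split_speeds = split_dist / 60, distance = sum(split_dist))
}

#' Screen patients against the trial's eligibility criteria
#'
#' A patient is eligible when age exceeds 20 years, post-bronchodilator FEV1
#' is below 80% of predicted, and the 6-minute walk distance exceeds 150 m
#' (all strict inequalities). Failing criteria are enumerated per patient.
#'
#' @param roster Data frame with numeric columns `age` (years),
#'   `fev1_pct_pred` (percent of predicted) and `sixmwt_distance` (meters).
#' @return The roster as a tibble with logical `eligible` and a character
#'   `reasons` column (semicolon-separated failing criteria, `""` when
#'   eligible).
#' @export
#' @examples
#' check_eligibility(tibble::tibble(age = 64, fev1_pct_pred = 58,
#'                                  sixmwt_distance = 356))
check_eligibility <- function(roster) {
  need <- c("age", "fev1_pct_pred", "sixmwt_distance")
  if (!is.data.frame(roster) || !all(need %in% names(roster))) {
    abort("`roster` needs columns age, fev1_pct_pred, sixmwt_distance.")
  }
  if (anyNA(roster[need])) abort("Eligibility inputs must not contain NA.")
  if (any(roster$age < 0) || any(roster$fev1_pct_pred < 0) ||
      any(roster$sixmwt_distance < 0)) {
    abort("Eligibility inputs must be nonnegative.")
  }
  roster |>
    tibble::as_tibble() |>
    dplyr::mutate(
      reasons = purrr::pmap_chr(
        list(.data$age, .data$fev1_pct_pred, .data$sixmwt_distance),
        function(age, fev1, dist) {
          r <- character()
          if (!(age > 20)) r <- c(r, "age_not_over_20")
          if (!(fev1 < 80)) r <- c(r, "fev1_not_below_80pct")
          if (!(dist > 150)) r <- c(r, "sixmwt_not_over_150m")
          paste(r, collapse = ";")
        }
      ),
      eligible = .data$reasons == ""
    )
}

#' Summarize patient global assessment responses
#'
#' Aggregates 5-point Likert PGA responses (1 = strongly disagree ...
#' 5 = strongly agree) per question.
#'
#' @param responses Long data frame with columns `patient_id`, `question`
#'   and `score` (integers in 1..5).
#' @return A tibble with one row per question: `n`, `mean`, `sd`.
#' @export
#' @examples
#' pga <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
#'                       question = "q1", score = c(2, 3, 3, 4))
#' summarize_pga(pga) # mean 3
summarize_pga <- function(responses) {
  need <- c("patient_id", "question", "score")
  if (!is.data.frame(responses) || !all(need %in% names(responses)) ||
      nrow(responses) == 0) {
    abort("`responses` must be a nonempty data frame with patient_id, question, score.")
  }
  s <- responses$score
  if (anyNA(s) || any(s < 1 | s > 5 | s != round(s))) {
    abort("PGA scores must be integers in 1..5.")
  }
  responses |>
    dplyr::group_by(.data$question) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$score),
      sd = stats::sd(.data$score),
      .groups = "drop"
    )
}
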