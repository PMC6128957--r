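#' Desaturation alerts over a pulse-oximetry stream
#'
#' Scans an in-session SpO2 sample stream and emits a desaturation alert at
#' the first sample strictly below the threshold (90% by default, the level
#' at which the apps vibrate to prompt the patient to pause). While the
#' signal stays below threshold, repeat alerts are suppressed for `debounce`
#' seconds after the last alert; a recovery to at or above threshold re-arms
#' the monitor immediately, so the next drop alerts at once.
#'
#' @param samples Data frame with numeric columns `elapsed_seconds`
#'   (strictly increasing) and `spo2` (percent, in \[0, 100\]).
#' @param threshold Alert threshold in percent (default 90; alerts fire
#'   strictly below it).
#' @param debounce Minimum seconds between repeat alerts within one
#'   continuous below-threshold run (default 30).
#' @param patient_id Optional identifier copied onto each alert.
#' @return A tibble of alert events with columns `patient_id`,
#'   `elapsed_seconds`, `spo2`, `kind` (always `"desaturation"`).
#' @export
#' @examples
#' s <- tibble::tibble(elapsed_seconds = c(0, 30, 60), spo2 = c(95, 92, 89))
#' monitor_spo2(s) # one alert at t = 60
monitor_spo2 <- function(samples, threshold = 90, debounce = 30,
                         patient_id = NA_character_) {
  if (!is.data.frame(samples) ||
      !all(c("elapsed_seconds", "spo2") %in% names(samples))) {
    abort("`samples` needs columns `elapsed_seconds` and `spo2`.")
  }
  t <- samples$elapsed_seconds
  s <- samples$spo2
  if (anyNA(t) || anyNA(s)) abort("SpO2 samples must not contain NA.")
  if (length(t) > 1 && any(diff(t) <= 0)) {
    abort("`elapsed_seconds` must be strictly increasing.")
  }
  if (any(s < 0 | s > 100)) abort("`spo2` must lie in [0, 100].")
  idx <- integer()
  in_run <- FALSE
  last_alert <- -Inf
  for (i in seq_along(t)) {
    if (s[i] < threshold) {
      if (!in_run || t[i] - last_alert >= debounce) {
        idx <- c(idx, i)
        last_alert <- t[i]
      }
      in_run <- TRUE
    } else {
      in_run <- FALSE
    }
  }
  tibble::tibble(
    patient_id = rep(patient_id, length(idx)),
    elapsed_seconds = t[idx],
    spo2 = s[idx],
    kind = rep("desaturation", length(idx))
  )
}
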