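#' Pulmonary-rehabilitation compliance summary
#'
#' A day counts as active when the patient logged at least one walking
#' session on that date; the compliance rate is active days divided by
#' prescribed days. The default prescription is one walk every day for 12
#' weeks from the first calendar day.
#'
#' @param sessions Session log with columns `patient_id`, `session_date`,
#'   `distance`, and optionally `borg`.
#' @param calendar Vector of prescribed dates (default: 84 consecutive days
#'   from the earliest session date, or from `start` when given).
#' @param start Optional first prescribed date.
#' @param weeks Prescription length in weeks used for the default calendar.
#' @param patients Patient ids to report on; defaults to those present in
#'   `sessions`. Patients with no logged session get a compliance rate of 0.
#' @return A tibble per patient: `prescribed_days`, `active_days`,
#'   `compliance_rate`, `total_distance`, `mean_borg`.
#' @export
compliance <- function(sessions, calendar = NULL, start = NULL, weeks = 12,
                       patients = NULL) {
  need <- c("patient_id", "session_date", "distance")
  if (!is.data.frame(sessions) || !all(need %in% names(sessions))) {
    abort("`sessions` needs columns patient_id, session_date, distance.")
  }
  if (is.null(calendar)) {
    if (is.null(start)) {
      if (nrow(sessions) == 0) abort("Cannot infer a calendar from an empty log.")
      start <- min(as.Date(sessions$session_date))
    }
    calendar <- as.Date(start) + 0:(weeks * 7 - 1)
  }
  calendar <- unique(as.Date(calendar))
  if (length(calendar) == 0) abort("The prescription calendar is empty.")
  if (is.null(patients)) patients <- unique(sessions$patient_id)
  in_cal <- dplyr::filter(sessions, as.Date(.data$session_date) %in% calendar)
  has_borg <- "borg" %in% names(sessions)
  out <- in_cal |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      active_days = dplyr::n_distinct(as.Date(.data$session_date)),
      total_distance = sum(.data$distance),
      mean_borg = if (has_borg) mean(.data$borg, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  tibble::tibble(patient_id = patients) |>
    dplyr::left_join(out, by = "patient_id") |>
    dplyr::mutate(
      prescribed_days = length(calendar),
      active_days = dplyr::coalesce(.data$active_days, 0L),
      compliance_rate = .data$active_days / length(calendar),
      total_distance = dplyr::coalesce(.data$total_distance, 0),
      .after = "patient_id"
    ) |>
    dplyr::select("patient_id", "prescribed_days", "active_days",
                  "compliance_rate", "total_distance", "mean_borg")
}

#' Flag patients needing closer monitoring
#'
#' Reproduces the monitoring website's watch lists: a patient is flagged
#' `low_spo2` if any telemetry sample fell below 90% saturation, and
#' `high_borg` if any session's modified Borg score reached 7 or more. Flags
#' are deduplicated per patient and reason, keeping the first occurrence as
#' evidence.
#'
#' @param sessions Session log with `patient_id`, `session_date`, `borg`,
#'   and a `samples` list-column of per-session telemetry tibbles with an
#'   `spo2` column (sessions without samples contribute no SpO2 evidence).
#' @param spo2_threshold Saturation below which a sample is flagged
#'   (default 90, strict).
#' @param borg_threshold Borg score at or above which a session is flagged
#'   (default 7).
#' @return A tibble of flags: `patient_id`, `reason`, `session_date`,
#'   `evidence` (the offending SpO2 or Borg value).
#' @export
flag_patients <- function(sessions, spo2_threshold = 90, borg_threshold = 7) {
  if (!is.data.frame(sessions) || !"patient_id" %in% names(sessions)) {
    abort("`sessions` must be a session log with a patient_id column.")
  }
  if (nrow(sessions) == 0) {
    return(tibble::tibble(patient_id = character(), reason = character(),
                          session_date = as.Date(character()),
                          evidence = numeric()))
  }
  rows <- purrr::map_dfr(seq_len(nrow(sessions)), function(i) {
    out <- list()
    if ("samples" %in% names(sessions)) {
      smp <- sessions$samples[[i]]
      if (is.data.frame(smp) && "spo2" %in% names(smp)) {
        if (anyNA(smp$spo2)) {
          warn(sprintf("Session %d of patient %s has NA SpO2 samples; skipped.",
                       i, sessions$patient_id[i]))
        }
        low <- smp$spo2[!is.na(smp$spo2) & smp$spo2 < spo2_threshold]
        if (length(low)) {
          out$spo2 <- tibble::tibble(
            patient_id = sessions$patient_id[i], reason = "low_spo2",
            session_date = as.Date(sessions$session_date[i]),
            evidence = min(low)
          )
        }
      }
    }
    if ("borg" %in% names(sessions) && !is.na(sessions$borg[i]) &&
        sessions$borg[i] >= borg_threshold) {
      out$borg <- tibble::tibble(
        patient_id = sessions$patient_id[i], reason = "high_borg",
        session_date = as.Date(sessions$session_date[i]),
        evidence = as.numeric(sessions$borg[i])
      )
    }
    dplyr::bind_rows(out)
  })
  rows |>
    dplyr::arrange(.data$session_date) |>
    dplyr::distinct(.data$patient_id, .data$reason, .keep_all = TRUE) |>
    dplyr::arrange(.data$patient_id, .data$reason)
}

#' Restrict records to one study site
#'
#' Each participating hospital may only access its own patients; this is the
#' corresponding row filter.
#'
#' @param records Data frame carrying a `site` column (directly or joined in
#'   via `roster`).
#' @param site_id Site identifier to keep.
#' @param roster Optional roster with `patient_id` and `site`, used when
#'   `records` has no `site` column.
#' @return The matching rows as a tibble; empty (with a warning) for an
#'   unknown site.
#' @export
site_view <- function(records, site_id, roster = NULL) {
  if (!"site" %in% names(records)) {
    if (is.null(roster) || !all(c("patient_id", "site") %in% names(roster))) {
      abort("`records` has no `site` column; supply a roster with patient_id and site.")
    }
    records <- dplyr::left_join(
      records, dplyr::select(roster, "patient_id", "site"), by = "patient_id"
    )
  }
  if (anyNA(records$site)) abort("Every record must carry a site id.")
  out <- dplyr::filter(records, .data$site == site_id)
  if (nrow(out) == 0) {
    warn(sprintf("No records for site '%s'.", site_id))
  }
  tibble::as_tibble(out)
}

#' Per-patient pulmonary-rehabilitation record
#'
#' The monitoring website's per-patient view: one row per session with the
#' regimen level in force on that date (reconstructed from the state
#' history), the walked distance, mean in-session heart rate, minimum SpO2,
#' and the reported Borg score.
#'
#' @param sessions One patient's session log (columns `session_date`,
#'   `distance`, `duration`, `borg`, optional `samples` list-column).
#' @param history The patient's regimen event history tibble (as stored on a
#'   `regimen_state`), used to track the level over time; pass `NULL` for a
#'   level-free report.
#' @return A tibble with one row per session: `session_date`, `level`,
#'   `distance`, `duration`, `mean_heart_rate`, `min_spo2`, `borg`.
#' @export
pr_record <- function(sessions, history = NULL) {
  if (!is.data.frame(sessions)) abort("`sessions` must be a data frame.")
  if (nrow(sessions) == 0) {
    return(tibble::tibble(session_date = as.Date(character()), level = integer(),
                          distance = numeric(), duration = numeric(),
                          mean_heart_rate = numeric(), min_spo2 = numeric(),
                          borg = numeric()))
  }
  sessions <- dplyr::arrange(sessions, .data$session_date)
  lvl <- rep(NA_integer_, nrow(sessions))
  if (!is.null(history) && nrow(history) > 0) {
    hist <- history[!is.na(history$date), ]
    hist <- hist[order(hist$date, hist$step), ]
    init_lvl <- history$level[history$event == "init"][1]
    if (is.na(init_lvl)) init_lvl <- history$level[1]
    for (i in seq_len(nrow(sessions))) {
      d <- as.Date(sessions$session_date[i])
      prior <- hist$level[hist$date <= d]
      lvl[i] <- if (length(prior)) prior[length(prior)] else init_lvl
    }
  }
  stat <- function(i, col, f) {
    if (!"samples" %in% names(sessions)) return(NA_real_)
    smp <- sessions$samples[[i]]
    if (is.data.frame(smp) && col %in% names(smp) && nrow(smp) > 0) {
      f(smp[[col]])
    } else NA_real_
  }
  tibble::tibble(
    session_date = as.Date(sessions$session_date),
    level = lvl,
    distance = sessions$distance,
    duration = sessions$duration,
    mean_heart_rate = vapply(seq_len(nrow(sessions)), stat,
                             numeric(1), col = "heart_rate", f = mean),
    min_spo2 = vapply(seq_len(nrow(sessions)), stat,
                      numeric(1), col = "spo2", f = min),
    borg = if ("borg" %in% names(sessions)) as.numeric(sessions$borg) else
      rep(NA_real_, nrow(sessions))
  )
}
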