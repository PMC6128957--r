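#' Write a walking-session log to disk
#'
#' Two plain-text renderings of the same log are supported and round-trip
#' through [read_sessions()]:
#' * `jsonl` — one JSON object per line, telemetry samples embedded;
#' * `csv` — one row per session; sample streams, if present, go to a
#'   companion JSONL file alongside (`<stem>_samples.jsonl`) keyed by a
#'   `session_id`.
#' Dates are ISO-8601, numbers full precision, encoding UTF-8.
#'
#' @param sessions Session tibble (`patient_id`, `session_date`, `distance`,
#'   `duration`, `borg`, optional `samples` list-column).
#' @param path Output file; the extension (`.jsonl` / `.csv`) picks the
#'   format unless `format` is given.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path,
                           format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  sessions <- tibble::as_tibble(sessions)
  has_samples <- "samples" %in% names(sessions)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(sessions)), function(i) {
      rec <- list(
        patient_id = sessions$patient_id[i],
        session_date = format(as.Date(sessions$session_date[i])),
        distance = sessions$distance[i],
        duration = sessions$duration[i],
        borg = sessions$borg[i]
      )
      if (has_samples && is.data.frame(sessions$samples[[i]])) {
        rec$samples <- sessions$samples[[i]]
      }
      jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", digits = NA,
                       dataframe = "columns")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    flat <- sessions |>
      dplyr::mutate(session_id = dplyr::row_number(), .before = 1) |>
      dplyr::select(dplyr::any_of(c("session_id", "patient_id", "session_date",
                                    "distance", "duration", "borg")))
    readr::write_csv(flat, path)
    if (has_samples) {
      spath <- sub("\\.csv$", "_samples.jsonl", path, ignore.case = TRUE)
      lines <- vapply(seq_len(nrow(sessions)), function(i) {
        jsonlite::toJSON(
          list(session_id = i, samples = sessions$samples[[i]]),
          auto_unbox = TRUE, na = "null", digits = NA, dataframe = "columns"
        )
      }, character(1))
      writeLines(lines, spath, useBytes = TRUE)
    }
  }
  invisible(path)
}

#' Read and validate a walking-session log
#'
#' Parses a JSONL or CSV session log written by [write_sessions()] (or by the
#' apps) and validates every record against the session invariants: distance
#' >= 0, duration > 0, Borg (when present) on the modified Borg grid in
#' \[0, 10\], telemetry sample times strictly increasing, SpO2 in \[0, 100\].
#' Invalid records are dropped with a warning naming the offending lines;
#' the read fails only when no record is valid.
#'
#' @param path Input file.
#' @param format `"jsonl"` or `"csv"`; inferred from the extension by
#'   default. For CSV, a companion `<stem>_samples.jsonl` is picked up
#'   automatically when present.
#' @return A validated session tibble.
#' @export
read_sessions <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  parse_samples <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    tibble::as_tibble(lapply(x, unlist))
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    rows <- purrr::map(recs, function(r) {
      if (is.null(r)) return(NULL)
      tibble::tibble(
        patient_id = as.character(r$patient_id),
        session_date = as.Date(r$session_date),
        distance = as.numeric(r$distance),
        duration = as.numeric(r$duration),
        borg = if (is.null(r$borg)) NA_real_ else as.numeric(r$borg),
        samples = list(parse_samples(r$samples))
      )
    })
  } else {
    flat <- readr::read_csv(path, show_col_types = FALSE)
    spath <- sub("\\.csv$", "_samples.jsonl", path, ignore.case = TRUE)
    smap <- list()
    if (file.exists(spath)) {
      for (l in readLines(spath, warn = FALSE, encoding = "UTF-8")) {
        if (!nzchar(trimws(l))) next
        r <- jsonlite::fromJSON(l)
        smap[[as.character(r$session_id)]] <- parse_samples(r$samples)
      }
    }
    rows <- purrr::map(seq_len(nrow(flat)), function(i) {
      sid <- if ("session_id" %in% names(flat)) as.character(flat$session_id[i])
             else as.character(i)
      tibble::tibble(
        patient_id = as.character(flat$patient_id[i]),
        session_date = as.Date(flat$session_date[i]),
        distance = as.numeric(flat$distance[i]),
        duration = as.numeric(flat$duration[i]),
        borg = if ("borg" %in% names(flat)) as.numeric(flat$borg[i]) else NA_real_,
        samples = list(smap[[sid]])
      )
    })
  }
  problems <- character()
  valid <- purrr::imap(rows, function(row, i) {
    msg <- validate_session_row(row)
    if (is.null(msg)) return(row)
    problems <<- c(problems, sprintf("line %d: %s", i, msg))
    NULL
  })
  valid <- purrr::compact(valid)
  if (length(problems)) {
    warn(paste0("Dropped ", length(problems), " invalid session record(s):\n  ",
                paste(problems, collapse = "\n  ")))
  }
  if (length(valid) == 0) {
    abort("No valid session records could be read.")
  }
  dplyr::bind_rows(valid)
}

validate_session_row <- function(row) {
  if (is.na(row$session_date)) return("unparseable session_date")
  if (is.na(row$distance) || row$distance < 0) return("distance must be >= 0")
  if (is.na(row$duration) || row$duration <= 0) return("duration must be > 0")
  if (!is.na(row$borg) && !is_borg(row$borg)) {
    return("borg must be on {0, 0.5, ..., 10}")
  }
  smp <- row$samples[[1]]
  if (!is.null(smp) && nrow(smp) > 0) {
    if (!all(c("elapsed_seconds", "spo2") %in% names(smp))) {
      return("samples need elapsed_seconds and spo2")
    }
    if (anyNA(smp$elapsed_seconds) ||
        (nrow(smp) > 1 && any(diff(smp$elapsed_seconds) <= 0))) {
      return("sample times must be strictly increasing")
    }
    if (anyNA(smp$spo2) || any(smp$spo2 < 0 | smp$spo2 > 100)) {
      return("spo2 must lie in [0, 100]")
    }
  }
  NULL
}

#' Load a platform configuration file
#'
#' Reads a YAML or JSON configuration holding level-table overrides and
#' monitoring thresholds, validates it against the known keys, and returns
#' ready-to-use objects. Recognized top-level keys: `fixed` (fields of
#' [fixed_level_table()]), `interactive` (fields of
#' [interactive_level_table()]), `thresholds` (`spo2_threshold`, `debounce`,
#' `borg_flag`), and `seed`. Missing keys fall back to the defaults, which
#' reproduce the platform's printed parameters exactly; unknown keys are
#' rejected.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A list with `fixed` and `interactive` level tables, a
#'   `thresholds` list, and `seed` (or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  known <- c("fixed", "interactive", "thresholds", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(paste0("Unknown configuration key(s): ", paste(extra, collapse = ", ")))
  }
  fixed <- do.call(fixed_level_table, as.list(cfg$fixed %||% list()))
  interactive <- do.call(interactive_level_table,
                         as.list(cfg$interactive %||% list()))
  thr_defaults <- list(spo2_threshold = 90, debounce = 30, borg_flag = 7)
  thresholds <- utils::modifyList(thr_defaults, as.list(cfg$thresholds %||% list()))
  extra_thr <- setdiff(names(thresholds), names(thr_defaults))
  if (length(extra_thr)) {
    abort(paste0("Unknown threshold key(s): ", paste(extra_thr, collapse = ", ")))
  }
  list(fixed = fixed, interactive = interactive, thresholds = thresholds,
       seed = cfg$seed)
}
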