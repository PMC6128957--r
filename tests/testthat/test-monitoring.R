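sess <- function(patient_id, dates, distance = 700, borg = 3, samples = NULL) {
  tibble::tibble(
    patient_id = patient_id, session_date = as.Date(dates),
    distance = distance, duration = 1800, borg = borg,
    samples = if (is.null(samples)) rep(list(NULL), length(dates)) else samples
  )
}

spo2_samples <- function(values) {
  list(tibble::tibble(elapsed_seconds = seq_along(values) * 30, spo2 = values,
                      heart_rate = 95))
}

test_that("compliance is active days over prescribed days", {
  cal <- as.Date("2024-01-01") + 0:41
  s <- sess("p1", as.Date("2024-01-01") + 0:20)
  out <- compliance(s, calendar = cal)
  expect_equal(out$compliance_rate, 0.5)
  expect_equal(out$active_days, 21L)
  expect_equal(out$prescribed_days, 42L)
  # two sessions on one day count one active day
  s2 <- sess("p1", as.Date(c("2024-01-01", "2024-01-01")))
  expect_equal(compliance(s2, calendar = cal)$active_days, 1L)
  # full adherence and zero adherence bounds
  expect_equal(compliance(sess("p1", cal), calendar = cal)$compliance_rate, 1)
  none <- compliance(s[0, ], calendar = cal, patients = "p1")
  expect_equal(none$compliance_rate, 0)
  expect_error(compliance(s, calendar = as.Date(character())), "empty")
})

test_that("patients are flagged on SpO2 < 90 or Borg >= 7, with evidence", {
  s <- dplyr::bind_rows(
    sess("low", "2024-01-01", borg = 3, samples = spo2_samples(c(93, 89, 92))),
    sess("breathless", "2024-01-02", borg = 7, samples = spo2_samples(c(95, 94))),
    sess("fine", "2024-01-03", borg = 6, samples = spo2_samples(c(90, 91)))
  )
  fl <- flag_patients(s)
  expect_setequal(fl$patient_id, c("low", "breathless"))
  expect_equal(fl$reason[fl$patient_id == "low"], "low_spo2")
  expect_equal(fl$evidence[fl$patient_id == "low"], 89)
  expect_equal(fl$reason[fl$patient_id == "breathless"], "high_borg")
  expect_equal(fl$evidence[fl$patient_id == "breathless"], 7)
})

test_that("flags are deduplicated per patient and reason, first occurrence kept", {
  s <- dplyr::bind_rows(
    sess("p", "2024-01-02", borg = 8),
    sess("p", "2024-01-01", borg = 9),
    sess("p", "2024-01-03", borg = 10)
  )
  fl <- flag_patients(s)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$session_date, as.Date("2024-01-01"))
  expect_equal(fl$evidence, 9)
})

test_that("flagging equals the brute-force union of the two predicate scans", {
  withr::with_seed(13, {
    s <- purrr::map_dfr(1:40, function(i) {
      sess(sprintf("p%02d", sample(1:12, 1)),
           as.Date("2024-01-01") + sample(0:60, 1),
           borg = sample(0:10, 1),
           samples = spo2_samples(sample(86:97, 10, replace = TRUE)))
    })
  })
  fl <- flag_patients(s)
  brute_low <- unique(s$patient_id[vapply(s$samples,
                                          function(x) any(x$spo2 < 90), logical(1))])
  brute_high <- unique(s$patient_id[s$borg >= 7])
  expect_setequal(fl$patient_id[fl$reason == "low_spo2"], brute_low)
  expect_setequal(fl$patient_id[fl$reason == "high_borg"], brute_high)
  expect_true(all(fl$evidence[fl$reason == "low_spo2"] < 90))
  expect_true(all(fl$evidence[fl$reason == "high_borg"] >= 7))
})

test_that("site_view partitions records without cross-site leakage", {
  roster <- tibble::tibble(patient_id = c("a", "b", "c"),
                           site = c("S1", "S1", "S2"))
  records <- tibble::tibble(patient_id = c("a", "b", "c", "a"),
                            value = 1:4)
  v1 <- site_view(records, "S1", roster = roster)
  v2 <- site_view(records, "S2", roster = roster)
  expect_setequal(v1$patient_id, c("a", "b"))
  expect_setequal(v2$patient_id, "c")
  expect_equal(nrow(v1) + nrow(v2), nrow(records))
  expect_length(intersect(v1$patient_id, v2$patient_id), 0)
  expect_warning(empty <- site_view(records, "S9", roster = roster), "No records")
  expect_equal(nrow(empty), 0L)
  # identity when every record belongs to the queried site
  one <- dplyr::filter(records, patient_id != "c")
  expect_equal(nrow(site_view(one, "S1", roster = roster)), nrow(one))
})

test_that("pr_record tracks the level over a fixed-arm log", {
  st <- init_fixed(fixed_level_table())
  dates <- as.Date("2024-01-01") + 0:27
  s <- sess("p", dates, distance = 3600) # clears every level's target
  for (i in seq_along(dates)) st <- update_fixed(st, s[i, ])
  rec <- pr_record(s, st$history)
  expect_equal(nrow(rec), nrow(s))
  expect_equal(rec$level[1], 1L)
  expect_equal(rec$level[14], 2L) # 14th qualifying day steps the level
  expect_equal(rec$level[28], 3L)
  expect_equal(nrow(pr_record(s[0, ], st$history)), 0L)
})

test_that("pr_record carries telemetry summaries per session", {
  s <- sess("p", "2024-01-01", samples = spo2_samples(c(95, 89, 93)))
  rec <- pr_record(s, NULL)
  expect_equal(rec$min_spo2, 89)
  expect_equal(rec$mean_heart_rate, 95)
  expect_equal(rec$borg, 3)
})
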