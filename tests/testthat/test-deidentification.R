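test_that("dates anchor to the baseline visit as day 0", {
  ev <- data.frame(
    participant_id = c("T1", "T1", "T1", "T2"),
    event_label = c("screening", "visit1", "prescreen", "baseline"),
    calendar_date = c("2010-03-05", "2010-03-19", "2010-02-26", "2011-07-01"),
    is_baseline = c(TRUE, FALSE, FALSE, TRUE))
  out <- anchor_dates(ev)
  expect_identical(out$study_day, c(0L, 14L, -7L, 0L))
  expect_false("calendar_date" %in% names(out))
})

test_that("participants without exactly one baseline are rejected by name", {
  ev <- data.frame(participant_id = "T9", event_label = "v1",
                   calendar_date = "2010-01-01", is_baseline = FALSE)
  expect_error(anchor_dates(ev), "T9")
  ev2 <- data.frame(participant_id = "T8", event_label = c("a", "b"),
                    calendar_date = c("2010-01-01", "2010-01-02"),
                    is_baseline = c(TRUE, TRUE))
  expect_error(anchor_dates(ev2), "T8")
})

test_that("study-day offsets preserve pairwise intervals for random event sets", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    dates <- as.Date("2008-01-01") + sample.int(3000L, n)
    ev <- data.frame(participant_id = "P", event_label = paste0("e", 1:n),
                     calendar_date = format(dates),
                     is_baseline = seq_len(n) == sample.int(n, 1))
    sd <- anchor_dates(ev)$study_day
    expect_identical(outer(sd, sd, `-`),
                     matrix(as.integer(outer(dates, dates, `-`)), n, n))
    expect_identical(sd[ev$is_baseline], 0L)
  }
})

test_that("times quantize to the nearest quarter hour with half-up ties and midnight wrap", {
  expect_identical(quantize_time("14:37:00"), "14:30:00")
  expect_identical(quantize_time("09:00:00"), "09:00:00")
  expect_identical(quantize_time("11:52:30"), "12:00:00")  # exact tie: up
  expect_identical(quantize_time("11:52:29"), "11:45:00")
  expect_identical(quantize_time("23:52:30"), "00:00:00")  # wraps forward
  expect_identical(quantize_time("23:52:29"), "23:45:00")
  expect_identical(quantize_time("00:07:29.5"), "00:00:00")
  expect_error(quantize_time("25:00:00"), "invalid")
  expect_error(quantize_time("half past nine"), "unparseable")
})

test_that("quantization error never exceeds 450 seconds (random times)", {
  set.seed(7)
  secs <- sort(c(sample(0:86399, 800), 0, 86399, 85950, 85949))
  t <- sprintf("%02d:%02d:%02d", secs %/% 3600, (secs %% 3600) %/% 60,
               secs %% 60)
  q <- quantize_time(t)
  p <- matrix(as.numeric(unlist(strsplit(q, ":"))), ncol = 3, byrow = TRUE)
  qsecs <- p[, 1] * 3600 + p[, 2] * 60 + p[, 3]
  diff <- pmin(abs(qsecs - secs), 86400 - abs(qsecs - secs))  # circular
  expect_true(all(diff <= 450))
  expect_true(all(qsecs %% 900 == 0))
})

test_that("recoding is stable, injective, and survives persistence", {
  m <- recoding_map("institution", seed = 3)
  r1 <- recode(m, "Hopital_de_la_Pitie_Salpetriere")
  expect_match(r1$code, "^[A-Z]{1,2}$")
  r2 <- recode(r1$map, "Hopital_de_la_Pitie_Salpetriere")
  expect_identical(r2$code, r1$code)               # stability
  r3 <- recode(r2$map, "Monash_Biomedical_Imaging")
  expect_false(identical(r3$code, r1$code))        # injectivity
  expect_identical(recode(r3$map, r1$code)$code, r1$code)  # codes pass through

  path <- file.path(withr::local_tempdir(), "maps.json")
  write_recoding_maps(list(institution = r3$map), path)
  back <- read_recoding_maps(path)$institution
  expect_identical(recode(back, "Hopital_de_la_Pitie_Salpetriere")$code,
                   r1$code)
  # new values after reload still get unused codes
  r4 <- recode(back, "University_College_London")
  expect_false(r4$code %in% unname(back$forward))
})

test_that("recoding is deterministic under a fixed seed and order-independent when sorted", {
  vals <- c("site_c", "site_a", "site_b")
  a <- recode_values(recoding_map("institution", seed = 9), vals)
  b <- recode_values(recoding_map("institution", seed = 9), vals)
  expect_identical(a$codes, b$codes)
  s1 <- recode_values(recoding_map("institution", seed = 9), vals,
                      sorted = TRUE)
  s2 <- recode_values(recoding_map("institution", seed = 9), rev(vals),
                      sorted = TRUE)
  expect_identical(stats::setNames(s1$codes, vals),
                   stats::setNames(rev(s2$codes), vals))
})

test_that("participant-ID codes follow the fixed-prefix zero-padded grammar", {
  m <- recoding_map("participant_id", seed = 1)
  r <- recode(m, "HD-1234")
  expect_match(r$code, "^T[0-9]{5}$")
})

test_that("code space exhaustion is rejected with the capacity stated", {
  m <- recoding_map("institution", seed = 0)
  m$pool <- m$pool[1:2]
  m <- recode(m, "a")$map
  m <- recode(m, "b")$map
  expect_error(recode(m, "c"), "capacity 2")
})

test_that("sidecar scrubbing removes, transforms, audits, and is idempotent", {
  policy <- default_scrub_policy()
  meta <- list(InstitutionName = "Hopital_de_la_Pitie_Salpetriere",
               InstitutionAddress = "47 Bd de l'Hopital",
               DeviceSerialNumber = "35197",
               AcquisitionTime = "14:37:00",
               AcquisitionDate = "2010-03-19",
               RepetitionTime = 2.2, FlipAngle = 9)
  maps <- list(institution = recoding_map("institution", seed = 2),
               scanner_serial = recoding_map("scanner_serial", seed = 2))
  res <- scrub_sidecar(meta, policy, maps, anchor = "2010-03-05")
  out <- res$metadata
  expect_match(out$InstitutionName, "^Institution [A-Z]{1,2}$")
  expect_null(out$InstitutionAddress)
  expect_identical(out$AcquisitionTime, "14:30:00")
  expect_identical(out$AcquisitionDate, 14L)
  expect_identical(out$RepetitionTime, 2.2)   # untouched fields identical
  expect_setequal(res$audit$field,
                  c("InstitutionName", "InstitutionAddress",
                    "DeviceSerialNumber", "AcquisitionTime",
                    "AcquisitionDate"))
  again <- scrub_sidecar(out, policy, res$maps, anchor = "2010-03-05")
  expect_identical(again$metadata, out)
  expect_identical(nrow(again$audit), 0L)
})

test_that("an unparseable transform value is dropped and flagged, not kept", {
  res <- scrub_sidecar(list(AcquisitionDate = "sometime in spring"),
                       default_scrub_policy(), list(), anchor = "2010-03-05")
  expect_null(res$metadata$AcquisitionDate)
  expect_match(res$audit$action, "dropped")
})

test_that("a scrub policy with overlapping remove/transform fields is invalid", {
  expect_error(scrub_policy("AcquisitionTime",
                            c(AcquisitionTime = "quantize_time")),
               "both removed and transformed")
  expect_error(scrub_policy(transform_fields = c(X = "shred")), "transform")
})

test_that("dataset deidentification is a fixed point after one application", {
  root <- file.path(withr::local_tempdir(), "deid")
  spec <- fixture_spec(3, 2, c(T1w = 1L), seed = 5,
                       planted_identifiers = list(
                         list(kind = "institution_name"),
                         list(kind = "time", value = "09:41:17"),
                         list(kind = "scanner_serial", value = "SN-778")))
  man <- make_fixture(spec, root)
  first <- deidentify_dataset(root, baselines = man$baselines, seed = 5)
  expect_gt(nrow(first$audit), 0L)
  second <- deidentify_dataset(root, maps = first$maps,
                               baselines = man$baselines)
  expect_identical(nrow(second$audit), 0L)
  expect_identical(nrow(audit_dataset(root)), 0L)
})

test_that("the audit finds every planted identifier and nothing else", {
  root <- file.path(withr::local_tempdir(), "audit")
  planted <- list(list(kind = "institution_name"),
                  list(kind = "institution_address"),
                  list(kind = "date"),
                  list(kind = "time", value = "14:37:12"),
                  list(kind = "scanner_serial", value = "Serial 91"),
                  list(kind = "participant_id"),
                  list(kind = "comment_date"))
  man <- make_fixture(fixture_spec(4, 2, c(T1w = 1L), seed = 11,
                                   planted_identifiers = planted), root)
  report <- audit_dataset(root)
  # recall 1.0: every planted (file, field) is reported
  planted_keys <- paste(man$planted$file, man$planted$field)
  found_keys <- paste(report$path, report$field)
  expect_true(all(planted_keys %in% found_keys))
  # precision 1.0: nothing beyond the planted identifiers is reported
  expect_setequal(found_keys, planted_keys)

  clean <- file.path(withr::local_tempdir(), "clean")
  make_fixture(fixture_spec(3, 1, c(T1w = 1L), seed = 2), clean)
  expect_identical(nrow(audit_dataset(clean)), 0L)
})

test_that("unreadable sidecars are reported as unverifiable, not fatal", {
  root <- file.path(withr::local_tempdir(), "broken")
  make_fixture(fixture_spec(1, 1, c(T1w = 1L), seed = 1), root)
  sidecar <- list.files(root, pattern = "T1w\\.json$", recursive = TRUE,
                        full.names = TRUE)[1]
  writeLines("{not json", sidecar)
  rep <- audit_dataset(root)
  expect_identical(rep$finding, "unverifiable")
})
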