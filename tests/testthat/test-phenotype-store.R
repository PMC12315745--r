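test_that("deconstruction splits wide tables into per-participant documents", {
  dict <- toy_dictionary()
  tabs <- toy_tables(n = 3L, visits = 2L)
  docs <- deconstruct_tables(tabs, dict, id_column = "subjid",
                             session_column = "visit")
  expect_length(docs, 3L)
  expect_setequal(names(docs), sprintf("T%05d", 1:3))
  for (d in docs) {
    expect_length(d$sessions, 2L)
    expect_named(d$demographics, c("sex", "age_baseline"),
                 ignore.order = TRUE)
  }
  # non-missing cell count is conserved
  expect_identical(count_pheno_cells(docs),
                   as.integer(count_table_cells(tabs, "subjid", "visit")))
})

test_that("columns named by alias or provenance original name map to the canonical variable", {
  dict <- toy_dictionary()
  tabs <- toy_tables()
  names(tabs$demographics.csv)[2] <- "gender"   # alias of sex
  names(tabs$visits.csv)[3] <- "tms"            # provenance original name
  docs <- deconstruct_tables(tabs, dict, "subjid", "visit")
  expect_identical(docs$T00001$demographics$sex, "F")
  expect_true("motor_score" %in% names(docs$T00001$sessions[["01"]]))
})

test_that("deconstruction rejects unknown columns and conflicting values", {
  dict <- toy_dictionary()
  tabs <- toy_tables()
  tabs$demographics.csv$handedness <- "R"
  expect_error(deconstruct_tables(tabs, dict, "subjid", "visit"),
               "handedness")

  tabs <- toy_tables()
  extra <- data.frame(subjid = "T00001", sex = "M")  # conflicts with F
  expect_error(
    deconstruct_tables(c(tabs, list(extra.csv = extra)), dict,
                       "subjid", "visit"),
    "T00001.*sex")

  dup <- toy_tables()
  dup$visits.csv <- rbind(dup$visits.csv, data.frame(
    subjid = "T00001", visit = "01", motor_score = 99, cognitive_score = 1L))
  expect_error(deconstruct_tables(dup, dict, "subjid", "visit"),
               "session '01'")

  expect_length(deconstruct_tables(list(), dict, "subjid"), 0L)
})

test_that("generated tables honour alias headers with canonical values", {
  dict <- toy_dictionary()
  docs <- deconstruct_tables(toy_tables(), dict, "subjid", "visit")
  via_alias <- generate_tables(docs, dict, requested_variables = "gender")
  via_canon <- generate_tables(docs, dict, requested_variables = "sex")
  expect_named(via_alias$participants, c("participant_id", "gender"))
  expect_identical(via_alias$participants$gender,
                   via_canon$participants$sex)
})

test_that("unresolvable requests list near-matches; empty documents give empty tables", {
  dict <- toy_dictionary()
  err <- tryCatch(generate_tables(list(), dict, "motor_scre"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "motor_score")
  tabs <- generate_tables(list(), dict)
  expect_identical(nrow(tabs$participants), 0L)
  expect_named(tabs$participants, c("participant_id", "sex", "age_baseline"))
  expect_named(tabs$sessions$sessions,
               c("participant_id", "session_id", "motor_score",
                 "cognitive_score"))
})

test_that("a participant lacking a session score keeps its row with a missing cell", {
  dict <- toy_dictionary()
  tabs <- toy_tables()
  tabs$visits.csv$motor_score[2] <- NA
  docs <- deconstruct_tables(tabs, dict, "subjid", "visit")
  out <- generate_tables(docs, dict)$sessions$sessions
  row <- out[out$participant_id == "T00001" & out$session_id == "02", ]
  expect_identical(nrow(row), 1L)
  expect_true(is.na(row$motor_score))
  # the BIDS TSV encoding writes the missing marker
  path <- file.path(withr::local_tempdir(), "ses.tsv")
  write_bids_tsv(out, path)
  expect_true(any(grepl("\tn/a", readLines(path), fixed = TRUE)))
})

test_that("categorical values outside accepted codes are rejected at generation", {
  dict <- toy_dictionary()
  docs <- list(X1 = pheno_document("X1", demographics = list(sex = "Q")))
  expect_error(generate_tables(docs, dict, "sex"), "accepted codes")
})

test_that("documents round-trip through JSON files in the subject folder", {
  dict <- toy_dictionary()
  docs <- deconstruct_tables(toy_tables(), dict, "subjid", "visit")
  root <- withr::local_tempdir()
  for (d in docs) write_pheno_document(d, root)
  expect_true(file.exists(file.path(root, "sub-T00001",
                                    "sub-T00001_phenotype.json")))
  back <- read_pheno_documents(root, dictionary = dict)
  expect_identical(back[order(names(back))], docs[order(names(docs))])
})

test_that("removing one participant's document changes only that participant's rows", {
  dict <- toy_dictionary()
  docs <- deconstruct_tables(toy_tables(n = 4L), dict, "subjid", "visit")
  full <- generate_tables(docs, dict)
  less <- generate_tables(docs[names(docs) != "T00002"], dict)
  keep <- full$participants$participant_id != "T00002"
  expect_identical(less$participants, full$participants[keep, ],
                   ignore_attr = TRUE)
  keep_s <- full$sessions$sessions$participant_id != "T00002"
  expect_identical(less$sessions$sessions,
                   full$sessions$sessions[keep_s, ], ignore_attr = TRUE)
})

test_that("session variables require a session label", {
  dict <- toy_dictionary()
  tabs <- toy_tables()
  tabs$visits.csv$visit <- NULL
  expect_error(deconstruct_tables(tabs, dict, "subjid", "visit"),
               "session")
})

test_that("phenotype tables are written with paired data dictionaries", {
  dict <- toy_dictionary()
  docs <- deconstruct_tables(toy_tables(), dict, "subjid", "visit")
  root <- withr::local_tempdir()
  write_phenotype_tables(generate_tables(docs, dict), dict, root)
  expect_true(file.exists(file.path(root, "participants.tsv")))
  dd <- jsonlite::read_json(file.path(root, "phenotype", "sessions.json"))
  expect_identical(dd$motor_score$Provenance[[1]]$original_variable_name,
                   "tms")
})
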