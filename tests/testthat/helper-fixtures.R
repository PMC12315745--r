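# Shared builders for toy studies used across the suite. All fixtures are
# generated in code at test time; nothing is read from disk.

toy_dictionary <- function(study = "toy") {
  src <- function(orig, file) list(source_record(study, file, orig))
  variable_dictionary(list(
    variable_spec("sex", "demographic", "categorical",
                  aliases = "gender",
                  accepted_codes = c(F = "female", M = "male"),
                  provenance = src("gender", "demographics.csv")),
    variable_spec("age_baseline", "demographic", "real",
                  provenance = src("age", "demographics.csv")),
    variable_spec("motor_score", "session", "real",
                  provenance = src("tms", "visits.csv")),
    variable_spec("cognitive_score", "session", "integer",
                  provenance = src("sdmt", "visits.csv"))),
    study_label = study)
}

toy_tables <- function(n = 3L, visits = 2L) {
  ids <- sprintf("T%05d", seq_len(n))
  list(
    demographics.csv = data.frame(
      subjid = ids,
      sex = rep(c("F", "M"), length.out = n),
      age_baseline = seq(40, by = 2.5, length.out = n),
      stringsAsFactors = FALSE),
    visits.csv = data.frame(
      subjid = rep(ids, each = visits),
      visit = rep(sprintf("%02d", seq_len(visits)), n),
      motor_score = seq(10, by = 1.5, length.out = n * visits),
      cognitive_score = seq_len(n * visits) + 20L,
      stringsAsFactors = FALSE))
}

# random wide-study generator for round-trip property tests
random_study <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1)
  visits <- sample(1:3, 1)
  ids <- sprintf("S%04d", seq_len(n))
  demo <- data.frame(pid = ids,
                     sex = sample(c("F", "M"), n, TRUE),
                     age_baseline = round(runif(n, 20, 80), 1),
                     stringsAsFactors = FALSE)
  ses <- data.frame(pid = rep(ids, each = visits),
                    visit = rep(sprintf("%02d", seq_len(visits)), n),
                    motor_score = round(runif(n * visits, 0, 100), 1),
                    cognitive_score = sample.int(60L, n * visits, TRUE),
                    stringsAsFactors = FALSE)
  # knock out some cells at random (missing values)
  for (col in c("motor_score", "cognitive_score")) {
    k <- sample(0:(n * visits), 1)
    if (k > 0) ses[[col]][sample.int(n * visits, k)] <- NA
  }
  if (runif(1) < 0.3) demo$age_baseline[sample.int(n, 1)] <- NA
  dict <- variable_dictionary(list(
    variable_spec("sex", "demographic", "categorical",
                  accepted_codes = c(F = "f", M = "m")),
    variable_spec("age_baseline", "demographic", "real"),
    variable_spec("motor_score", "session", "real"),
    variable_spec("cognitive_score", "session", "integer")),
    study_label = paste0("rand", seed))
  list(tables = list(demo.csv = demo, visits.csv = ses), dict = dict,
       id_column = "pid", session_column = "visit")
}

count_table_cells <- function(tables, id_column, session_column = NULL) {
  sum(vapply(tables, function(tab) {
    cols <- setdiff(names(tab), c(id_column, session_column))
    sum(!is.na(as.matrix(tab[cols])))
  }, numeric(1)))
}

# look up the value the generated tables carry for one input cell
generated_cell <- function(tabs, pid, column, session = NULL) {
  if (is.null(session)) {
    row <- tabs$participants[tabs$participants$participant_id == pid, ]
    row[[column]]
  } else {
    for (tab in tabs$sessions) {
      if (!column %in% names(tab)) next
      hit <- tab$participant_id == pid & tab$session_id == session
      if (any(hit)) return(tab[[column]][hit])
    }
    NULL
  }
}
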