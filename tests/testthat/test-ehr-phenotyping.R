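# Fixture: 5 patients x 3 codes with known visit patterns, built in code.
make_toy_records <- function() {
  d <- function(x) as.Date(x)
  rbind(
    # P1: 250.00 on 3 distinct dates -> case
    data.frame(patient_id = "P1", code = "250.00",
               date = d(c("2012-01-01", "2012-02-01", "2012-03-01"))),
    # P2: 250.00 three times on ONE date -> 1 independent visit, not a case
    data.frame(patient_id = "P2", code = "250.00",
               date = d(rep("2012-01-15", 3))),
    # P3: 250.00 on 2 dates (one duplicated) -> not a case at min_visits = 3
    data.frame(patient_id = "P3", code = "250.00",
               date = d(c("2012-01-01", "2012-01-01", "2012-05-01"))),
    # P3: 401.1 on 4 distinct dates -> case
    data.frame(patient_id = "P3", code = "401.1",
               date = d(c("2012-01-02", "2012-03-02", "2012-06-02",
                          "2012-09-02"))),
    # P4: 401.1 on 3 distinct dates -> case
    data.frame(patient_id = "P4", code = "401.1",
               date = d(c("2013-01-01", "2013-01-02", "2013-01-03"))),
    # P5: V70.0 on 2 distinct dates -> not a case
    data.frame(patient_id = "P5", code = "V70.0",
               date = d(c("2012-07-01", "2012-08-01")))
  )
}

test_that("rule-of-three case definition counts distinct visit dates", {
  rec <- make_toy_records()
  expect_identical(define_cases(rec, "250.00"), "P1")
  expect_identical(define_cases(rec, "401.1"), c("P3", "P4"))
  expect_identical(define_cases(rec, "V70.0"), character(0))
  # relaxing the threshold admits more patients; tightening nests inside
  expect_identical(define_cases(rec, "250.00", min_visits = 1),
                   c("P1", "P2", "P3"))
  for (code in c("250.00", "401.1", "V70.0")) {
    for (k in 1:3) {
      expect_true(all(define_cases(rec, code, k + 1) %in%
                        define_cases(rec, code, k)))
    }
  }
  # empty record set
  expect_identical(
    define_cases(rec[0, ], "250.00"), character(0))
  expect_error(define_cases(rec, "not-a-code"), "malformed")
})

test_that("case counts per code match a brute-force recount exactly", {
  rec <- make_toy_records()
  tab <- case_counts_by_code(rec)
  expect_identical(tab$code, c("250.00", "401.1", "V70.0"))
  expect_identical(tab$n_cases, c(1L, 2L, 0L))
  bf <- brute_force_case_counts(rec, 3)
  expect_identical(as.data.frame(tab), bf)
  # min_visits = 1: distinct patients per code
  tab1 <- case_counts_by_code(rec, min_visits = 1)
  expect_identical(tab1$n_cases, c(3L, 2L, 1L))
  # duplicate records collapse (P2/P3 rows above already exercise this)
  expect_identical(as.data.frame(case_counts_by_code(rbind(rec, rec))),
                   bf)
})

test_that("threshold tabulation enumerates codes with at least t cases", {
  tab <- data.frame(code = c("001.0", "250.00", "401.1"),
                    n_cases = c(5L, 250L, 1200L))
  out <- tabulate_codes_by_threshold(tab, c(10, 200, 1000))
  expect_identical(out$threshold, c(10L, 200L, 1000L))
  expect_identical(out$n_codes, c(2L, 2L, 1L))
  expect_identical(tabulate_codes_by_threshold(tab, 1)$n_codes, 3L)
  expect_identical(tabulate_codes_by_threshold(tab, 5000)$n_codes, 0L)
  # non-increasing in the threshold (survival-curve shape)
  out <- tabulate_codes_by_threshold(tab, c(1, 2, 5, 10, 100, 251, 1500))
  expect_true(all(diff(out$n_codes) <= 0))
})

test_that("synthetic EHR generator matches its closed-form case-count oracle", {
  catalog <- data.frame(code = c("250.00", "401.1", "V70.0"),
                        prevalence = c(0.1, 0.02, 0),
                        visit_rate = c(5, 3, 4))
  set.seed(601)
  rec <- synth_ehr(1e4, catalog)
  expect_false("V70.0" %in% rec$code)  # zero prevalence -> absent
  counts <- case_counts_by_code(rec, min_visits = 3)
  p_case <- 0.1 * ppois(2, 5, lower.tail = FALSE)  # carriage x P(Pois(5) >= 3)
  got <- counts[counts$code == "250.00", ]$n_cases
  expect_lt(abs(got - 1e4 * p_case), 4 * sqrt(1e4 * p_case * (1 - p_case)))
  # brute-force recount agrees exactly on the generated set
  sub <- rec[rec$code == "401.1"]
  expect_identical(as.data.frame(case_counts_by_code(sub)),
                   brute_force_case_counts(sub))
  # reproducible under a fixed seed
  set.seed(601)
  rec2 <- synth_ehr(1e4, catalog)
  expect_identical(rec, rec2)
})

test_that("visit records round-trip through delimited text with validation", {
  rec <- make_toy_records()
  path <- tempfile(fileext = ".tsv")
  write_ehr_table(rec, path)
  back <- read_visit_records(path)
  expect_identical(as.data.frame(back),
                   as.data.frame(data.table::as.data.table(rec)))
  # malformed inputs are rejected with informative errors
  bad <- rec; bad$date <- as.character(bad$date); bad$date[2] <- "02/01/2012"
  pb <- tempfile(fileext = ".csv"); write.csv(bad, pb, row.names = FALSE)
  expect_error(read_visit_records(pb), "date")
  bad <- rec; bad$code <- as.character(bad$code); bad$code[1] <- "25A.00"
  pb2 <- tempfile(fileext = ".csv"); write.csv(bad, pb2, row.names = FALSE)
  expect_error(read_visit_records(pb2), "ICD-9")
  pb3 <- tempfile(fileext = ".csv")
  write.csv(rec[, c("patient_id", "date")], pb3, row.names = FALSE)
  expect_error(read_visit_records(pb3), "missing column")
})

test_that("ICD-9 lexical validation accepts numeric, V and E forms", {
  expect_true(all(is_icd9_code(c("250", "250.0", "250.00", "V70", "V70.0",
                                 "E880", "E880.1"))))
  expect_false(any(is_icd9_code(c("25", "2500", "250.000", "X12", "V7",
                                  "E88", "250-00", ""))))
})
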