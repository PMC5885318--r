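#' ICD-9 "rule of three" case definition
#'
#' To guard against one-off misdiagnoses, a patient counts as a case for an
#' ICD-9 code only when the code appears on at least `min_visits` independent
#' visits, where independent visits are distinct calendar dates for that
#' patient/code pair. Duplicate records (same patient, code and date) collapse
#' to one visit.
#'
#' @param records visit records: a `data.frame`/`data.table` with columns
#'   `patient_id`, `code`, `date` (see [read_visit_records()]).
#' @param code a single ICD-9 code string in 3-5 digit dotted form (e.g.
#'   `"250.00"`, `"V70.0"`, `"E880.1"`).
#' @param min_visits minimum number of distinct visit dates (default 3).
#' @return Sorted character vector of patient ids meeting the case definition.
#' @examples
#' rec <- data.frame(patient_id = "P1", code = "250.00",
#'                   date = as.Date("2012-01-01") + c(0, 30, 60))
#' define_cases(rec, "250.00")
#' @export
define_cases <- function(records, code, min_visits = 3L) {
  target <- code
  check_icd9_code(target)
  stopifnot(is.numeric(min_visits), length(min_visits) == 1, min_visits >= 1)
  dt <- as_visit_dt(records)
  sub <- unique(dt[code == target, list(patient_id, date)])
  if (nrow(sub) == 0L) return(character(0))
  counts <- sub[, list(N = .N), by = patient_id]
  sort(counts[N >= min_visits, patient_id])
}

#' Case counts per ICD-9 code
#'
#' Applies the case definition of [define_cases()] to every distinct code in
#' the records and returns one row per code with its case count (codes whose
#' patients never reach `min_visits` distinct dates get a count of 0).
#'
#' @inheritParams define_cases
#' @return `data.table` with columns `code`, `n_cases`, sorted by code.
#' @export
case_counts_by_code <- function(records, min_visits = 3L) {
  stopifnot(is.numeric(min_visits), length(min_visits) == 1, min_visits >= 1)
  dt <- as_visit_dt(records)
  uu <- unique(dt[, list(patient_id, code, date)])
  per <- uu[, list(N = .N), by = list(code, patient_id)]
  out <- per[, list(n_cases = sum(N >= min_visits)), by = code]
  data.table::setorder(out, code)
  out[]
}

#' Number of codes exceeding each case-count threshold
#'
#' For each threshold `t`, counts the codes with `n_cases >= t`. The resulting
#' curve is non-increasing in the threshold and shows how many phenotypes
#' survive a given minimum-case filter (e.g. the recommended 200-case cutoff
#' for common-variant PheWAS).
#'
#' @param table a [case_counts_by_code()] table (columns `code`, `n_cases`).
#' @param thresholds positive integer case-count thresholds.
#' @return `data.table` with columns `threshold`, `n_codes`, sorted by
#'   threshold.
#' @examples
#' tab <- data.frame(code = c("001.0", "250.00", "401.1"),
#'                   n_cases = c(5, 1200, 250))
#' tabulate_codes_by_threshold(tab, c(10, 200, 1000))
#' @export
tabulate_codes_by_threshold <- function(table, thresholds) {
  stopifnot(is.data.frame(table), all(c("code", "n_cases") %in% names(table)),
            is.numeric(thresholds), length(thresholds) >= 1,
            all(thresholds > 0))
  cnt <- table[["n_cases"]]
  stopifnot(all(cnt >= 0), all(cnt == floor(cnt)))
  th <- sort(unique(as.integer(thresholds)))
  data.table::data.table(
    threshold = th,
    n_codes = vapply(th, function(t) sum(cnt >= t), integer(1))
  )
}

#' Generate synthetic longitudinal EHR visit records
#'
#' Emulates sparse longitudinal ICD-9 coding so the phenotyping procedure can
#' be exercised without clinical data: each patient carries each code
#' independently with the code's `prevalence`; carriers receive a
#' `Poisson(visit_rate)` number of coded visits, dated uniformly over the
#' study window. The expected number of rule-of-three cases for a code is thus
#' approximately `n_patients * prevalence * P(Poisson(visit_rate) >= 3)`
#' (exactly, up to the rare collapse of two visits drawn on the same date).
#'
#' @param n_patients number of patients.
#' @param catalog `data.frame` with columns `code` (ICD-9 strings),
#'   `prevalence` (in `[0, 1]`) and `visit_rate` (Poisson mean, > 0).
#' @param start_date,end_date study window (ISO-8601 strings or `Date`s).
#' @return `data.table` of visit records with columns `patient_id`, `code`,
#'   `date`, sorted by patient, code, date.
#' @examples
#' set.seed(1)
#' cat1 <- data.frame(code = c("250.00", "401.1"),
#'                    prevalence = c(0.1, 0.05), visit_rate = c(5, 2))
#' synth_ehr(100, cat1)
#' @export
synth_ehr <- function(n_patients, catalog,
                      start_date = "2010-01-01", end_date = "2011-12-31") {
  stopifnot(is.numeric(n_patients), length(n_patients) == 1, n_patients >= 1,
            is.data.frame(catalog),
            all(c("code", "prevalence", "visit_rate") %in% names(catalog)))
  n_patients <- as.integer(n_patients)
  for (cc in catalog$code) check_icd9_code(cc)
  stopifnot(all(catalog$prevalence >= 0), all(catalog$prevalence <= 1),
            all(catalog$visit_rate > 0))
  days <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  stopifnot(length(days) >= 1)
  ids <- sprintf("P%06d", seq_len(n_patients))
  pieces <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    carriers <- which(runif(n_patients) < catalog$prevalence[i])
    if (length(carriers) == 0L) next
    nv <- rpois(length(carriers), catalog$visit_rate[i])
    keep <- nv > 0L
    if (!any(keep)) next
    carriers <- carriers[keep]
    nv <- nv[keep]
    pieces[[i]] <- data.table::data.table(
      patient_id = rep(ids[carriers], nv),
      code = catalog$code[i],
      date = days[sample.int(length(days), sum(nv), replace = TRUE)]
    )
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  code = character(0),
                                  date = as.Date(character(0))))
  }
  out <- data.table::rbindlist(pieces)
  data.table::setorder(out, patient_id, code, date)
  out[]
}

#' Read and write visit-record and phenotyping tables
#'
#' `read_visit_records()` reads a headered CSV/TSV file with columns
#' `patient_id`, `code`, `date` (ISO-8601) and validates codes and dates.
#' `write_ehr_table()` writes any of the module's tables as TSV.
#'
#' @param path file path.
#' @return `read_visit_records()`: a `data.table` of visit records.
#' @export
read_visit_records <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, colClasses = "character",
                          showProgress = FALSE)
  need <- c("patient_id", "code", "date")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as_visit_dt(dt[, need, with = FALSE])
}

#' @param x a table (`data.frame`/`data.table`) to serialise.
#' @rdname read_visit_records
#' @export
write_ehr_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

as_visit_dt <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("patient_id", "code", "date")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dt <- data.table::as.data.table(records)[, need, with = FALSE]
  dt[, patient_id := as.character(patient_id)]
  dt[, code := as.character(code)]
  chr <- as.character(dt$date)
  parsed <- as.Date(chr, format = "%Y-%m-%d")
  if (anyNA(parsed) || anyNA(chr)) {
    bad <- unique(chr[is.na(parsed) | is.na(chr)])
    stop("unparseable ISO-8601 date(s): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  dt[, date := parsed]
  bad_codes <- unique(dt$code[!is_icd9_code(dt$code)])
  if (length(bad_codes) > 0) {
    stop("malformed ICD-9 code(s): ",
         paste(utils::head(bad_codes, 3), collapse = ", "), call. = FALSE)
  }
  dt
}

#' ICD-9 code syntax check
#'
#' Accepts the 3-5 digit dotted forms: a three-digit numeric root (`"250"`,
#' `"250.0"`, `"250.00"`), V codes (`"V70"`, `"V70.0"`) and E codes
#' (`"E880"`, `"E880.1"`).
#'
#' @param x character vector of candidate codes.
#' @return Logical vector.
#' @export
is_icd9_code <- function(x) {
  grepl("^([0-9]{3}|V[0-9]{2}|E[0-9]{3})(\\.[0-9]{1,2})?$", x)
}

check_icd9_code <- function(code) {
  if (!is.character(code) || length(code) != 1 || !is_icd9_code(code)) {
    stop(sprintf("malformed ICD-9 code: %s",
                 paste(as.character(code), collapse = ", ")), call. = FALSE)
  }
  invisible(code)
}
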