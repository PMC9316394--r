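#' Canonical cohort column names
#'
#' The thirteen per-patient columns every cohort table carries: ten risk
#' factors plus follow-up `time` (days) and the death indicator `event`.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("age", "anaemia", "cpk", "diabetes", "ejection_fraction", "high_bp",
    "platelets", "serum_creatinine", "serum_sodium", "sex", "smoking",
    "time", "event")
}

cohort_binary_columns <- function() {
  c("anaemia", "diabetes", "high_bp", "sex", "smoking", "event")
}

cohort_covariates <- function() {
  setdiff(cohort_columns(), c("time", "event"))
}

#' Default CSV header mapping for heart-failure cohort files
#'
#' Maps the package's canonical column names to the header names used in the
#' widely circulated heart-failure clinical-records CSV
#' (`DEATH_EVENT`, `creatinine_phosphokinase`, `high_blood_pressure`, ...).
#'
#' @return Named character vector: canonical name -> CSV header.
#' @export
default_column_map <- function() {
  c(age = "age",
    anaemia = "anaemia",
    cpk = "creatinine_phosphokinase",
    diabetes = "diabetes",
    ejection_fraction = "ejection_fraction",
    high_bp = "high_blood_pressure",
    platelets = "platelets",
    serum_creatinine = "serum_creatinine",
    serum_sodium = "serum_sodium",
    sex = "sex",
    smoking = "smoking",
    time = "time",
    event = "DEATH_EVENT")
}

#' Validate a cohort table
#'
#' Checks the per-patient invariants: all thirteen canonical columns present
#' and numeric with no missing values; follow-up `time > 0`; binary columns
#' in \{0, 1\}; ejection fraction in (0, 100]; age, CPK, platelets, serum
#' creatinine and serum sodium strictly positive.
#'
#' @param cohort A data frame with the canonical cohort columns.
#' @param allow_empty If `TRUE`, a zero-row table passes (used by the
#'   synthetic generator); fitting functions require rows.
#' @return The cohort, invisibly, as a tibble.
#' @export
validate_cohort <- function(cohort, allow_empty = FALSE) {
  if (!is.data.frame(cohort)) stop_symcox("`cohort` must be a data frame")
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop_symcox(
      sprintf("cohort is missing required columns: %s",
              paste(missing_cols, collapse = ", ")),
      class = "symcox_error_columns"
    )
  }
  if (nrow(cohort) == 0L) {
    if (allow_empty) return(invisible(cohort))
    stop_symcox("cohort has zero rows", class = "symcox_error_empty")
  }
  for (col in cohort_columns()) {
    v <- cohort[[col]]
    if (!is.numeric(v)) stop_symcox(sprintf("column `%s` is not numeric", col))
    if (anyNA(v)) {
      stop_symcox(sprintf("column `%s` has missing values (row %d)",
                          col, which(is.na(v))[1L]),
                  class = "symcox_error_missing")
    }
  }
  check_pos <- function(col, strict_msg) {
    bad <- which(cohort[[col]] <= 0)
    if (length(bad)) {
      stop_symcox(sprintf("column `%s` must be %s (row %d has %g)",
                          col, strict_msg, bad[1L], cohort[[col]][bad[1L]]))
    }
  }
  for (col in c("age", "cpk", "platelets", "serum_creatinine",
                "serum_sodium", "time")) {
    check_pos(col, "strictly positive")
  }
  for (col in cohort_binary_columns()) {
    bad <- which(!cohort[[col]] %in% c(0, 1))
    if (length(bad)) {
      stop_symcox(sprintf("binary column `%s` has value %g at row %d",
                          col, cohort[[col]][bad[1L]], bad[1L]))
    }
  }
  ef_bad <- which(cohort$ejection_fraction <= 0 | cohort$ejection_fraction > 100)
  if (length(ef_bad)) {
    stop_symcox(sprintf("ejection_fraction must lie in (0, 100] (row %d has %g)",
                        ef_bad[1L], cohort$ejection_fraction[ef_bad[1L]]))
  }
  invisible(cohort)
}

#' Read a heart-failure cohort CSV
#'
#' Reads a comma-separated file with a header row and period decimal point,
#' maps its headers onto the package's canonical column names, validates the
#' per-patient invariants, and returns the cohort as a tibble with one row
#' per patient. Row order is preserved. Missing or non-numeric cells are hard
#' errors (the deposited cohort is complete); the error names the offending
#' row and column.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping canonical names
#'   (see `cohort_columns`) to the file's headers. Defaults to
#'   [default_column_map()], the circulated `DEATH_EVENT` dialect.
#' @return A tibble with columns `age`, `anaemia`, `cpk`, `diabetes`,
#'   `ejection_fraction`, `high_bp`, `platelets`, `serum_creatinine`,
#'   `serum_sodium`, `sex`, `smoking`, `time`, `event`.
#' @seealso [write_cohort_csv()], [summarize_cohort()]
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop_symcox(sprintf("file not found: %s", path), class = "symcox_error_io")
  }
  column_map <- column_map %||% default_column_map()
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent)) {
    stop_symcox(sprintf("CSV is missing mapped columns: %s",
                        paste(absent, collapse = ", ")),
                class = "symcox_error_columns")
  }
  if (nrow(raw) == 0L) {
    stop_symcox("CSV contains a header but zero data rows",
                class = "symcox_error_empty")
  }
  out <- purrr::imap(column_map, function(hdr, canonical) {
    txt <- raw[[hdr]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & !is.na(txt))
    if (length(bad)) {
      stop_symcox(sprintf("non-numeric value \"%s\" in column `%s`, row %d",
                          txt[bad[1L]], hdr, bad[1L]),
                  class = "symcox_error_parse")
    }
    na <- which(is.na(txt))
    if (length(na)) {
      stop_symcox(sprintf("missing value in column `%s`, row %d", hdr, na[1L]),
                  class = "symcox_error_missing")
    }
    val
  })
  cohort <- tibble::as_tibble(out)[, cohort_columns()]
  validate_cohort(cohort)
  cohort
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: writes the canonical cohort columns under
#' the headers given by `column_map`, so synthetic and real cohorts share one
#' on-disk dialect.
#'
#' @inheritParams read_cohort_csv
#' @param cohort A validated cohort tibble.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, column_map = NULL) {
  cohort <- validate_cohort(cohort, allow_empty = TRUE)
  column_map <- column_map %||% default_column_map()
  out <- cohort[, cohort_columns()]
  names(out) <- unname(column_map[cohort_columns()])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Cohort summary table
#'
#' Per-column summaries in the style of a clinical baseline table: mean, SD
#' (n - 1 denominator), minimum, quartiles (linear interpolation between
#' order statistics, i.e. `stats::quantile()` type 7) and maximum for
#' continuous columns; count and percentage of each level for binary
#' columns. Invariant to row order.
#'
#' @param cohort A validated cohort tibble.
#' @return A tibble with one row per column: `variable`, `type`, `mean`,
#'   `sd`, `min`, `q25`, `median`, `q75`, `max`, `n1`, `pct1` (count and
#'   percent of the 1 level; `NA` for continuous variables).
#' @export
summarize_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  bin <- cohort_binary_columns()
  purrr::map_dfr(cohort_columns(), function(col) {
    v <- cohort[[col]]
    if (col %in% bin) {
      tibble::tibble(
        variable = col, type = "binary",
        mean = mean(v), sd = stats::sd(v),
        min = NA_real_, q25 = NA_real_, median = NA_real_,
        q75 = NA_real_, max = NA_real_,
        n1 = sum(v == 1), pct1 = 100 * mean(v == 1)
      )
    } else {
      q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
      tibble::tibble(
        variable = col, type = "continuous",
        mean = mean(v), sd = stats::sd(v),
        min = min(v), q25 = q[1], median = q[2], q75 = q[3], max = max(v),
        n1 = NA_real_, pct1 = NA_real_
      )
    }
  })
}

#' Render a cohort summary as aligned text
#'
#' @param summary A tibble from [summarize_cohort()].
#' @return A character vector of aligned lines, invisibly printed.
#' @export
summary_text <- function(summary) {
  num <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 4))
  body <- dplyr::mutate(summary, dplyr::across(dplyr::where(is.numeric), num))
  widths <- purrr::map_int(names(body), function(nm) {
    max(nchar(nm), max(nchar(as.character(body[[nm]]))))
  })
  fmt_row <- function(vals) {
    paste(purrr::map2_chr(as.character(vals), widths, formatC, flag = "-"),
          collapse = "  ")
  }
  lines <- c(fmt_row(names(body)),
             purrr::pmap_chr(body, function(...) fmt_row(list(...))))
  lines
}
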