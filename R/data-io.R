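#' Read a per-nucleus scoring table
#'
#' Reads a tab-delimited table with one row per scored nucleus per probe.
#' Required columns: `experiment_id`, `individual_id`, `sex`
#' (`homogametic`/`heterogametic`), `probe_id`, `control_signals`,
#' `test_signals`. Signal counts must be non-negative integers; values above 4
#' are rejected (more than four signals in a nucleus indicates an upstream
#' scoring problem), values of 3-4 are kept and flag polyploidy downstream.
#'
#' Malformed rows are dropped from the returned tibble and collected, with
#' their line numbers in the source file, in the `row_errors` attribute
#' (retrievable with [row_errors()]). A missing required column is an error.
#'
#' @param path Path to a TSV file.
#' @return A tibble of nucleus records; attribute `row_errors` holds a tibble
#'   with columns `line` and `message` for rows that failed validation.
#' @seealso [write_nucleus_table()], [filter_diploid()]
#' @export
read_nucleus_table <- function(path) {
  raw <- read_checked_tsv(path, c(
    "experiment_id", "individual_id", "sex", "probe_id",
    "control_signals", "test_signals"
  ))
  validate_nucleus_rows(raw)
}

#' Write a per-nucleus scoring table
#'
#' Inverse of [read_nucleus_table()]; round-trips losslessly.
#'
#' @param records A tibble of nucleus records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_nucleus_table <- function(records, path) {
  records <- validate_nucleus_records(records)
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read a locus/probe panel table
#'
#' Panel TSV columns: `probe_id`, `species`, `chromosome`, `locus_class`
#' (`autosomal`, `sex_specific` or `pseudoautosomal`), `start`, `end`
#' (0-based half-open base-pair coordinates) and `genes` (comma-joined gene
#' names). Probe ids must be unique and `start < end`.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per probe.
#' @export
read_panel <- function(path) {
  raw <- read_checked_tsv(path, c(
    "probe_id", "species", "chromosome", "locus_class", "start", "end", "genes"
  ))
  raw$start <- as_count(raw$start)
  raw$end <- as_count(raw$end)
  validate_panel(raw)
}

#' Write a locus/probe panel table
#' @param panel A panel tibble (see [read_panel()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  readr::write_tsv(panel, path)
  invisible(path)
}

#' Read a two-color gene-pair scoring table
#'
#' One row per nucleus scored in a two-probe experiment. Columns:
#' `experiment_id`, `probe_a`, `probe_b`, `signals_a`, `signals_b` (0-2) and
#' `colocated` (0/1/NA). `colocated` must be non-missing exactly when both
#' probes show a single signal (the only configuration in which co-location
#' of the two signals identifies a single active chromosome).
#'
#' @param path Path to a TSV file.
#' @return A tibble of pair records.
#' @export
read_pair_table <- function(path) {
  raw <- read_checked_tsv(path, c(
    "experiment_id", "probe_a", "probe_b", "signals_a", "signals_b", "colocated"
  ))
  validate_pair_records(raw)
}

#' Write a two-color gene-pair scoring table
#' @param records A tibble of pair records (see [read_pair_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(records, path) {
  records <- validate_pair_records(records)
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read a pre-aggregated signal-count summary table
#'
#' Accepts published-style aggregated tables directly: one row per
#' (probe, sex) with columns `probe_id`, `sex`, `n2`, `n1`, `n0` (counts of
#' nuclei with two, one and zero test-probe signals among scored diploid
#' nuclei). `n_scored` is derived as `n2 + n1 + n0`.
#'
#' @param path Path to a TSV file.
#' @return A summary tibble as produced by [summarize_counts()].
#' @export
read_summary_table <- function(path) {
  raw <- read_checked_tsv(path, c("probe_id", "sex", "n2", "n1", "n0"))
  for (col in c("n2", "n1", "n0")) {
    raw[[col]] <- as_count(raw[[col]])
    if (anyNA(raw[[col]])) {
      abort_validation(sprintf("column '%s' must contain non-negative integers", col))
    }
  }
  if (!all(raw$sex %in% .sexes)) {
    abort_validation("sex must be 'homogametic' or 'heterogametic'")
  }
  raw$n_scored <- raw$n2 + raw$n1 + raw$n0
  raw$n_gt2 <- rep(0L, nrow(raw))
  as_tibble(raw[, c("probe_id", "sex", "n_scored", "n2", "n1", "n0", "n_gt2")])
}

#' Row-level validation failures from a reader
#'
#' @param x A tibble returned by [read_nucleus_table()].
#' @return A tibble with columns `line` and `message` (zero rows if the file
#'   was fully well-formed).
#' @export
row_errors <- function(x) {
  errs <- attr(x, "row_errors")
  if (is.null(errs)) {
    errs <- tibble(line = integer(), message = character())
  }
  errs
}

# ---- internal helpers -------------------------------------------------------

read_checked_tsv <- function(path, required) {
  if (!file.exists(path)) {
    abort_io(sprintf("file not found: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "missing required column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  raw
}

# Strict integer parse: "2" -> 2L, "two"/"2.5"/"" -> NA
as_count <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[0-9]+$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(x[ok])
  out
}

validate_nucleus_rows <- function(raw) {
  n <- nrow(raw)
  # line numbers in the file: header is line 1
  line <- seq_len(n) + 1L
  control <- as_count(raw$control_signals)
  test <- as_count(raw$test_signals)
  problems <- character(n)
  bad <- is.na(control) | is.na(test)
  problems[bad] <- "signal counts must be non-negative integers"
  out_of_range <- !bad & (control > 4L | test > 4L)
  problems[out_of_range] <- "signal counts above 4 are not accepted"
  bad_sex <- !nzchar(problems) & !(raw$sex %in% .sexes)
  problems[bad_sex] <- "sex must be 'homogametic' or 'heterogametic'"
  keep <- !nzchar(problems)
  records <- tibble(
    experiment_id = raw$experiment_id[keep],
    individual_id = raw$individual_id[keep],
    sex = raw$sex[keep],
    probe_id = raw$probe_id[keep],
    control_signals = control[keep],
    test_signals = test[keep]
  )
  errs <- tibble(line = line[!keep], message = problems[!keep])
  if (nrow(errs) > 0) {
    warn(sprintf("%d malformed row(s) dropped; see row_errors()", nrow(errs)))
  }
  attr(records, "row_errors") <- errs
  records
}

validate_nucleus_records <- function(records) {
  required <- c("experiment_id", "individual_id", "sex", "probe_id",
                "control_signals", "test_signals")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "nucleus records lack column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  if (!all(records$sex %in% .sexes)) {
    abort_validation("sex must be 'homogametic' or 'heterogametic'")
  }
  if (any(records$control_signals < 0) || any(records$test_signals < 0)) {
    abort_validation("signal counts must be non-negative")
  }
  as_tibble(records)
}

validate_panel <- function(panel) {
  required <- c("probe_id", "species", "chromosome", "locus_class",
                "start", "end", "genes")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "panel lacks column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(panel$probe_id)) {
    abort_validation("probe_id must be unique within a panel")
  }
  if (!all(panel$locus_class %in% .locus_classes)) {
    abort_validation(sprintf(
      "locus_class must be one of: %s", paste(.locus_classes, collapse = ", ")
    ))
  }
  if (any(panel$start >= panel$end)) {
    abort_validation("panel coordinates must satisfy start < end (0-based half-open)")
  }
  as_tibble(panel)
}

validate_pair_records <- function(records) {
  required <- c("experiment_id", "probe_a", "probe_b",
                "signals_a", "signals_b", "colocated")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "pair records lack column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  records <- as_tibble(records)
  records$signals_a <- as.integer(records$signals_a)
  records$signals_b <- as.integer(records$signals_b)
  if (is.character(records$colocated)) {
    v <- toupper(records$colocated)
    lg <- as.logical(v) # handles TRUE/FALSE/T/F/NA
    num <- suppressWarnings(as.integer(v))
    lg[is.na(lg) & !is.na(num)] <- num[is.na(lg) & !is.na(num)] > 0
    records$colocated <- lg
  } else {
    records$colocated <- as.logical(records$colocated)
  }
  if (any(records$signals_a < 0 | records$signals_a > 2 |
          records$signals_b < 0 | records$signals_b > 2)) {
    abort_validation("signals_a and signals_b must be in 0..2")
  }
  both_mono <- records$signals_a == 1L & records$signals_b == 1L
  if (any(both_mono & is.na(records$colocated))) {
    abort_validation("colocated must be scored when both probes show one signal")
  }
  if (any(!both_mono & !is.na(records$colocated))) {
    abort_validation("colocated is defined only when both probes show one signal")
  }
  records
}
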