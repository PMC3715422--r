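#' Restrict scoring to diploid nuclei
#'
#' Only nuclei showing exactly two signals from the autosomal control probe are
#' scored for the test probe: the control both rules out polyploid nuclei
#' (tetraploid nuclei show extra control signals) and confirms the probe mix
#' penetrated the nucleus. Everything else is excluded.
#'
#' @param records A tibble of nucleus records (see [read_nucleus_table()]).
#' @return A list with tibbles `kept` (control_signals == 2) and `excluded`
#'   (all other records). The two partitions the input exactly.
#' @export
filter_diploid <- function(records) {
  records <- validate_nucleus_records(records)
  if (nrow(records) == 0) {
    abort_validation("no nucleus records to filter")
  }
  is_diploid <- records$control_signals == 2L
  list(kept = records[is_diploid, ], excluded = records[!is_diploid, ])
}

#' Tally nuclei by test-signal count for one probe and sex
#'
#' Counts, among already diploid-filtered records for the requested probe and
#' sex, the nuclei with two (`n2`), one (`n1`) and zero (`n0`) test-probe
#' signals. Nuclei with more than two test signals in a diploid nucleus are an
#' anomaly (reported in `n_gt2`) and never folded into `n2`; `n_scored`
#' counts only the 0/1/2 classes.
#'
#' @param records Diploid-filtered nucleus records.
#' @param probe Probe id to tally.
#' @param sex `"homogametic"` or `"heterogametic"`.
#' @return A one-row tibble: `probe_id`, `sex`, `n_scored`, `n2`, `n1`, `n0`,
#'   `n_gt2`.
#' @export
summarize_counts <- function(records, probe, sex) {
  sex <- arg_match(sex, .sexes)
  records <- validate_nucleus_records(records)
  sub <- records[records$probe_id == probe & records$sex == sex, ]
  if (nrow(sub) == 0) {
    abort_validation(sprintf("no records for probe '%s' in %s nuclei", probe, sex))
  }
  tally_signals(sub$test_signals, probe, sex)
}

#' Tally nuclei by test-signal count for every (probe, sex) present
#'
#' Vectorised companion of [summarize_counts()].
#'
#' @param records Diploid-filtered nucleus records.
#' @return A tibble with one row per (probe_id, sex) combination observed.
#' @export
summarize_counts_all <- function(records) {
  records <- validate_nucleus_records(records)
  records %>%
    group_by(.data$probe_id, .data$sex) %>%
    summarise(tally_signals(.data$test_signals, .data$probe_id[1], .data$sex[1])[
      , c("n_scored", "n2", "n1", "n0", "n_gt2")],
      .groups = "drop")
}

tally_signals <- function(test_signals, probe, sex) {
  n2 <- sum(test_signals == 2L)
  n1 <- sum(test_signals == 1L)
  n0 <- sum(test_signals == 0L)
  n_gt2 <- sum(test_signals > 2L)
  tibble(
    probe_id = probe, sex = sex,
    n_scored = n2 + n1 + n0,
    n2 = n2, n1 = n1, n0 = n0, n_gt2 = n_gt2
  )
}

validate_summary <- function(summary) {
  required <- c("probe_id", "sex", "n_scored", "n2", "n1", "n0")
  missing <- setdiff(required, names(summary))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "signal-count summary lacks column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  if (any(summary$n2 + summary$n1 + summary$n0 != summary$n_scored)) {
    abort_validation("summary counts must satisfy n2 + n1 + n0 = n_scored")
  }
  if (any(summary$n2 < 0 | summary$n1 < 0 | summary$n0 < 0)) {
    abort_validation("summary counts must be non-negative")
  }
  as_tibble(summary)
}
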