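#' Exact (Garwood) Poisson confidence limits
#'
#' Exact two-sided confidence limits for the mean of a Poisson count `k`, from
#' chi-square quantiles: `low = qchisq(alpha/2, 2k) / 2` (0 when `k = 0`) and
#' `high = qchisq(1 - alpha/2, 2k + 2) / 2`, with `alpha = 1 - level`.
#'
#' @param k Non-negative integer count(s).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `k`, `low`, `high`.
#' @export
poisson_exact_ci <- function(k, level = 0.95) {
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1) {
    abort_validation("level must lie strictly between 0 and 1")
  }
  if (any(k < 0) || any(k != floor(k)) || anyNA(k)) {
    abort_validation("k must be a non-negative integer count")
  }
  alpha <- 1 - level
  low <- ifelse(k == 0, 0, qchisq(alpha / 2, df = 2 * k) / 2)
  high <- qchisq(1 - alpha / 2, df = 2 * k + 2) / 2
  tibble(k = k, low = low, high = high)
}

#' Bound the experimental error rate from autosomal controls
#'
#' Autosomal loci are transcribed from both alleles in essentially every
#' nucleus, so each scored diploid nucleus should show two signals; every
#' shortfall is a missed hybridization. Pooling autosomal experiments from both
#' sexes, the number of missed signals is `2 * n0 + n1` against
#' `2 * n_scored` expected. Treating the missed count as Poisson, the upper
#' exact 95% confidence limit divided by the expected signal count gives a
#' conservative bound on the per-signal experimental error rate, used by
#' [adjust_and_retest()].
#'
#' @param summaries Signal-count summaries (rows as from [summarize_counts()])
#'   for autosomal control loci, both sexes. If a `locus_class` column is
#'   present, any non-autosomal row is a validation error.
#' @param level Confidence level for the Poisson limits; default 0.95.
#' @return A one-row tibble: `n_experiments`, `n_nuclei`, `expected_signals`,
#'   `missed`, `raw_rate`, `ci_low`, `ci_high`, `max_error_rate`.
#' @export
estimate_error <- function(summaries, level = 0.95) {
  summaries <- validate_summary(summaries)
  if (nrow(summaries) == 0) {
    abort_validation("no autosomal summaries supplied")
  }
  if ("locus_class" %in% names(summaries) &&
      any(summaries$locus_class != "autosomal")) {
    abort_validation("error estimation uses autosomal (obligate biallelic) loci only")
  }
  n_nuclei <- sum(summaries$n_scored)
  expected_signals <- 2L * n_nuclei
  missed <- sum(2L * summaries$n0 + summaries$n1)
  ci <- poisson_exact_ci(missed, level = level)
  tibble(
    n_experiments = nrow(summaries),
    n_nuclei = n_nuclei,
    expected_signals = expected_signals,
    missed = missed,
    raw_rate = missed / expected_signals,
    ci_low = ci$low,
    ci_high = ci$high,
    max_error_rate = ci$high / expected_signals
  )
}
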