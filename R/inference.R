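#' Estimate probe hybridization efficiency from the heterogametic sex
#'
#' In the heterogametic sex a sex-specific locus is present in a single copy,
#' so every nucleus carries exactly one transcribing allele and the fraction of
#' nuclei showing the expected single signal estimates the per-allele detection
#' probability `p` of the probe: `p_hat = n1 / (n1 + n0)`. Nuclei with two
#' signals should not occur for a single-copy locus; they are excluded from the
#' estimate and trigger a warning.
#'
#' @param summary A one-row signal-count summary (see [summarize_counts()])
#'   from heterogametic nuclei at a sex-specific locus.
#' @return A one-row tibble: `probe_id`, `p_hat`, `q_hat = 1 - p_hat`, `n_het`
#'   (nuclei used).
#' @export
estimate_efficiency <- function(summary) {
  summary <- validate_summary(summary)
  if (nrow(summary) != 1) {
    abort_validation("estimate_efficiency expects a single (probe, sex) summary row")
  }
  if (summary$sex != "heterogametic") {
    abort_validation("hybridization efficiency is estimated from heterogametic nuclei")
  }
  if (summary$n2 > 0) {
    warn(sprintf(
      "probe '%s': %d heterogametic nuclei show two signals at a single-copy locus",
      summary$probe_id, summary$n2
    ))
  }
  n_het <- summary$n1 + summary$n0
  if (n_het == 0) {
    abort_validation(sprintf(
      "probe '%s': no informative heterogametic nuclei, efficiency undefined",
      summary$probe_id
    ))
  }
  p_hat <- summary$n1 / n_het
  tibble(probe_id = summary$probe_id, p_hat = p_hat, q_hat = 1 - p_hat,
         n_het = n_het)
}

#' Expected signal-count distribution under full biallelic transcription
#'
#' If both alleles transcribe in every nucleus and each transcribing allele is
#' detected independently with probability `p`, nuclei show two, one or zero
#' signals with frequencies `p^2`, `2pq` and `q^2` (`q = 1 - p`). Departures
#' from this null — an excess of single-signal nuclei — indicate that one
#' allele is silenced in a fraction of cells rather than merely undetected.
#'
#' @param p Hybridization efficiency (scalar or vector of probabilities).
#' @return A tibble with columns `f2`, `f1`, `f0` summing to 1 per row.
#' @export
null_distribution <- function(p) {
  if (any(p < 0 | p > 1) || anyNA(p)) {
    abort_validation("efficiency p must lie in [0, 1]")
  }
  q <- 1 - p
  tibble(f2 = p^2, f1 = 2 * p * q, f0 = q^2)
}

#' Chi-square test of observed signal counts against the detection null
#'
#' Pearson goodness-of-fit of the observed (two, one, zero)-signal nucleus
#' counts in the homogametic sex against the binomial detection null
#' (`p^2`, `2pq`, `q^2`) at the probe's estimated efficiency, with 2 degrees
#' of freedom. A significant excess of single-signal nuclei indicates that the
#' locus is silenced on one chromosome in a fraction of cells.
#'
#' When the efficiency is near 1 the expected zero-signal count can drop below
#' 1; the three-category test is still reported (with a warning) and the
#' error-adjusted two-category test of [adjust_and_retest()] is the primary
#' inference. An expected count of exactly zero with non-zero observations
#' yields an infinite statistic, reported as `p_value = 0` with
#' `degenerate = TRUE`.
#'
#' @param observed A one-row signal-count summary from homogametic nuclei.
#' @param efficiency Either the tibble returned by [estimate_efficiency()] or
#'   a probability.
#' @return A one-row tibble: `chi2`, `df` (2), `p_value`, `degenerate`.
#' @export
test_inactivation <- function(observed, efficiency) {
  observed <- validate_summary(observed)
  p <- efficiency_value(efficiency)
  if (observed$n_scored <= 0) {
    abort_validation("no scored nuclei to test")
  }
  nd <- null_distribution(p)
  O <- c(observed$n2, observed$n1, observed$n0)
  E <- observed$n_scored * c(nd$f2, nd$f1, nd$f0)
  if (any(E == 0 & O > 0)) {
    return(tibble(chi2 = Inf, df = 2L, p_value = 0, degenerate = TRUE))
  }
  use <- E > 0 # E == 0 implies O == 0 here; the category carries no information
  if (any(E[use] < 1)) {
    warn("expected count below 1 in the 3-category test; rely on the error-adjusted 1-df test")
  }
  chi2 <- sum((O[use] - E[use])^2 / E[use])
  tibble(chi2 = chi2, df = 2L,
         p_value = pchisq(chi2, df = 2, lower.tail = FALSE),
         degenerate = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size and caps at 1, preserving input
#' order. The family size may exceed the number of p-values supplied (e.g.
#' when a run tests more loci than are being corrected in this call).
#'
#' @param p_values Numeric vector of p-values.
#' @param family_size Number of tests in the family; must be at least
#'   `length(p_values)`.
#' @return Corrected p-values, same length and order as the input.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (length(family_size) != 1 || is.na(family_size) || family_size < 1) {
    abort_validation("family_size must be a positive integer")
  }
  if (family_size < length(p_values)) {
    abort_validation("family_size must be at least the number of p-values")
  }
  pmin(1, p_values * family_size)
}

#' Estimate the per-locus silencing probability
#'
#' Method-of-moments estimate of the probability `s` that the allele on the
#' inactivatable chromosome is silenced in a given nucleus. Under the
#' generative model the single-signal fraction among scored homogametic nuclei
#' is `2pq + s * p * (2p - 1)`, so the excess over the detection null,
#' renormalized, gives `s_hat = (f1_obs - 2pq) / (p * (2p - 1))`, clamped to
#' `[0, 1]`. Requires `p > 0.5` (always true for usable FISH probes, whose
#' efficiencies run well above 90%).
#'
#' @inheritParams test_inactivation
#' @return The estimate `s_hat` as a single number.
#' @export
estimate_silencing <- function(observed, efficiency) {
  observed <- validate_summary(observed)
  p <- efficiency_value(efficiency)
  if (p <= 0.5) {
    abort_validation("silencing is not identifiable from the 1-signal fraction when p <= 0.5")
  }
  f1_obs <- observed$n1 / observed$n_scored
  s_hat <- (f1_obs - 2 * p * (1 - p)) / (p * (2 * p - 1))
  min(1, max(0, s_hat))
}

efficiency_value <- function(efficiency) {
  if (is.data.frame(efficiency)) {
    if (!"p_hat" %in% names(efficiency) || nrow(efficiency) != 1) {
      abort_validation("efficiency must be a probability or a one-row estimate with p_hat")
    }
    efficiency <- efficiency$p_hat
  }
  if (!is.numeric(efficiency) || length(efficiency) != 1 ||
      is.na(efficiency) || efficiency < 0 || efficiency > 1) {
    abort_validation("efficiency must be a single probability in [0, 1]")
  }
  efficiency
}
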