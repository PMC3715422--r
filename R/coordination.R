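#' Co-location fraction among jointly monoallelic nuclei
#'
#' In a two-color experiment, nuclei in which both neighbouring loci show
#' exactly one signal are informative about whether the two active alleles sit
#' on the same chromosome: closely linked signals from the same chromosome
#' co-locate, signals from homologues do not. A co-location fraction near 1
#' supports a single active chromosome shared by the pair.
#'
#' @param pairs A tibble of pair records (see [read_pair_table()]).
#' @return A one-row tibble: `fraction`, `n` (eligible nuclei). When no
#'   nucleus is eligible the fraction is `NA` and `n = 0`.
#' @export
colocation_fraction <- function(pairs) {
  pairs <- validate_pair_records(pairs)
  eligible <- pairs$signals_a == 1L & pairs$signals_b == 1L
  n <- sum(eligible)
  if (n == 0) {
    return(tibble(fraction = NA_real_, n = 0L))
  }
  tibble(fraction = sum(pairs$colocated[eligible]) / n, n = n)
}

#' Expected joint biallelic frequency under independence
#'
#' If silencing of two neighbouring loci is independent, the fraction of
#' nuclei biallelic at both is the product of the marginal biallelic
#' fractions (taken from the single-probe experiments).
#'
#' @param f2_a,f2_b Marginal 2-active fractions in `[0, 1]`.
#' @return The product, as a fraction.
#' @export
expected_joint_biallelic <- function(f2_a, f2_b) {
  if (any(c(f2_a, f2_b) < 0 | c(f2_a, f2_b) > 1) || anyNA(c(f2_a, f2_b))) {
    abort_validation("marginal fractions must lie in [0, 1]")
  }
  f2_a * f2_b
}

#' Test joint biallelic frequency against the independence expectation
#'
#' Pearson 1-df chi-square of the two-category table (jointly biallelic vs
#' not) against the product-of-marginals expectation, with Bonferroni
#' correction over the pairs tested in the run. An observed frequency
#' significantly above expectation indicates coordinated (regional) control of
#' silencing; agreement indicates independent, gene-by-gene silencing.
#'
#' @param observed_joint Number of nuclei biallelic at both loci (may be
#'   non-integer when derived from a published percentage).
#' @param n Number of scored diploid nuclei.
#' @param expected_fraction Expected joint fraction in (0, 1), from
#'   [expected_joint_biallelic()].
#' @param family_size Bonferroni family (number of pairs tested); default 1.
#' @return A one-row tibble: `chi2`, `df` (1), `p_value`, `p_adj`.
#' @export
test_coordination <- function(observed_joint, n, expected_fraction,
                              family_size = 1) {
  if (n <= 0 || observed_joint < 0 || observed_joint > n) {
    abort_validation("observed_joint must lie in [0, n] with n > 0")
  }
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    abort_validation("expected_fraction must lie strictly between 0 and 1")
  }
  O <- c(observed_joint, n - observed_joint)
  E <- n * c(expected_fraction, 1 - expected_fraction)
  chi2 <- sum((O - E)^2 / E)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble(chi2 = chi2, df = 1L, p_value = p,
         p_adj = pmin(1, p * max(family_size, 1)))
}

#' Classify pairs as independently or coordinately silenced
#'
#' A pair is called `coordinated_escape` when its joint biallelic frequency is
#' significantly above the independence expectation (corrected p below
#' `alpha` and observed above expected); otherwise `independent_escape`. A
#' significant deficit (observed below expected) is still classed
#' `independent_escape` but raises an anti-coordination warning, since the
#' model offers no mechanism for it.
#'
#' @param pair_results A tibble with at least `observed_joint_pct`,
#'   `expected_joint_pct`, `p_adj` per pair (as from [analyze_pairs()]).
#' @param alpha Significance threshold; default 0.01.
#' @return The input with a `regime` column added.
#' @export
classify_regime <- function(pair_results, alpha = 0.01) {
  required <- c("observed_joint_pct", "expected_joint_pct", "p_adj")
  missing <- setdiff(required, names(pair_results))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "pair results lack column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  excess <- pair_results$observed_joint_pct > pair_results$expected_joint_pct
  sig <- pair_results$p_adj < alpha
  if (any(sig & !excess)) {
    warn("significant joint-biallelic deficit for at least one pair (anti-coordination)")
  }
  pair_results$regime <- ifelse(sig & excess, "coordinated_escape",
                                "independent_escape")
  pair_results
}

#' Full neighbouring-pair coordination analysis
#'
#' For each (probe_a, probe_b) pair present in `pairs`: co-location fraction
#' among jointly monoallelic nuclei, observed joint biallelic fraction over
#' all scored nuclei, independence expectation from the supplied marginals,
#' the 1-df chi-square test and the regime call.
#'
#' @param pairs Pair records (see [read_pair_table()]), already
#'   diploid-filtered upstream.
#' @param marginals Tibble (`probe_id`, `f2`) of marginal 2-active fractions
#'   from the single-probe experiments.
#' @param alpha Significance threshold after correction; default 0.01.
#' @param family_size Bonferroni family; defaults to the number of pairs.
#' @return A tibble, one row per pair: `pair`, `n_scored_joint`,
#'   `n_both_monoallelic`, `colocation_fraction`, `expected_joint_pct`,
#'   `observed_joint_pct`, `chi2`, `df`, `p_value`, `p_adj`, `regime`.
#' @export
analyze_pairs <- function(pairs, marginals, alpha = 0.01, family_size = NULL) {
  pairs <- validate_pair_records(pairs)
  if (!all(c("probe_id", "f2") %in% names(marginals))) {
    abort_validation("marginals must have columns probe_id and f2")
  }
  keys <- unique(pairs[, c("probe_a", "probe_b")])
  m <- if (is.null(family_size)) nrow(keys) else family_size
  rows <- purrr::map(seq_len(nrow(keys)), function(i) {
    a <- keys$probe_a[i]
    b <- keys$probe_b[i]
    sub <- pairs[pairs$probe_a == a & pairs$probe_b == b, ]
    f2_a <- marginals$f2[match(a, marginals$probe_id)]
    f2_b <- marginals$f2[match(b, marginals$probe_id)]
    if (is.na(f2_a) || is.na(f2_b)) {
      abort_validation(sprintf("no marginal 2-active fraction for pair %s/%s", a, b))
    }
    expected <- expected_joint_biallelic(f2_a, f2_b)
    n <- nrow(sub)
    joint <- sum(sub$signals_a == 2L & sub$signals_b == 2L)
    coloc <- colocation_fraction(sub)
    test <- test_coordination(joint, n, expected, family_size = m)
    tibble(
      pair = paste(a, b, sep = "/"),
      n_scored_joint = n,
      n_both_monoallelic = coloc$n,
      colocation_fraction = coloc$fraction,
      expected_joint_pct = 100 * expected,
      observed_joint_pct = 100 * joint / n,
      chi2 = test$chi2, df = test$df,
      p_value = test$p_value, p_adj = test$p_adj
    )
  })
  classify_regime(bind_rows(rows), alpha = alpha)
}
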