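test_that("hybridization efficiency is the single-signal fraction in heterogametic nuclei", {
  s <- summary_fixture(n2 = 0, n1 = 95, n0 = 5, sex = "heterogametic")
  est <- estimate_efficiency(s)
  expect_equal(est$p_hat, 0.95)
  expect_equal(est$q_hat, 0.05)
  expect_equal(est$n_het, 100)

  perfect <- summary_fixture(n2 = 0, n1 = 100, n0 = 0, sex = "heterogametic")
  expect_equal(estimate_efficiency(perfect)$p_hat, 1.0)

  twosig <- summary_fixture(n2 = 3, n1 = 90, n0 = 7, sex = "heterogametic")
  expect_warning(est2 <- estimate_efficiency(twosig), "two signals")
  expect_equal(est2$p_hat, 90 / 97)

  empty <- summary_fixture(n2 = 2, n1 = 0, n0 = 0, sex = "heterogametic")
  expect_error(suppressWarnings(estimate_efficiency(empty)), "undefined")
  hom <- summary_fixture(n2 = 0, n1 = 95, n0 = 5, sex = "homogametic")
  expect_error(estimate_efficiency(hom), "heterogametic")
})

test_that("simulated heterogametic cells recover the true efficiency", {
  p_true <- 0.97
  n <- 5000
  cfg <- one_locus_config(s = 0, p = p_true, n_hom = 0, n_het = n)
  records <- filter_diploid(simulate_population(cfg, seed = 5))$kept
  est <- estimate_efficiency(summarize_counts(records, "locus1", "heterogametic"))
  # exact binomial 99% central interval on the detected fraction
  bounds <- qbinom(c(0.005, 0.995), n, p_true) / n
  expect_gte(est$p_hat, bounds[1])
  expect_lte(est$p_hat, bounds[2])
})

test_that("the detection null follows p^2 + 2pq + q^2", {
  nd <- null_distribution(0.95)
  expect_equal(nd$f0, 0.0025)
  expect_equal(nd$f1, 0.095)
  expect_equal(nd$f2, 0.9025)
  expect_equal(null_distribution(1), tibble::tibble(f2 = 1, f1 = 0, f0 = 0))
  expect_equal(null_distribution(0.5), tibble::tibble(f2 = 0.25, f1 = 0.5, f0 = 0.25))
  # analytic conservation across the whole parameter range
  grid <- null_distribution(seq(0, 1, by = 0.01))
  expect_equal(grid$f2 + grid$f1 + grid$f0, rep(1, 101))
  expect_error(null_distribution(1.2), class = "fishact_validation_error")
})

test_that("the 2-df test matches hand-computed Pearson arithmetic", {
  obs <- summary_fixture(n2 = 60, n1 = 35, n0 = 5)
  # oracle: explicit O/E table at p = 0.95, n = 100
  E <- 100 * c(0.9025, 0.095, 0.0025)
  chi2_oracle <- sum((c(60, 35, 5) - E)^2 / E)
  res <- suppressWarnings(test_inactivation(obs, 0.95))
  expect_equal(res$chi2, chi2_oracle)
  expect_equal(res$df, 2L)
  expect_gt(res$chi2, qchisq(0.99, df = 2))
  expect_lt(res$p_value, 0.01)
  # agrees with the reference chi-square survival function
  expect_equal(res$p_value, pchisq(chi2_oracle, 2, lower.tail = FALSE))
})

test_that("observed counts equal to expected give chi2 ~ 0", {
  # at p = 0.95 and n = 400 the expected counts are integers: 361, 38, 1
  obs <- summary_fixture(n2 = 361, n1 = 38, n0 = 1)
  res <- test_inactivation(obs, 0.95)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
})

test_that("a zero expected class with observations is flagged degenerate", {
  obs <- summary_fixture(n2 = 90, n1 = 10, n0 = 0)
  res <- test_inactivation(obs, 1)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0)
  # p = 1 with no 1- or 0-signal nuclei is a perfect fit, not degenerate
  clean <- summary_fixture(n2 = 100, n1 = 0, n0 = 0)
  res2 <- test_inactivation(clean, 1)
  expect_false(res2$degenerate)
  expect_equal(res2$chi2, 0)
})

test_that("type-I error of the raw test stays near nominal under the null", {
  set.seed(101)
  p <- 0.97
  n <- 200
  nrep <- 500
  nd <- null_distribution(p)
  rej <- vapply(seq_len(nrep), function(i) {
    cnt <- as.vector(rmultinom(1, n, c(nd$f2, nd$f1, nd$f0)))
    obs <- summary_fixture(n2 = cnt[1], n1 = cnt[2], n0 = cnt[3])
    suppressWarnings(test_inactivation(obs, p))$p_value < 0.01
  }, logical(1))
  # nominal 0.01 plus slack for the small expected zero-signal class and
  # Monte-Carlo error
  expect_lte(mean(rej), 0.03)
})

test_that("bonferroni multiplies and caps, preserving order", {
  expect_equal(bonferroni(c(0.001, 0.5), family_size = 10), c(0.01, 1.0))
  expect_equal(bonferroni(0.2, family_size = 1), 0.2)
  set.seed(1)
  p <- runif(20)
  expect_true(all(bonferroni(p, 25) >= p))
  # cross-check against the reference implementation when family = length
  expect_equal(bonferroni(p), p.adjust(p, method = "bonferroni"))
  expect_error(bonferroni(p, family_size = 5), "at least")
  expect_error(bonferroni(p, family_size = 0), class = "fishact_validation_error")
})

test_that("silencing estimate inverts the mixture model exactly at expectation", {
  s <- 0.3
  p <- 0.95
  n <- 100000
  f1 <- 2 * p * (1 - p) + s * p * (2 * p - 1)
  f2 <- (1 - s) * p^2
  obs <- summary_fixture(n2 = round(n * f2), n1 = round(n * f1),
                         n0 = n - round(n * f2) - round(n * f1))
  expect_equal(estimate_silencing(obs, p), s, tolerance = 1e-3)
  # clamped at the boundaries
  null_obs <- summary_fixture(n2 = 9025, n1 = 950, n0 = 25)
  expect_equal(estimate_silencing(null_obs, 0.95), 0, tolerance = 1e-9)
  expect_error(estimate_silencing(obs, 0.5), "identifiable")
})
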