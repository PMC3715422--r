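test_that("colocation fraction counts jointly monoallelic nuclei only", {
  # 100 eligible nuclei, 96 co-located, plus ineligible rows that must not count
  pairs <- dplyr::bind_rows(
    pair_fixture(rep(1L, 100), rep(1L, 100), c(rep(TRUE, 96), rep(FALSE, 4))),
    pair_fixture(c(2L, 2L, 0L), c(2L, 1L, 1L), c(NA, NA, NA))
  )
  res <- colocation_fraction(pairs)
  expect_equal(res$fraction, 0.96)
  expect_equal(res$n, 100)

  all26 <- pair_fixture(rep(1L, 26), rep(1L, 26), rep(TRUE, 26))
  expect_equal(colocation_fraction(all26)$fraction, 1.0)

  none <- pair_fixture(c(2L, 0L), c(2L, 2L), c(NA, NA))
  res0 <- colocation_fraction(none)
  expect_true(is.na(res0$fraction))
  expect_equal(res0$n, 0L)
})

test_that("expected joint biallelic frequency is the product of marginals", {
  expect_equal(expected_joint_biallelic(0.76, 0.60), 0.456)
  expect_equal(expected_joint_biallelic(1, 1), 1)
  expect_equal(expected_joint_biallelic(0.37, 0), 0)
  expect_error(expected_joint_biallelic(1.2, 0.5),
               class = "fishact_validation_error")
})

test_that("the 1-df independence test separates the two published regimes", {
  # agreement with expectation: observed 45.67% vs expected 45.6% at n = 216
  near <- test_coordination(0.4567 * 216, 216, 0.456)
  expect_lt(near$chi2, 0.01)
  expect_gt(near$p_value, 0.05)
  # strong excess: observed 55.87% vs expected 18.6% at n = 243, 5 pairs tested
  far <- test_coordination(0.5587 * 243, 243, 0.186, family_size = 5)
  expect_lt(far$p_adj, 0.01)
  # exact agreement gives a zero statistic
  zero <- test_coordination(216 * 0.456, 216, 0.456)
  expect_equal(zero$chi2, 0)
  expect_equal(zero$p_value, 1)
  expect_error(test_coordination(10, 5, 0.4), class = "fishact_validation_error")
})

test_that("regimes are classified from significance and direction", {
  results <- tibble::tibble(
    observed_joint_pct = c(45.67, 55.87, 5),
    expected_joint_pct = c(45.6, 18.6, 20),
    p_adj = c(0.9, 0.001, 0.001)
  )
  expect_warning(out <- classify_regime(results), "anti-coordination")
  expect_equal(out$regime, c("independent_escape", "coordinated_escape",
                             "independent_escape"))
})

test_that("independent silencing yields joint frequency near the product of marginals", {
  s_a <- 0.4
  s_b <- 0.3
  cfg <- two_locus_pair_config(s_a, s_b, p_a = 1, p_b = 1, rho = 0,
                               n_hom = 10000)
  pairs <- simulate_pair_population(cfg, 1, seed = 21)
  joint <- mean(pairs$signals_a == 2L & pairs$signals_b == 2L)
  product <- (1 - s_a) * (1 - s_b)
  expect_lt(abs(joint - product), 0.02)
  # and the independence test rejects at no more than roughly nominal rate
  set.seed(22)
  rej <- vapply(1:200, function(i) {
    pr <- simulate_pair_population(cfg, 1, seed = 1000 + i, n = 200)
    obs <- sum(pr$signals_a == 2L & pr$signals_b == 2L)
    test_coordination(obs, 200, product)$p_value < 0.01
  }, logical(1))
  expect_lte(mean(rej), 0.03)
})

test_that("fully coordinated silencing is detected with high power", {
  s <- 0.6 # marginal 2-active fraction near 0.4
  cfg <- two_locus_pair_config(s, s, p_a = 1, p_b = 1, rho = 1, n_hom = 200)
  marginal <- 1 - s
  expected <- marginal^2
  # under rho = 1 the joint biallelic fraction approaches the marginal itself
  big <- simulate_pair_population(cfg, 1, seed = 31, n = 20000)
  joint <- mean(big$signals_a == 2L & big$signals_b == 2L)
  expect_lt(abs(joint - marginal), 0.02)
  rej <- vapply(1:100, function(i) {
    pr <- simulate_pair_population(cfg, 1, seed = 2000 + i)
    obs <- sum(pr$signals_a == 2L & pr$signals_b == 2L)
    test_coordination(obs, 200, expected, family_size = 5)$p_adj < 0.01
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("colocation fraction recovers the simulator's fidelity parameter", {
  # at perfect detection every jointly monoallelic nucleus has both silenced
  # alleles, so both signals come from the active chromosome
  gamma <- 0.9
  cfg <- two_locus_pair_config(0.5, 0.5, p_a = 1, p_b = 1, rho = 0,
                               n_hom = 4000, gamma = gamma)
  pairs <- simulate_pair_population(cfg, 1, seed = 41)
  res <- colocation_fraction(pairs)
  bounds <- qbinom(c(0.005, 0.995), res$n, gamma) / res$n
  expect_gte(res$fraction, bounds[1])
  expect_lte(res$fraction, bounds[2])

  cfg1 <- two_locus_pair_config(0.5, 0.5, p_a = 1, p_b = 1, rho = 0,
                                n_hom = 2000, gamma = 1)
  expect_equal(colocation_fraction(simulate_pair_population(cfg1, 1, seed = 42))$fraction, 1)
})

test_that("analyze_pairs assembles per-pair results and regime calls", {
  cfg <- study_panel_config(n_homogametic = 400)
  pairs <- dplyr::bind_rows(lapply(1:5, function(i) {
    simulate_pair_population(cfg, i, seed = 50 + i)
  }))
  marginals <- tibble::tibble(
    probe_id = cfg$loci$probe_id,
    f2 = (1 - cfg$loci$silencing_prob) * cfg$loci$efficiency^2
  )
  res <- analyze_pairs(pairs, marginals)
  expect_equal(nrow(res), 5)
  # the two rho = 0 chicken-like pairs silence independently, the three
  # rho = 1 platypus-like pairs are coordinated
  expect_equal(res$regime, c("independent_escape", "independent_escape",
                             "coordinated_escape", "coordinated_escape",
                             "coordinated_escape"))
  expect_true(all(res$n_scored_joint == 400))
})
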