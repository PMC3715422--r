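test_that("identical seed and config reproduce the population bit for bit", {
  cfg <- study_panel_config(n_homogametic = 50, n_heterogametic = 50)
  a <- simulate_population(cfg, seed = 123)
  b <- simulate_population(cfg, seed = 123)
  expect_identical(a, b)
  c <- simulate_population(cfg, seed = 124)
  expect_false(identical(a, c))
  pa <- simulate_pair_population(cfg, 1, seed = 9)
  pb <- simulate_pair_population(cfg, 1, seed = 9)
  expect_identical(pa, pb)
})

test_that("degenerate parameters give fully biallelic homogametic nuclei", {
  cfg <- one_locus_config(s = 0, p = 1, n_hom = 500, n_het = 0)
  records <- simulate_population(cfg, seed = 1)
  hom <- records[records$sex == "homogametic", ]
  expect_true(all(hom$test_signals == 2L))
  expect_true(all(hom$control_signals == 2L))
})

test_that("the monoallelic fraction converges to the silencing probability", {
  s <- 0.3
  cfg <- one_locus_config(s = s, p = 1, n_hom = 50000, n_het = 0)
  records <- simulate_population(cfg, seed = 6)
  sm <- summarize_counts(filter_diploid(records)$kept, "locus1", "homogametic")
  expect_lt(abs(sm$n1 / sm$n_scored - s), 0.01)
})

test_that("without silencing the signal counts follow the detection null", {
  cfg <- one_locus_config(s = 0, p = 0.95, n_hom = 50000, n_het = 0)
  records <- simulate_population(cfg, seed = 7)
  sm <- summarize_counts(filter_diploid(records)$kept, "locus1", "homogametic")
  fr <- c(sm$n2, sm$n1, sm$n0) / sm$n_scored
  expect_lt(max(abs(fr - c(0.9025, 0.095, 0.0025))), 0.01)
})

test_that("heterogametic nuclei carry a single detectable allele at sex-specific loci", {
  cfg <- one_locus_config(s = 0.4, p = 0.95, n_hom = 0, n_het = 20000)
  records <- simulate_population(cfg, seed = 8)
  het <- filter_diploid(records)$kept
  expect_true(all(het$test_signals <= 1L))
  expect_lt(abs(mean(het$test_signals == 1L) - 0.95), 0.01)
})

test_that("pseudoautosomal silencing applies in both sexes", {
  s <- 0.35
  cfg <- one_locus_config(s = s, p = 1, class = "pseudoautosomal",
                          n_hom = 20000, n_het = 20000)
  records <- filter_diploid(simulate_population(cfg, seed = 9))$kept
  for (sex in c("homogametic", "heterogametic")) {
    sm <- summarize_counts(records, "locus1", sex)
    expect_lt(abs(sm$n1 / sm$n_scored - s), 0.015)
  }
})

test_that("joint pair frequencies follow the coupling algebra", {
  # rho = 0: joint biallelic = product of (1 - s) and detection terms
  s_a <- 0.3
  s_b <- 0.45
  p <- 0.96
  cfg0 <- two_locus_pair_config(s_a, s_b, p, p, rho = 0, n_hom = 100000)
  pr0 <- simulate_pair_population(cfg0, 1, seed = 10)
  joint0 <- mean(pr0$signals_a == 2L & pr0$signals_b == 2L)
  expect_lt(abs(joint0 - (1 - s_a) * (1 - s_b) * p^4), 0.01)

  # rho = 1, equal s: joint biallelic matches either marginal
  cfg1 <- two_locus_pair_config(0.4, 0.4, p, p, rho = 1, n_hom = 100000)
  pr1 <- simulate_pair_population(cfg1, 1, seed = 11)
  joint1 <- mean(pr1$signals_a == 2L & pr1$signals_b == 2L)
  marg1 <- mean(pr1$signals_a == 2L)
  expect_lt(abs(joint1 - (1 - 0.4) * p^4), 0.01)
  expect_lt(abs(joint1 / marg1 - p^2), 0.01)
})

test_that("the reference study panel has the published composition", {
  cfg <- study_panel_config()
  loci <- cfg$loci
  chicken_z <- loci[loci$species == "chicken" & loci$locus_class == "sex_specific", ]
  expect_equal(nrow(chicken_z), 11)
  expect_equal(range(chicken_z$silencing_prob), c(0.15, 0.51))
  expect_true(all(chicken_z$efficiency >= 0.95 & chicken_z$efficiency <= 1))

  plat_x <- loci[loci$species == "platypus" & loci$locus_class == "sex_specific", ]
  expect_equal(nrow(plat_x), 19)
  expect_equal(range(plat_x$silencing_prob), c(0.25, 0.62))
  expect_equal(sum(plat_x$chromosome == "X5"), 14)

  par <- loci[loci$locus_class == "pseudoautosomal", ]
  expect_equal(nrow(par), 9)
  expect_true(all(par$silencing_prob >= 0.16 & par$silencing_prob <= 0.47))

  auto <- loci[loci$locus_class == "autosomal", ]
  expect_equal(nrow(auto), 12)
  expect_true(all(auto$silencing_prob == 0))

  expect_equal(nrow(cfg$pairs), 5)
  expect_equal(cfg$pairs$rho, c(0, 0, 1, 1, 1))
  # every locus resolvable in the derived panel
  expect_equal(nrow(sim_panel(cfg)), nrow(loci))
})

test_that("sim_config validates probabilities and pair references", {
  loci <- sim_locus("L1", "sp", "Z", "sex_specific", 0.3, 0.95)
  expect_error(sim_config(loci, tetraploid_fraction = 1.5),
               class = "fishact_validation_error")
  expect_error(sim_config(loci, pairs = tibble::tibble(
    probe_a = "L1", probe_b = "absent", rho = 0.5
  )), "not in loci")
  expect_error(sim_locus("L1", "sp", "Z", "sex_specific", 1.2, 0.95),
               class = "fishact_validation_error")
  expect_error(sim_locus("L1", "sp", "Z", "sex_specific", 0.3, 0.4),
               class = "fishact_validation_error")
})

test_that("configs round-trip through YAML", {
  cfg <- study_panel_config(n_homogametic = 77, n_heterogametic = 88, seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_homogametic, 77L)
  expect_equal(back$seed, 5L)
  expect_equal(as.data.frame(back$loci), as.data.frame(cfg$loci))
  expect_equal(as.data.frame(back$pairs), as.data.frame(cfg$pairs))
  # identical simulations from the round-tripped config
  expect_identical(simulate_population(cfg, seed = 3),
                   simulate_population(back, seed = 3))
})

test_that("the silencing probability is recovered without material bias", {
  cfg <- one_locus_config(s = 0.4, p = 0.97, n_hom = 2000, n_het = 2000,
                          tetraploid = 0.05, control_eff = 0.99)
  rec <- recovery_study(cfg, n_replicates = 50, seed = 100)
  expect_lt(abs(rec$mean_s_hat - 0.4), 0.03)

  cfg0 <- one_locus_config(s = 0, p = 0.97, n_hom = 2000, n_het = 2000)
  rec0 <- recovery_study(cfg0, n_replicates = 50, seed = 200)
  expect_lte(rec0$mean_s_hat, 0.02)
})

test_that("recovery error shrinks as the population grows", {
  rmse <- vapply(c(500, 1000, 2000, 4000), function(n) {
    cfg <- one_locus_config(s = 0.4, p = 0.97, n_hom = n, n_het = n)
    recovery_study(cfg, n_replicates = 50, seed = 300)$rmse
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})
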