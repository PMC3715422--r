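# Shared fixture builders; everything is generated in code.

nucleus_fixture <- function(control = c(2L, 2L, 2L), test = c(2L, 1L, 0L),
                            sex = "homogametic", probe = "probeA") {
  n <- max(length(control), length(test))
  tibble::tibble(
    experiment_id = "exp1",
    individual_id = "ind1",
    sex = rep(sex, length.out = n),
    probe_id = rep(probe, length.out = n),
    control_signals = rep(control, length.out = n),
    test_signals = rep(test, length.out = n)
  )
}

summary_fixture <- function(n2, n1, n0, probe = "probeA",
                            sex = "homogametic", n_gt2 = 0L) {
  tibble::tibble(probe_id = probe, sex = sex,
                 n_scored = n2 + n1 + n0,
                 n2 = n2, n1 = n1, n0 = n0, n_gt2 = n_gt2)
}

pair_fixture <- function(signals_a, signals_b, colocated) {
  tibble::tibble(
    experiment_id = "pairexp",
    probe_a = "probeA", probe_b = "probeB",
    signals_a = as.integer(signals_a),
    signals_b = as.integer(signals_b),
    colocated = colocated
  )
}

# Minimal single-locus configs used across simulator-driven tests
one_locus_config <- function(s, p, class = "sex_specific",
                             n_hom = 200, n_het = 200,
                             tetraploid = 0, control_eff = 1, seed = 1L,
                             gamma = 0.96) {
  sim_config(
    sim_locus("locus1", "testspecies", "Z", class, s, p,
              start = 0L, end = 200000L),
    n_homogametic = n_hom, n_heterogametic = n_het,
    tetraploid_fraction = tetraploid, control_efficiency = control_eff,
    colocation_fidelity = gamma, seed = seed
  )
}

two_locus_pair_config <- function(s_a, s_b, p_a, p_b, rho,
                                  n_hom = 200, gamma = 0.96, seed = 1L) {
  loci <- dplyr::bind_rows(
    sim_locus("locusA", "testspecies", "Z", "sex_specific", s_a, p_a,
              start = 0L, end = 200000L),
    sim_locus("locusB", "testspecies", "Z", "sex_specific", s_b, p_b,
              start = 2000000L, end = 2200000L)
  )
  sim_config(loci,
             pairs = tibble::tibble(probe_a = "locusA", probe_b = "locusB",
                                    rho = rho),
             n_homogametic = n_hom, n_heterogametic = 100,
             tetraploid_fraction = 0, control_efficiency = 1,
             colocation_fidelity = gamma, seed = seed)
}
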