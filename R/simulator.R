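#' Define a simulated locus
#'
#' One row of the simulator's locus table. `silencing_prob` is the probability
#' that the allele on the inactivatable chromosome is silenced in a given
#' nucleus (drawn independently per nucleus: activity states are not clonally
#' inherited in the fibroblast populations this emulates). `efficiency` is the
#' per-allele detection probability of the probe; usable FISH probes sit in
#' the 0.94-1.0 range, and values at or below 0.5 are rejected because the
#' monoallelic excess is then unidentifiable.
#'
#' @param probe_id,species,chromosome Identifiers.
#' @param locus_class `"autosomal"`, `"sex_specific"` or `"pseudoautosomal"`.
#' @param silencing_prob Probability in `[0, 1]`; ignored (forced 0) for
#'   autosomal loci.
#' @param efficiency Probability in `(0.5, 1]`.
#' @param start,end 0-based half-open coordinates (synthetic).
#' @param genes Comma-joined gene names.
#' @return A one-row tibble.
#' @export
sim_locus <- function(probe_id, species, chromosome, locus_class,
                      silencing_prob, efficiency,
                      start = 0L, end = 200000L, genes = toupper(probe_id)) {
  locus_class <- arg_match(locus_class, .locus_classes)
  if (silencing_prob < 0 || silencing_prob > 1) {
    abort_validation("silencing_prob must lie in [0, 1]")
  }
  if (efficiency <= 0.5 || efficiency > 1) {
    abort_validation("efficiency must lie in (0.5, 1]")
  }
  if (locus_class == "autosomal") silencing_prob <- 0
  tibble(probe_id = probe_id, species = species, chromosome = chromosome,
         locus_class = locus_class, silencing_prob = silencing_prob,
         efficiency = efficiency, start = as.integer(start),
         end = as.integer(end), genes = genes)
}

#' Assemble a simulation configuration
#'
#' Full parameterization of the generative model of scored fibroblast nuclei:
#' per-locus silencing probabilities and probe efficiencies, optional
#' coordination of silencing between declared locus pairs, a tetraploid cell
#' fraction that the diploid-control filter is meant to catch, and signal
#' co-location fidelity for two-color experiments.
#'
#' @param loci A tibble of loci (rows from [sim_locus()]).
#' @param pairs Optional tibble (`probe_a`, `probe_b`, `rho`) of coupled
#'   pairs; `rho = 0` silences the two loci independently, `rho = 1` makes
#'   the second locus copy the first locus's silencing state in every nucleus.
#' @param n_homogametic,n_heterogametic Nuclei scored per hybridization
#'   experiment per sex (the study scored at least 100 per hybridization).
#' @param tetraploid_fraction Fraction of tetraploid cells in the culture.
#' @param control_efficiency Detection probability of the autosomal control
#'   probe.
#' @param colocation_fidelity Probability that two signals on the same
#'   chromosome are scored as co-located.
#' @param seed Default seed for [simulate_population()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(loci, pairs = NULL,
                       n_homogametic = 200, n_heterogametic = 200,
                       tetraploid_fraction = 0.05,
                       control_efficiency = 0.99,
                       colocation_fidelity = 0.96,
                       seed = 1L) {
  loci <- as_tibble(loci)
  required <- c("probe_id", "species", "chromosome", "locus_class",
                "silencing_prob", "efficiency", "start", "end", "genes")
  missing <- setdiff(required, names(loci))
  if (length(missing) > 0) {
    abort_validation(sprintf("loci lack column(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(loci$probe_id)) {
    abort_validation("locus probe_id must be unique")
  }
  probs <- c(tetraploid_fraction, control_efficiency, colocation_fidelity,
             loci$silencing_prob, loci$efficiency)
  if (any(probs < 0 | probs > 1) || anyNA(probs)) {
    abort_validation("all probabilities must lie in [0, 1]")
  }
  if (!is.null(pairs)) {
    pairs <- as_tibble(pairs)
    if (!all(c("probe_a", "probe_b", "rho") %in% names(pairs))) {
      abort_validation("pairs must have columns probe_a, probe_b, rho")
    }
    bad <- setdiff(c(pairs$probe_a, pairs$probe_b), loci$probe_id)
    if (length(bad) > 0) {
      abort_validation(sprintf("pair member(s) not in loci: %s",
                               paste(bad, collapse = ", ")))
    }
    if (any(pairs$rho < 0 | pairs$rho > 1)) {
      abort_validation("rho must lie in [0, 1]")
    }
  } else {
    pairs <- tibble(probe_a = character(), probe_b = character(),
                    rho = numeric())
  }
  structure(list(
    loci = loci, pairs = pairs,
    n_homogametic = as.integer(n_homogametic),
    n_heterogametic = as.integer(n_heterogametic),
    tetraploid_fraction = tetraploid_fraction,
    control_efficiency = control_efficiency,
    colocation_fidelity = colocation_fidelity,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Extract the locus panel from a simulation configuration
#'
#' @param config A `sim_config`.
#' @return A panel tibble accepted by [score_panel()] and
#'   [write_activity_map()].
#' @export
sim_panel <- function(config) {
  validate_panel(config$loci[, c("probe_id", "species", "chromosome",
                                 "locus_class", "start", "end", "genes")])
}

#' Simulate a scored nucleus population
#'
#' Generates per-nucleus records for every locus in the configuration, for
#' both sexes, under the generative model:
#'
#' * each cell is tetraploid with probability `tetraploid_fraction`
#'   (tetraploid cells carry twice the diploid allele count before detection,
#'   so the control probe flags them with high probability);
#' * in homogametic diploid cells one sex chromosome is constitutively active;
#'   on the other ("inactivatable") homologue each sex-specific locus is
#'   silenced independently per nucleus with its `silencing_prob`, except
#'   declared pair members, whose states are coupled with coefficient `rho`;
#' * heterogametic cells carry a single transcribing allele at sex-specific
#'   loci; pseudoautosomal loci carry two alleles in both sexes, with the
#'   inactivatable-side (or Y-side) allele silenced with the same
#'   `silencing_prob`; autosomal alleles are never silenced;
#' * every transcribing test allele is detected with the probe's
#'   `efficiency`, every control allele with `control_efficiency`.
#'
#' Within a sex, all loci are drawn on one shared cell population so that
#' pair coupling is meaningful; each locus is emitted as its own experiment.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; defaults to `config$seed`. Identical seed and
#'   configuration give bit-identical output.
#' @return A nucleus-record tibble in the schema of [read_nucleus_table()].
#' @export
simulate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  out <- purrr::map(.sexes, function(sex) {
    n <- if (sex == "homogametic") config$n_homogametic else config$n_heterogametic
    if (n == 0) return(NULL)
    ploidy <- ifelse(runif(n) < config$tetraploid_fraction, 2L, 1L)
    sil <- draw_silencing(config, sex, n)
    loci <- config$loci
    purrr::map(seq_len(nrow(loci)), function(j) {
      alleles <- transcribing_alleles(loci$locus_class[j], sex, sil[, j]) * ploidy
      tibble(
        experiment_id = paste0("exp_", loci$probe_id[j]),
        individual_id = "sim_01",
        sex = sex,
        probe_id = loci$probe_id[j],
        control_signals = rbinom(n, 2L * ploidy, config$control_efficiency),
        test_signals = rbinom(n, alleles, loci$efficiency[j])
      )
    }) %>% bind_rows()
  }) %>% bind_rows()
  out
}

# Silencing indicator matrix (n cells x n loci) for one sex, with pair
# coupling applied where both members are silenceable in that sex.
draw_silencing <- function(config, sex, n) {
  loci <- config$loci
  silenceable <- silencing_applies(loci$locus_class, sex)
  sil <- matrix(FALSE, nrow = n, ncol = nrow(loci),
                dimnames = list(NULL, loci$probe_id))
  for (j in seq_len(nrow(loci))) {
    if (silenceable[j] && loci$silencing_prob[j] > 0) {
      sil[, j] <- runif(n) < loci$silencing_prob[j]
    }
  }
  if (nrow(config$pairs) > 0) {
    for (i in seq_len(nrow(config$pairs))) {
      a <- config$pairs$probe_a[i]
      b <- config$pairs$probe_b[i]
      ja <- match(a, loci$probe_id)
      jb <- match(b, loci$probe_id)
      if (silenceable[ja] && silenceable[jb] && config$pairs$rho[i] > 0) {
        copy <- runif(n) < config$pairs$rho[i]
        sil[copy, jb] <- sil[copy, ja]
      }
    }
  }
  sil
}

silencing_applies <- function(locus_class, sex) {
  (locus_class == "sex_specific" & sex == "homogametic") |
    locus_class == "pseudoautosomal"
}

transcribing_alleles <- function(locus_class, sex, silenced) {
  if (locus_class == "autosomal") {
    rep(2L, length(silenced))
  } else if (locus_class == "sex_specific" && sex == "heterogametic") {
    rep(1L, length(silenced))
  } else {
    # sex-specific homogametic, or pseudoautosomal in either sex:
    # one constitutive allele plus one silenceable allele
    2L - as.integer(silenced)
  }
}

#' Simulate a two-color gene-pair experiment
#'
#' Draws joint allelic states for one declared pair under the coupling model
#' (the second locus copies the first locus's silencing state with probability
#' `rho`, otherwise draws independently), detects each transcribing allele
#' with its probe's efficiency, and emits per-nucleus pair records. For nuclei
#' in which both loci show exactly one signal, the chromosome of origin of
#' each signal is tracked exactly: signals from the same chromosome are scored
#' co-located with probability `colocation_fidelity`, signals from different
#' homologues are never co-located.
#'
#' Pair records carry no control-probe column, so the output represents
#' already diploid-filtered nuclei; no tetraploid cells are drawn.
#'
#' @param config A `sim_config`.
#' @param pair Either a row index into `config$pairs` or a length-2 character
#'   vector `c(probe_a, probe_b)`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param sex Cells to simulate; default `"homogametic"` (the informative
#'   sex).
#' @param n Number of nuclei; defaults to the config's count for `sex`.
#' @return A pair-record tibble in the schema of [read_pair_table()].
#' @export
simulate_pair_population <- function(config, pair, seed = config$seed,
                                     sex = "homogametic", n = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sex <- arg_match(sex, .sexes)
  if (is.character(pair)) {
    idx <- which(config$pairs$probe_a == pair[1] & config$pairs$probe_b == pair[2])
    if (length(idx) != 1) {
      abort_validation(sprintf("pair %s/%s not declared in config", pair[1], pair[2]))
    }
  } else {
    idx <- pair
    if (idx < 1 || idx > nrow(config$pairs)) {
      abort_validation("pair index out of range")
    }
  }
  a <- config$pairs$probe_a[idx]
  b <- config$pairs$probe_b[idx]
  rho <- config$pairs$rho[idx]
  la <- config$loci[match(a, config$loci$probe_id), ]
  lb <- config$loci[match(b, config$loci$probe_id), ]
  if (is.null(n)) {
    n <- if (sex == "homogametic") config$n_homogametic else config$n_heterogametic
  }
  set.seed(seed)

  sil_a <- draw_pair_silencing(la, sex, n)
  sil_b_own <- draw_pair_silencing(lb, sex, n)
  copy <- runif(n) < rho
  couple <- silencing_applies(la$locus_class, sex) &&
    silencing_applies(lb$locus_class, sex)
  sil_b <- if (couple) ifelse(copy, sil_a, sil_b_own) else sil_b_own

  da <- detect_pair_locus(la, sex, sil_a, n)
  db <- detect_pair_locus(lb, sex, sil_b, n)

  both1 <- da$signals == 1L & db$signals == 1L
  same_chr <- da$origin == db$origin
  colocated <- rep(NA, n)
  colocated[both1] <- same_chr[both1] &
    (runif(sum(both1)) < config$colocation_fidelity)

  tibble(
    experiment_id = paste0("pair_", a, "_", b),
    probe_a = a, probe_b = b,
    signals_a = da$signals, signals_b = db$signals,
    colocated = colocated
  )
}

draw_pair_silencing <- function(locus, sex, n) {
  if (silencing_applies(locus$locus_class, sex) && locus$silencing_prob > 0) {
    runif(n) < locus$silencing_prob
  } else {
    rep(FALSE, n)
  }
}

# Detect signals for one locus of a pair experiment in diploid nuclei,
# tracking the chromosome ("act"/"inact") of the signal when exactly one
# allele is detected.
detect_pair_locus <- function(locus, sex, silenced, n) {
  p <- locus$efficiency
  single_copy <- locus$locus_class == "sex_specific" && sex == "heterogametic"
  if (single_copy) {
    d_act <- runif(n) < p
    signals <- as.integer(d_act)
    origin <- ifelse(d_act, "act", NA_character_)
  } else {
    d_act <- runif(n) < p
    d_inact <- !silenced & (runif(n) < p)
    signals <- as.integer(d_act) + as.integer(d_inact)
    origin <- rep(NA_character_, n)
    one <- signals == 1L
    origin[one & d_act] <- "act"
    origin[one & d_inact] <- "inact"
  }
  list(signals = signals, origin = origin)
}

#' Reference simulated panel matching the study's composition
#'
#' Deterministic fixture configuration mirroring the published panel: 11
#' chicken Z-specific loci with silencing probabilities evenly spanning
#' 0.15-0.51 and probe efficiencies in 0.95-1.0; 19 platypus X-specific loci
#' (two on X1, one on X2, two on X3, fourteen on X5) with silencing spanning
#' 0.25-0.62 and efficiencies in 0.94-1.0; nine pseudoautosomal loci with
#' silencing in 0.16-0.47; and twelve autosomal loci (six per species) with no
#' silencing. Two chicken Z pairs are declared with `rho = 0` (independent
#' silencing) and three platypus X5 pairs with `rho = 1` (regionally
#' coordinated silencing), reproducing the two regimes the coordination
#' analysis distinguishes.
#'
#' @param n_homogametic,n_heterogametic Nuclei per experiment per sex.
#' @param seed Default seed.
#' @return A `sim_config`.
#' @export
study_panel_config <- function(n_homogametic = 200, n_heterogametic = 200,
                               seed = 1L) {
  chicken_z <- tibble(
    probe_id = sprintf("chzZ%02d", 1:11),
    species = "chicken", chromosome = "Z", locus_class = "sex_specific",
    silencing_prob = seq(0.15, 0.51, length.out = 11),
    efficiency = seq(0.95, 1.0, length.out = 11)
  )
  platypus_chrom <- c("X1", "X1", "X2", "X3", "X3", rep("X5", 14))
  platypus_x <- tibble(
    probe_id = sprintf("plaX%02d", 1:19),
    species = "platypus", chromosome = platypus_chrom,
    locus_class = "sex_specific",
    silencing_prob = seq(0.25, 0.62, length.out = 19),
    efficiency = seq(0.94, 1.0, length.out = 19)
  )
  par_loci <- tibble(
    probe_id = sprintf("plaPAR%d", 1:9),
    species = "platypus",
    chromosome = c("X1", "X1", "X1", "X2", "X3", "X3", "X4", "X5", "X5"),
    locus_class = "pseudoautosomal",
    silencing_prob = seq(0.16, 0.47, length.out = 9),
    efficiency = seq(0.94, 1.0, length.out = 9)
  )
  autosomal <- tibble(
    probe_id = c(sprintf("chzA%d", 1:6), sprintf("plaA%d", 1:6)),
    species = rep(c("chicken", "platypus"), each = 6),
    chromosome = rep(sprintf("chr%d", 1:6), 2),
    locus_class = "autosomal",
    silencing_prob = 0,
    efficiency = 0.98
  )
  loci <- bind_rows(chicken_z, platypus_x, par_loci, autosomal) %>%
    group_by(.data$chromosome, .data$species) %>%
    mutate(start = 2000000L * (row_number() - 1L),
           end = .data$start + 200000L) %>%
    ungroup() %>%
    mutate(genes = paste0(toupper(.data$probe_id), "_G1"))
  pairs <- tibble(
    probe_a = c("chzZ02", "chzZ05", "plaX06", "plaX08", "plaX10"),
    probe_b = c("chzZ03", "chzZ06", "plaX07", "plaX09", "plaX11"),
    rho = c(0, 0, 1, 1, 1)
  )
  sim_config(loci, pairs = pairs,
             n_homogametic = n_homogametic,
             n_heterogametic = n_heterogametic,
             seed = seed)
}

#' Parameter-recovery study for the silencing probability
#'
#' Repeatedly simulates the configured population, runs the full inference
#' path (diploid filter, per-sex tallies, heterogametic efficiency estimate,
#' silencing estimate from the homogametic 1-signal excess) and summarizes,
#' per sex-specific locus, how well the estimated silencing probability
#' recovers the generating value.
#'
#' @param config A `sim_config`.
#' @param n_replicates Number of simulated populations.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @return A tibble per locus: `probe_id`, `true_s`, `mean_s_hat`, `bias`,
#'   `rmse`, `n_replicates`.
#' @export
recovery_study <- function(config, n_replicates = 20, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  loci <- config$loci[config$loci$locus_class == "sex_specific", ]
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    records <- simulate_population(config, seed = seed + r)
    kept <- filter_diploid(records)$kept
    summaries <- summarize_counts_all(kept)
    purrr::map(loci$probe_id, function(id) {
      het <- summaries[summaries$probe_id == id &
                         summaries$sex == "heterogametic", ]
      hom <- summaries[summaries$probe_id == id &
                         summaries$sex == "homogametic", ]
      # tetraploid leak-through can put a 2-signal nucleus in heterogametic
      # cells; that anomaly is expected under this generative model
      eff <- suppressWarnings(estimate_efficiency(het))
      tibble(probe_id = id, replicate = r,
             s_hat = estimate_silencing(hom, eff))
    }) %>% bind_rows()
  }) %>% bind_rows()
  truth <- setNames(loci$silencing_prob, loci$probe_id)
  reps %>%
    group_by(.data$probe_id) %>%
    summarise(
      true_s = unname(truth[.data$probe_id[1]]),
      mean_s_hat = mean(.data$s_hat),
      bias = mean(.data$s_hat) - unname(truth[.data$probe_id[1]]),
      rmse = sqrt(mean((.data$s_hat - unname(truth[.data$probe_id[1]]))^2)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Serialize a simulation configuration to YAML
#'
#' @param config A `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- list(
    n_homogametic = config$n_homogametic,
    n_heterogametic = config$n_heterogametic,
    tetraploid_fraction = config$tetraploid_fraction,
    control_efficiency = config$control_efficiency,
    colocation_fidelity = config$colocation_fidelity,
    seed = config$seed,
    loci = purrr::transpose(as.list(config$loci)),
    pairs = purrr::transpose(as.list(config$pairs))
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path Path to a YAML file written by [write_sim_config()].
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("file not found: %s", path))
  }
  obj <- yaml::read_yaml(path)
  loci <- bind_rows(lapply(obj$loci, as_tibble))
  pairs <- if (length(obj$pairs) > 0) {
    bind_rows(lapply(obj$pairs, as_tibble))
  } else {
    NULL
  }
  sim_config(loci, pairs = pairs,
             n_homogametic = obj$n_homogametic,
             n_heterogametic = obj$n_heterogametic,
             tetraploid_fraction = obj$tetraploid_fraction,
             control_efficiency = obj$control_efficiency,
             colocation_fidelity = obj$colocation_fidelity,
             seed = obj$seed)
}
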