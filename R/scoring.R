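#' Full inactivation-scoring pipeline for a locus panel
#'
#' Runs the complete per-locus workflow on a long per-nucleus table:
#'
#' 1. diploid-control filtering ([filter_diploid()]);
#' 2. signal-count tallies per (probe, sex) ([summarize_counts_all()]);
#' 3. experimental-error bound from the autosomal controls of both sexes
#'    ([estimate_error()]), unless a fixed `error_rate` is supplied;
#' 4. per sex-specific locus: hybridization efficiency from heterogametic
#'    nuclei, 2-df chi-square test of homogametic counts against the detection
#'    null, error-adjusted 1-df re-test, and the silencing-probability
#'    estimate;
#' 5. Bonferroni correction across the loci tested in this run (the adjusted
#'    1-df p-value is the primary inference).
#'
#' Pseudoautosomal loci carry two alleles in both sexes, so their efficiency
#' cannot be calibrated from heterogametic nuclei. They are tested — in both
#' sexes — only when an efficiency is supplied via `efficiencies`, or when
#' `pooled = TRUE` (mean of the sex-specific probes' estimates); otherwise
#' they are skipped with a message.
#'
#' @param records Per-nucleus records (see [read_nucleus_table()]); not yet
#'   diploid-filtered.
#' @param panel Locus panel (see [read_panel()]).
#' @param alpha Significance threshold after correction; default 0.01.
#' @param family_size Bonferroni family; defaults to the number of tests
#'   performed in the run.
#' @param error_rate Fixed experimental error rate; if `NULL` (default) the
#'   upper Poisson bound from the run's autosomal summaries is used.
#' @param efficiencies Optional tibble (`probe_id`, `p_hat`) overriding or
#'   supplying per-probe efficiencies.
#' @param pooled Use the mean sex-specific efficiency for probes without a
#'   heterogametic estimate; default `FALSE`.
#' @param method Adjustment arithmetic, see [adjust_and_retest()].
#' @return A tibble with one row per (locus, sex) tested: observed counts,
#'   `efficiency`, activity percentages (`pct_2_active`, `pct_1_active`,
#'   `pct_0`), `s_hat`, `chi2_raw`/`p_raw` (2 df), `chi2_adj`/`p_adj_raw`
#'   (1 df), Bonferroni-corrected `p_adj`, and `significant` at `alpha`.
#' @export
score_panel <- function(records, panel, alpha = 0.01, family_size = NULL,
                        error_rate = NULL, efficiencies = NULL,
                        pooled = FALSE, method = c("shift", "scale")) {
  method <- arg_match(method)
  panel <- validate_panel(panel)
  flt <- filter_diploid(records)
  kept <- flt$kept
  unknown <- setdiff(unique(kept$probe_id), panel$probe_id)
  if (length(unknown) > 0) {
    abort_validation(sprintf(
      "probe(s) absent from panel: %s", paste(unknown, collapse = ", ")
    ))
  }
  summaries <- summarize_counts_all(kept) %>%
    left_join(panel[, c("probe_id", "locus_class")], by = "probe_id")

  if (is.null(error_rate)) {
    auto <- summaries %>% filter(.data$locus_class == "autosomal")
    if (nrow(auto) == 0) {
      abort_validation(
        "no autosomal control summaries to estimate error from; supply error_rate"
      )
    }
    err <- estimate_error(auto)
    error_rate <- err$max_error_rate
  } else {
    err <- NULL
  }

  eff_tbl <- heterogametic_efficiencies(summaries, efficiencies)
  pooled_p <- if (nrow(eff_tbl) > 0) mean(eff_tbl$p_hat) else NA_real_

  tasks <- scoring_tasks(summaries, eff_tbl, pooled, pooled_p)
  if (nrow(tasks) == 0) {
    abort_validation("no testable loci (no sex-specific or calibrated PAR summaries)")
  }

  rows <- purrr::pmap(tasks, function(probe_id, sex, p_use, ...) {
    obs <- summaries %>%
      filter(.data$probe_id == !!probe_id, .data$sex == !!sex)
    raw <- test_inactivation(obs, p_use)
    adj <- adjust_and_retest(obs, p_use, error_rate, method = method)
    tibble(
      probe_id = probe_id,
      sex = sex,
      n_scored = obs$n_scored,
      n2 = obs$n2, n1 = obs$n1, n0 = obs$n0, n_gt2 = obs$n_gt2,
      efficiency = p_use,
      pct_2_active = 100 * obs$n2 / obs$n_scored,
      pct_1_active = 100 * obs$n1 / obs$n_scored,
      pct_0 = 100 * obs$n0 / obs$n_scored,
      s_hat = estimate_silencing(obs, p_use),
      chi2_raw = raw$chi2, p_raw = raw$p_value,
      chi2_adj = adj$chi2, p_adj_raw = adj$p_value
    )
  })
  out <- bind_rows(rows)
  m <- if (is.null(family_size)) nrow(out) else family_size
  out$p_adj <- bonferroni(out$p_adj_raw, m)
  out$significant <- out$p_adj < alpha
  attr(out, "error_estimate") <- err
  attr(out, "error_rate") <- error_rate
  attr(out, "family_size") <- m
  attr(out, "alpha") <- alpha
  out
}

heterogametic_efficiencies <- function(summaries, efficiencies) {
  sex_spec <- summaries %>%
    filter(.data$locus_class == "sex_specific", .data$sex == "heterogametic")
  est <- purrr::map(seq_len(nrow(sex_spec)), function(i) {
    estimate_efficiency(sex_spec[i, setdiff(names(sex_spec), "locus_class")])
  })
  est <- bind_rows(est)
  if (!is.null(efficiencies)) {
    if (!all(c("probe_id", "p_hat") %in% names(efficiencies))) {
      abort_validation("efficiencies must have columns probe_id and p_hat")
    }
    override <- as_tibble(efficiencies)
    override$q_hat <- 1 - override$p_hat
    override$n_het <- NA_integer_
    est <- bind_rows(
      override[, c("probe_id", "p_hat", "q_hat", "n_het")],
      est[!est$probe_id %in% override$probe_id, , drop = FALSE]
    )
  }
  est
}

scoring_tasks <- function(summaries, eff_tbl, pooled, pooled_p) {
  # sex-specific loci: tested in homogametic nuclei against the probe's own
  # heterogametic-sex efficiency
  ss <- summaries %>%
    filter(.data$locus_class == "sex_specific", .data$sex == "homogametic") %>%
    left_join(eff_tbl[, c("probe_id", "p_hat")], by = "probe_id")
  no_eff <- ss$probe_id[is.na(ss$p_hat)]
  if (length(no_eff) > 0) {
    inform(sprintf(
      "skipping sex-specific locus(s) without heterogametic efficiency: %s",
      paste(no_eff, collapse = ", ")
    ))
    ss <- ss[!is.na(ss$p_hat), ]
  }
  ss_tasks <- tibble(probe_id = ss$probe_id, sex = ss$sex, p_use = ss$p_hat)

  # PAR loci: biallelic in both sexes, tested in both, efficiency must come
  # from the caller or the pooled fallback
  par <- summaries %>%
    filter(.data$locus_class == "pseudoautosomal") %>%
    left_join(eff_tbl[, c("probe_id", "p_hat")], by = "probe_id")
  if (pooled && !is.na(pooled_p)) {
    par$p_hat[is.na(par$p_hat)] <- pooled_p
  }
  skipped <- unique(par$probe_id[is.na(par$p_hat)])
  if (length(skipped) > 0) {
    inform(sprintf(
      "skipping pseudoautosomal locus(s) without supplied efficiency: %s",
      paste(skipped, collapse = ", ")
    ))
    par <- par[!is.na(par$p_hat), ]
  }
  par_tasks <- tibble(probe_id = par$probe_id, sex = par$sex, p_use = par$p_hat)

  bind_rows(ss_tasks, par_tasks)
}

#' Export a chromosome activity map
#'
#' Writes one row per tested locus in a BED-like 6+ column layout: `chrom`,
#' `start`, `end` (0-based half-open, from the panel), `name` (probe id),
#' `score` (percent 1-active rounded to integer), `strand` (`.`; FISH scoring
#' is strandless), then `pct_2_active`, `pct_1_active`, `pct_0` and the
#' corrected p-value. Rows are sorted by chromosome then start so the file
#' reads as a per-chromosome activity map.
#'
#' @param results A scoring results tibble (see [score_panel()]).
#' @param panel The locus panel the probes belong to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_map <- function(results, panel, path) {
  panel <- validate_panel(panel)
  missing <- setdiff(unique(results$probe_id), panel$probe_id)
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "probe(s) not resolvable in panel: %s", paste(missing, collapse = ", ")
    ))
  }
  bed <- results %>%
    left_join(panel[, c("probe_id", "chromosome", "start", "end")],
              by = "probe_id") %>%
    mutate(
      name = .data$probe_id,
      score = as.integer(round(.data$pct_1_active)),
      strand = "."
    ) %>%
    arrange(.data$chromosome, .data$start) %>%
    select("chromosome", "start", "end", "name", "score", "strand",
           "pct_2_active", "pct_1_active", "pct_0", "p_adj")
  readr::write_tsv(bed, path, col_names = TRUE)
  invisible(path)
}
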