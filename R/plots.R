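#' Stacked-bar activity map of scored loci
#'
#' One bar per tested locus showing the percentage of homogametic (or, for
#' pseudoautosomal loci, per-sex) nuclei transcribing two (blue), one (red) or
#' zero (grey) alleles, faceted by chromosome — the per-chromosome activity
#' map view of the scoring results.
#'
#' @param results A scoring results tibble (see [score_panel()]).
#' @param panel The locus panel, used to order loci by chromosome and
#'   position.
#' @return A ggplot object.
#' @export
plot_activity_map <- function(results, panel) {
  panel <- validate_panel(panel)
  df <- results %>%
    left_join(panel[, c("probe_id", "chromosome", "start")], by = "probe_id") %>%
    arrange(.data$chromosome, .data$start) %>%
    mutate(locus = factor(
      paste(.data$probe_id, .data$sex, sep = "\n"),
      levels = unique(paste(.data$probe_id, .data$sex, sep = "\n"))
    )) %>%
    tidyr::pivot_longer(cols = c("pct_2_active", "pct_1_active", "pct_0"),
                        names_to = "category", values_to = "pct") %>%
    mutate(category = factor(.data$category,
                             levels = c("pct_0", "pct_1_active", "pct_2_active"),
                             labels = c("0 alleles", "1 allele", "2 alleles")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$pct,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("0 alleles" = "grey70",
                                          "1 allele" = "firebrick",
                                          "2 alleles" = "steelblue")) +
    ggplot2::facet_grid(. ~ chromosome, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "% nuclei", fill = "transcribing") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 7))
}
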