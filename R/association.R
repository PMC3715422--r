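#' Average monoallelic percentages across replicate experiments
#'
#' When a probe was hybridized more than once (e.g. fibroblasts from a second
#' individual), the replicate observed percentages are combined by an
#' unweighted mean before the association analysis.
#'
#' @param results A tibble with columns `probe_id` and `pct_1_active` (one row
#'   per replicate experiment).
#' @return A tibble with one row per probe: `probe_id`, `pct_1_active`,
#'   `n_replicates`.
#' @export
average_replicates <- function(results) {
  if (!all(c("probe_id", "pct_1_active") %in% names(results))) {
    abort_validation("results must have columns probe_id and pct_1_active")
  }
  results %>%
    group_by(.data$probe_id) %>%
    summarise(pct_1_active = mean(.data$pct_1_active),
              n_replicates = dplyr::n(), .groups = "drop")
}

#' Regress monoallelic frequency on between-sex expression ratio
#'
#' Ordinary least squares of the percentage of 1-active homogametic nuclei on
#' the homogametic:heterogametic expression ratio (e.g. M:F for a ZZ/ZW
#' species), one point per locus. A positive association means loci
#' over-expressed in the homogametic sex tend to be silenced in a larger
#' fraction of nuclei — the pattern expected if partial inactivation
#' counterbalances dosage. Loci named in `exclude` (e.g. sex-determination
#' genes whose dosage imbalance is functional) are dropped before fitting.
#'
#' @param points A tibble with columns `probe_id`, `expression_ratio` (> 0)
#'   and `pct_1_active`.
#' @param exclude Character vector of probe ids to drop; default none.
#' @return An object of class `ratio_fit`; see [tidy.ratio_fit()],
#'   [glance.ratio_fit()] and [autoplot.ratio_fit()].
#' @export
fit_ratio_regression <- function(points, exclude = character()) {
  required <- c("probe_id", "expression_ratio", "pct_1_active")
  missing <- setdiff(required, names(points))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "points lack column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  points <- as_tibble(points)
  points <- points[!points$probe_id %in% exclude, ]
  if (any(points$expression_ratio <= 0)) {
    abort_validation("expression ratios must be positive")
  }
  if (nrow(points) < 3) {
    abort_validation("at least 3 loci are required to fit the regression")
  }
  if (length(unique(points$expression_ratio)) < 2) {
    abort_validation("expression ratios are all identical; slope is undefined")
  }
  model <- lm(pct_1_active ~ expression_ratio, data = points)
  structure(list(model = model, data = points), class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Expression-ratio association: n = %d loci\n  slope = %.4g, intercept = %.4g\n  R^2 = %.3f, p = %.4g\n",
    g$n, g$slope, g$intercept, g$r_squared, g$p_value
  ))
  invisible(x)
}

#' Tidy the expression-ratio regression
#'
#' @param x A `ratio_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`.
#' @export
tidy.ratio_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
}

#' One-row summary of the expression-ratio regression
#'
#' @param x A `ratio_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`
#'   (F-test of the slope, df 1 and n - 2), `n`.
#' @export
glance.ratio_fit <- function(x, ...) {
  y <- x$data$pct_1_active
  rss <- sum(stats::residuals(x$model)^2)
  tss <- sum((y - mean(y))^2)
  n <- nrow(x$data)
  df2 <- n - 2
  # guard the degenerate edges lm's summary leaves as NaN: a constant response
  # carries no association (R^2 = 0), an exact fit is maximally significant
  r_squared <- if (tss == 0) 0 else 1 - rss / tss
  p_value <- if (tss == 0) {
    1
  } else if (rss == 0) {
    0
  } else {
    stats::pf((tss - rss) / (rss / df2), 1, df2, lower.tail = FALSE)
  }
  tibble(
    slope = unname(coef(x$model)["expression_ratio"]),
    intercept = unname(coef(x$model)["(Intercept)"]),
    r_squared = r_squared,
    p_value = p_value,
    n = n
  )
}

#' Scatter plot of the expression-ratio association
#'
#' @param object A `ratio_fit` object.
#' @param ... Unused.
#' @return A ggplot: one point per locus with the fitted line and the R²
#'   annotation.
#' @export
autoplot.ratio_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$expression_ratio,
                               y = .data$pct_1_active)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "expression ratio (homogametic : heterogametic)",
      y = "% 1-active nuclei (homogametic sex)",
      title = sprintf("R² = %.2f, p = %.3g (n = %d loci)",
                      g$r_squared, g$p_value, g$n)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
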