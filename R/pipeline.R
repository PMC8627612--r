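#' Per-comparison inter-instrument reliability report
#'
#' The main pipeline: validates and harmonizes a cohort of paired
#' assessments, computes Gwet's agreement coefficient for each of the eleven
#' matched comparisons (quadratic-weighted on the three-level scale for the
#' literature-search comparison, unweighted otherwise), attaches jackknife
#' confidence intervals and agreement-band labels, and returns one row per
#' comparison in the canonical order. The category scale of each comparison
#' is design-fixed (`NEG`/`POS`, or `N < PY < Y`), so unobserved categories
#' still contribute zero-propensity terms to the chance agreement.
#' Comparisons with fewer than two applicable reviews (or a degenerate
#' chance-agreement term) are reported as not estimable rather than dropped.
#'
#' @inheritParams harmonize_all
#' @param alpha Significance level for the confidence intervals (default
#'   0.05).
#' @return A tibble of class `agreement_report` with columns
#'   `comparison_id`, `domain`, `domain_name`, `label`, `amstar_items`,
#'   `robis_items`, `n_applicable`, `n_excluded`, `q`, `weighting`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `band`, `note`. Estimates are
#'   unrounded; use [format_report()] or the print method for the two-decimal
#'   reporting convention.
#' @examples
#' cohort <- simulate_cohort(n_reviews = 60, seed = 11)
#' run_reliability(cohort)
#' @export
run_reliability <- function(assessments, metadata = NULL,
                            table = comparison_table(),
                            rule_e_mode = c("ALL", "ANY"), alpha = 0.05) {
  rule_e_mode <- match.arg(rule_e_mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  pairs <- harmonize_all(assessments, metadata, table = table,
                         rule_e_mode = rule_e_mode)
  n_total <- length(unique(pairs$review_id))
  rows <- purrr::pmap(table, function(comparison_id, domain, domain_name,
                                      label, amstar_items, robis_items, rule,
                                      fully_overlapping, scale, weighting) {
    p <- pairs |>
      dplyr::filter(.data$comparison_id == .env$comparison_id, .data$applicable)
    categories <- if (scale == "ORDINAL3") c("N", "PY", "Y") else c("NEG", "POS")
    weights <- if (weighting == "QUADRATIC") "quadratic" else NULL
    base <- tibble(
      comparison_id = comparison_id, domain = domain,
      domain_name = domain_name, label = label,
      amstar_items = paste(amstar_items, collapse = "+"),
      robis_items = paste(robis_items, collapse = "+"),
      n_applicable = nrow(p), n_excluded = n_total - nrow(p),
      q = length(categories), weighting = weighting,
      estimate = NA_real_, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_,
      band = NA_character_, note = NA_character_
    )
    if (nrow(p) < 2L) {
      base$note <- "NOT_ESTIMABLE: fewer than 2 applicable reviews"
      return(base)
    }
    res <- tryCatch(
      gwet_ac(p[c("amstar_cat", "robis_cat")], categories = categories,
              weights = weights, conf_level = 1 - alpha,
              ci = nrow(p) >= 3L),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      base$note <- paste0("NOT_ESTIMABLE: ", conditionMessage(res))
      return(base)
    }
    base$estimate <- res$estimate
    base$se <- res$se
    base$ci_low <- res$ci_low
    base$ci_high <- res$ci_high
    base$band <- res$band
    base
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  attr(out, "rule_e_mode") <- rule_e_mode
  attr(out, "n_reviews") <- n_total
  class(out) <- c("agreement_report", class(out))
  out
}

#' Format a reliability report for display
#'
#' Applies the reporting convention (coefficients and interval bounds to two
#' decimals, ties rounded away from zero) and renders the
#' "Band; AC (CI low, CI high)" column used in tabular summaries.
#'
#' @param report An `agreement_report` from [run_reliability()].
#' @param digits Decimal places (default 2).
#' @return Tibble with the comparison identifiers and a formatted `agreement`
#'   column.
#' @export
format_report <- function(report, digits = 2) {
  fmt <- function(x) formatC(round_half_up(x, digits), format = "f", digits = digits)
  report |>
    as_tibble() |>
    dplyr::mutate(
      agreement = ifelse(
        is.na(.data$estimate),
        dplyr::coalesce(.data$note, "NOT_ESTIMABLE"),
        paste0(.data$band, "; ", fmt(.data$estimate), " (",
               fmt(.data$ci_low), ", ", fmt(.data$ci_high), ")")
      )
    ) |>
    dplyr::select("comparison_id", "domain", "domain_name", "label",
                  "amstar_items", "robis_items", "n_applicable", "agreement")
}

#' @export
print.agreement_report <- function(x, digits = 2, ...) {
  cat("Inter-instrument reliability over", attr(x, "n_reviews"),
      "reviews (11 matched comparisons)\n")
  f <- format_report(x, digits = digits)
  for (d in unique(f$domain)) {
    cat("\nDomain ", d, ": ", f$domain_name[f$domain == d][1], "\n", sep = "")
    sub <- f[f$domain == d, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf(
        "  c%-2d %-45s A%s vs R%s  n=%-4d %s\n",
        sub$comparison_id[i], sub$label[i], sub$amstar_items[i],
        sub$robis_items[i], sub$n_applicable[i], sub$agreement[i]
      ))
    }
  }
  invisible(x)
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble(
    n_reviews = attr(x, "n_reviews"),
    n_comparisons = nrow(x),
    n_estimable = sum(!is.na(x$estimate)),
    n_almost_perfect = sum(x$band == "ALMOST_PERFECT", na.rm = TRUE),
    n_substantial = sum(x$band == "SUBSTANTIAL", na.rm = TRUE),
    median_estimate = stats::median(x$estimate, na.rm = TRUE)
  )
}

#' Forest-style plot of a reliability report
#'
#' One row per comparison with the coefficient point estimate, its
#' confidence interval and the agreement-band thresholds as reference lines,
#' grouped by domain.
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::filter(!is.na(.data$estimate)) |>
    dplyr::mutate(
      comparison = factor(
        paste0("c", .data$comparison_id, ": ", .data$label),
        levels = rev(paste0("c", .data$comparison_id, ": ", .data$label))
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$comparison)) +
    ggplot2::geom_vline(xintercept = c(0, 0.2, 0.4, 0.6, 0.8),
                        linetype = "dotted", colour = "grey70") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$domain_name), size = 2.5) +
    ggplot2::labs(
      x = "Gwet's agreement coefficient (95% CI)", y = NULL,
      colour = "Domain",
      title = "Inter-instrument agreement across matched comparisons"
    ) +
    ggplot2::theme_minimal()
}

#' Structural audit of the comparison scheme
#'
#' Summarises the canonical matching: number of comparisons, matched and
#' unmatched items per instrument, the percentage of all 37 items covered,
#' and the count of fully overlapping comparisons.
#'
#' @param table Comparison table, by default [comparison_table()].
#' @return An object of class `structural_audit`: a list with elements
#'   `coverage` (see [coverage_stats()]), `unmatched` (see
#'   [unmatched_items()]) and `table`.
#' @examples
#' run_audit()
#' @export
run_audit <- function(table = comparison_table()) {
  out <- list(
    coverage = coverage_stats(table),
    unmatched = unmatched_items(table),
    table = table
  )
  class(out) <- "structural_audit"
  out
}

#' @export
print.structural_audit <- function(x, ...) {
  cv <- x$coverage
  cat("Structural audit of the AMSTAR-2/ROBIS comparison scheme\n")
  cat("  comparisons:          ", cv$n_comparisons, "\n")
  cat("  matched AMSTAR-2 items:", cv$n_amstar_matched, "\n")
  cat("  matched ROBIS items:   ", cv$n_robis_matched, "\n")
  cat("  items matched:         ",
      cv$n_amstar_matched + cv$n_robis_matched, "/37 = ",
      cv$pct_items_matched, "%\n", sep = "")
  cat("  fully overlapping:     ", cv$n_fully_overlapping, "\n")
  cat("  unmatched AMSTAR-2:    ",
      paste(x$unmatched$amstar, collapse = ", "), "\n")
  cat("  unmatched ROBIS:       ",
      paste(x$unmatched$robis, collapse = ", "), "\n")
  invisible(x)
}
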