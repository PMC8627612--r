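#' The canonical table of matched AMSTAR-2/ROBIS comparisons
#'
#' Returns the fixed set of 11 item-level comparisons between AMSTAR-2 and
#' ROBIS, grouped under the four ROBIS domains. Twelve AMSTAR-2 items and
#' fourteen ROBIS items take part; ROBIS item 4.4 is used twice (once against
#' AMSTAR-2 item 11 as part of the synthesis-appropriateness comparison, once
#' against item 14 on heterogeneity). Ten comparisons are fully overlapping
#' in construct; the publication-bias/robustness comparison (AMSTAR-2 item 15
#' vs ROBIS 4.5) is only partially overlapping. The comparison of AMSTAR-2
#' item 4 against ROBIS 2.1-2.4 is scored on a three-level ordered scale with
#' quadratic agreement weights; all others are binary and unweighted.
#'
#' Harmonization rules (see [harmonize_all()]):
#' * `DEFAULT_BINARY` - ROBIS `Y`/`PY` vs `N`/`PN`/`NI` against AMSTAR-2
#'   `Y` vs `N`;
#' * `A_BINARY_PYCOLLAPSE` - as default, with AMSTAR-2 `PY` merged into the
#'   positive category;
#' * `B_ORDINAL3_QUADRATIC` - composite three-level rule for ROBIS 2.1-2.4;
#' * `C_DESIGN_CONDITIONAL` - RCT/NRSI strata of AMSTAR-2 item 9 combined
#'   conjunctively;
#' * `E_MA_DESIGN_CONDITIONAL` - as C for item 11, gated on a meta-analysis
#'   being present, against the ROBIS 4.3+4.4 composite;
#' * `F_MA_COMPOSITE` - AMSTAR-2 items 12 and 13 combined (item 13 alone when
#'   there is no meta-analysis) against ROBIS 4.6;
#' * `G_MA_CONDITIONAL` - default binary rule gated on a meta-analysis.
#'
#' @return Tibble with 11 rows and columns `comparison_id`, `domain`,
#'   `domain_name`, `label`, `amstar_items` (list), `robis_items` (list),
#'   `rule`, `fully_overlapping`, `scale`, `weighting`.
#' @examples
#' comparison_table()
#' @export
comparison_table <- function() {
  tab <- tibble(
    comparison_id = 1:11,
    domain = c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 4L),
    label = c(
      "eligibility criteria / PICO",
      "a priori protocol",
      "comprehensive literature search",
      "duplicate study selection",
      "duplicate data extraction",
      "adequate description of included studies",
      "risk-of-bias assessment method",
      "appropriate statistical synthesis",
      "risk of bias in synthesis and interpretation",
      "heterogeneity addressed",
      "publication bias / robustness of findings"
    ),
    amstar_items = list("1", "2", "4", "5", "6", "8", "9", "11", c("12", "13"), "14", "15"),
    robis_items = list(
      "1.3", "1.1", c("2.1", "2.2", "2.3", "2.4"), "2.5", "3.1", "3.2",
      "3.4", c("4.3", "4.4"), "4.6", "4.4", "4.5"
    ),
    rule = c(
      "DEFAULT_BINARY", "A_BINARY_PYCOLLAPSE", "B_ORDINAL3_QUADRATIC",
      "DEFAULT_BINARY", "DEFAULT_BINARY", "A_BINARY_PYCOLLAPSE",
      "C_DESIGN_CONDITIONAL", "E_MA_DESIGN_CONDITIONAL", "F_MA_COMPOSITE",
      "DEFAULT_BINARY", "G_MA_CONDITIONAL"
    ),
    fully_overlapping = c(rep(TRUE, 10), FALSE),
    scale = c(
      "BINARY", "BINARY", "ORDINAL3", "BINARY", "BINARY", "BINARY",
      "BINARY", "BINARY", "BINARY", "BINARY", "BINARY"
    ),
    weighting = c(
      "IDENTITY", "IDENTITY", "QUADRATIC", "IDENTITY", "IDENTITY",
      "IDENTITY", "IDENTITY", "IDENTITY", "IDENTITY", "IDENTITY", "IDENTITY"
    )
  )
  tab$domain_name <- unname(.robis_domain_names[as.character(tab$domain)])
  tab[c("comparison_id", "domain", "domain_name", "label", "amstar_items",
        "robis_items", "rule", "fully_overlapping", "scale", "weighting")]
}

#' Structural coverage of the comparison table
#'
#' Summarises how much of the two instruments the matched comparisons cover:
#' the count of comparisons, the distinct matched items per instrument, the
#' percentage of the 37 items (16 AMSTAR-2 + 21 ROBIS) that are matched, and
#' the number of fully overlapping comparisons.
#'
#' @param table A comparison table, by default [comparison_table()].
#' @return One-row tibble with columns `n_comparisons`, `n_amstar_matched`,
#'   `n_robis_matched`, `pct_items_matched` (percent, one decimal),
#'   `n_fully_overlapping`.
#' @examples
#' coverage_stats()
#' @export
coverage_stats <- function(table = comparison_table()) {
  n_amstar <- length(unique(unlist(table$amstar_items)))
  n_robis <- length(unique(unlist(table$robis_items)))
  tibble(
    n_comparisons = nrow(table),
    n_amstar_matched = n_amstar,
    n_robis_matched = n_robis,
    pct_items_matched = round(100 * (n_amstar + n_robis) / 37, 1),
    n_fully_overlapping = sum(table$fully_overlapping)
  )
}

#' Items not covered by any comparison
#'
#' @param table A comparison table, by default [comparison_table()].
#' @return Named list with character vectors `amstar` and `robis` of item ids
#'   unique to each instrument.
#' @examples
#' unmatched_items()
#' @export
unmatched_items <- function(table = comparison_table()) {
  list(
    amstar = setdiff(build_schema("AMSTAR2")$item_id, unique(unlist(table$amstar_items))),
    robis = setdiff(build_schema("ROBIS")$item_id, unique(unlist(table$robis_items)))
  )
}

#' Export / import the comparison table as JSON
#'
#' The canonical matching is deliberately auditable: it can be serialized to
#' JSON and read back, so deviations from the shipped table are visible in
#' plain text.
#'
#' @param table A comparison table.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return `comparison_table_to_json()`: the JSON string (invisibly when
#'   written to file). `comparison_table_from_json()`: a comparison table
#'   tibble.
#' @export
comparison_table_to_json <- function(table = comparison_table(), path = NULL) {
  obj <- purrr::pmap(table, function(comparison_id, domain, domain_name, label,
                                     amstar_items, robis_items, rule,
                                     fully_overlapping, scale, weighting) {
    list(
      comparison_id = comparison_id, domain = domain, domain_name = domain_name,
      label = label, amstar_items = as.list(amstar_items),
      robis_items = as.list(robis_items), rule = rule,
      fully_overlapping = fully_overlapping, scale = scale, weighting = weighting
    )
  })
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname comparison_table_to_json
#' @param json JSON string or path to a JSON file written by
#'   `comparison_table_to_json()`.
#' @export
comparison_table_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  purrr::map_dfr(raw, function(x) {
    tibble(
      comparison_id = as.integer(x$comparison_id),
      domain = as.integer(x$domain),
      domain_name = x$domain_name,
      label = x$label,
      amstar_items = list(as.character(unlist(x$amstar_items))),
      robis_items = list(as.character(unlist(x$robis_items))),
      rule = x$rule,
      fully_overlapping = x$fully_overlapping,
      scale = x$scale,
      weighting = x$weighting
    )
  })
}
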