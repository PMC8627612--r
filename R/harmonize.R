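.robis_alphabet <- c("Y", "PY", "PN", "N", "NI")

.check_robis <- function(x, what = "ROBIS response") {
  bad <- !x %in% .robis_alphabet
  if (any(bad)) {
    stop(what, " outside the ROBIS alphabet: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

.pos <- function(x) x %in% c("Y", "PY")

#' Default binary harmonization of a ROBIS response
#'
#' The header rule of the matching scheme: ROBIS `Y` and `PY` correspond to
#' the positive AMSTAR-2 judgement, while `N`, `PN` and `NI` correspond to
#' the negative one.
#'
#' @param response Character vector of ROBIS response tokens.
#' @return Character vector of `"POS"`/`"NEG"` categories.
#' @examples
#' harmonize_robis_default(c("Y", "PY", "PN", "N", "NI"))
#' @export
harmonize_robis_default <- function(response) {
  response <- parse_response(response)
  .check_robis(response)
  ifelse(.pos(response), "POS", "NEG")
}

#' Default binary harmonization of an AMSTAR-2 response
#'
#' AMSTAR-2 `Y` (and `PY`, where the item admits it) maps to the positive
#' category and `N` to the negative one. The `NA` token is rejected: items
#' not considered for a review are excluded upstream, not harmonized.
#'
#' @param response Character vector of AMSTAR-2 response tokens.
#' @return Character vector of `"POS"`/`"NEG"` categories.
#' @export
harmonize_amstar_default <- function(response) {
  response <- parse_response(response)
  bad <- !response %in% c("Y", "PY", "N")
  if (any(bad)) {
    stop("AMSTAR-2 response not harmonizable: ",
         paste(unique(response[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(.pos(response), "POS", "NEG")
}

#' Composite three-level harmonization of ROBIS items 2.1-2.4
#'
#' The ROBIS side of the literature-search comparison (AMSTAR-2 item 4 vs
#' ROBIS 2.1-2.4) is scored on the ordered scale `N < PY < Y`: `Y` when all
#' four sub-items are `Y`/`PY`; `PY` when items 2.3 and 2.4 are both `Y`/`PY`
#' but not all four are; `N` otherwise. The AMSTAR-2 side passes item 4's own
#' `Y`/`PY`/`N` through unchanged, and agreement for this comparison uses
#' quadratic weights on the three-level scale.
#'
#' @param r21,r22,r23,r24 ROBIS responses to items 2.1-2.4 (vectorized).
#' @return Character vector with values in `c("N", "PY", "Y")`.
#' @examples
#' harmonize_rule_b("Y", "Y", "Y", "PY")  # "Y"
#' harmonize_rule_b("N", "Y", "Y", "PY")  # "PY"
#' harmonize_rule_b("Y", "Y", "N", "Y")   # "N"
#' @export
harmonize_rule_b <- function(r21, r22, r23, r24) {
  args <- list(r21 = r21, r22 = r22, r23 = r23, r24 = r24)
  args <- lapply(args, parse_response)
  for (nm in names(args)) {
    .check_robis(args[[nm]], paste0("ROBIS item 2.", substr(nm, 3, 3), " response"))
  }
  all4 <- .pos(args$r21) & .pos(args$r22) & .pos(args$r23) & .pos(args$r24)
  core <- .pos(args$r23) & .pos(args$r24)
  dplyr::case_when(all4 ~ "Y", core ~ "PY", TRUE ~ "N")
}

# conjunctive positivity of a possibly design-stratified AMSTAR-2 item:
# x is a single response (single-design review) or a named c(RCT=, NRSI=)
# vector; positive iff every required stratum meets `accept`
.stratified_pos <- function(x, design_mix, accept = c("Y", "PY"), item = "9") {
  x <- parse_response(x)
  if (identical(design_mix, "BOTH")) {
    if (is.null(names(x)) || !all(c("RCT", "NRSI") %in% names(x))) {
      stop("design_mix is BOTH but AMSTAR-2 item ", item,
           " is missing an RCT or NRSI stratum response", call. = FALSE)
    }
    all(x[c("RCT", "NRSI")] %in% accept)
  } else {
    if (length(x) != 1L) {
      stop("single-design review: AMSTAR-2 item ", item,
           " must have exactly one response", call. = FALSE)
    }
    unname(x) %in% accept
  }
}

#' Design-conditional harmonization of AMSTAR-2 item 9 vs ROBIS 3.4
#'
#' For single-design reviews the default binary rule applies to item 9. For
#' reviews including both RCTs and NRSI, the AMSTAR-2 side is positive only
#' when *both* design strata are `Y`/`PY`. The ROBIS side follows the default
#' rule on item 3.4.
#'
#' @param a9 AMSTAR-2 item-9 response: a single token, or for `design_mix =
#'   "BOTH"` a named vector `c(RCT = , NRSI = )`.
#' @param r34 ROBIS item-3.4 response.
#' @param design_mix `"RCT_ONLY"`, `"NRSI_ONLY"` or `"BOTH"`.
#' @return Named list with elements `amstar`, `robis` (each `"POS"`/`"NEG"`)
#'   and `applicable = TRUE`.
#' @examples
#' harmonize_rule_c(c(RCT = "Y", NRSI = "PY"), "Y", "BOTH")
#' @export
harmonize_rule_c <- function(a9, r34, design_mix) {
  list(
    amstar = if (.stratified_pos(a9, design_mix, item = "9")) "POS" else "NEG",
    robis = harmonize_robis_default(r34),
    applicable = TRUE
  )
}

#' Meta-analysis- and design-conditional harmonization of item 11 vs ROBIS 4.3/4.4
#'
#' Not considered when the review has no meta-analysis. Otherwise the
#' AMSTAR-2 side is positive only for an unqualified `Y` on item 11 (both
#' design strata `Y` when the review includes RCTs and NRSI). The ROBIS side
#' combines items 4.3 and 4.4: by default both must be `Y`/`PY`
#' (`robis_mode = "ALL"`); `robis_mode = "ANY"` accepts either.
#'
#' @param a11 AMSTAR-2 item-11 response (single token, or named
#'   `c(RCT = , NRSI = )` when `design_mix = "BOTH"`).
#' @param r43,r44 ROBIS responses to items 4.3 and 4.4.
#' @param has_ma Did the review perform a meta-analysis?
#' @param design_mix `"RCT_ONLY"`, `"NRSI_ONLY"` or `"BOTH"`.
#' @param robis_mode `"ALL"` (default) or `"ANY"`: how 4.3 and 4.4 combine.
#' @return Named list with elements `amstar`, `robis`, `applicable`. When
#'   `has_ma` is `FALSE` the categories are `NA` and `applicable` is `FALSE`.
#' @export
harmonize_rule_e <- function(a11, r43, r44, has_ma, design_mix,
                             robis_mode = c("ALL", "ANY")) {
  robis_mode <- match.arg(robis_mode)
  if (!isTRUE(has_ma)) {
    return(list(amstar = NA_character_, robis = NA_character_, applicable = FALSE))
  }
  r43 <- parse_response(r43); r44 <- parse_response(r44)
  .check_robis(r43, "ROBIS item 4.3 response")
  .check_robis(r44, "ROBIS item 4.4 response")
  robis_pos <- if (robis_mode == "ALL") .pos(r43) && .pos(r44) else .pos(r43) || .pos(r44)
  list(
    amstar = if (.stratified_pos(a11, design_mix, accept = "Y", item = "11")) "POS" else "NEG",
    robis = if (robis_pos) "POS" else "NEG",
    applicable = TRUE
  )
}

#' Composite harmonization of AMSTAR-2 items 12+13 vs ROBIS 4.6
#'
#' When the review has no meta-analysis, item 12 is not assessed (`NA`) and
#' only item 13 is compared with ROBIS 4.6: AMSTAR-2 positive iff item 13 is
#' `Y`. With a meta-analysis, the AMSTAR-2 side is positive iff both items 12
#' and 13 are `Y`. The ROBIS side follows the default rule on item 4.6.
#'
#' @param a12,a13 AMSTAR-2 responses to items 12 and 13 (`a12` must be the
#'   `NA` token exactly when `has_ma` is `FALSE`).
#' @param r46 ROBIS item-4.6 response.
#' @param has_ma Did the review perform a meta-analysis?
#' @return Named list with elements `amstar`, `robis`, `applicable = TRUE`.
#' @export
harmonize_rule_f <- function(a12, a13, r46, has_ma) {
  a12 <- parse_response(a12); a13 <- parse_response(a13)
  if (isTRUE(has_ma) && a12 == "NA") {
    stop("item 12 is NA although the review has a meta-analysis", call. = FALSE)
  }
  if (!isTRUE(has_ma) && a12 != "NA") {
    stop("item 12 must be NA when the review has no meta-analysis", call. = FALSE)
  }
  amstar_pos <- if (isTRUE(has_ma)) a12 == "Y" && a13 == "Y" else a13 == "Y"
  list(
    amstar = if (amstar_pos) "POS" else "NEG",
    robis = harmonize_robis_default(r46),
    applicable = TRUE
  )
}

# wide per-review response matrix for one instrument; columns get prefixed
# names ("a4", "a9_RCT", "r2.3", ...); absent strata columns are created as NA
.wide_responses <- function(assessments, instrument, prefix) {
  w <- assessments |>
    dplyr::filter(.data$instrument == .env$instrument) |>
    dplyr::mutate(
      col = paste0(
        prefix, .data$item_id,
        ifelse(is.na(.data$stratum), "", paste0("_", .data$stratum))
      )
    ) |>
    dplyr::select("review_id", "col", "response") |>
    tidyr::pivot_wider(names_from = "col", values_from = "response")
  for (col in paste0("a", c("9", "9_RCT", "9_NRSI", "11", "11_RCT", "11_NRSI"))) {
    if (prefix == "a" && !col %in% names(w)) w[[col]] <- NA_character_
  }
  w
}

#' Harmonize a cohort of paired assessments across all comparisons
#'
#' Applies each comparison's harmonization rule to every review, producing
#' the per-comparison pairs of harmonized categories on which agreement is
#' computed. Comparisons gated on a meta-analysis (item 11 vs 4.3+4.4 and
#' item 15 vs 4.5) mark reviews without one as not applicable; the items
#' 12+13 vs 4.6 comparison instead falls back to item 13 alone for such
#' reviews. Reviews failing [validate_assessment()] are dropped from all
#' comparisons with a warning.
#'
#' @param assessments,metadata Long assessments and review metadata as for
#'   [validate_assessment()]. A `synthetic_cohort` may be passed as
#'   `assessments`, in which case `metadata` is taken from it.
#' @param table Comparison table, by default [comparison_table()].
#' @param rule_e_mode How ROBIS items 4.3/4.4 combine in the item-11
#'   comparison: `"ALL"` (default, both positive) or `"ANY"`.
#' @return Tibble with columns `comparison_id`, `review_id`, `amstar_cat`,
#'   `robis_cat`, `applicable`. Categories are `"POS"`/`"NEG"` for binary
#'   comparisons and `"N"`/`"PY"`/`"Y"` for the ordinal one; both are `NA`
#'   where `applicable` is `FALSE`.
#' @examples
#' cohort <- simulate_cohort(n_reviews = 6, seed = 7)
#' harmonize_all(cohort)
#' @export
harmonize_all <- function(assessments, metadata = NULL,
                          table = comparison_table(),
                          rule_e_mode = c("ALL", "ANY")) {
  rule_e_mode <- match.arg(rule_e_mode)
  if (inherits(assessments, "synthetic_cohort")) {
    metadata <- assessments$metadata
    assessments <- assessments$assessments
  }
  if (is.null(metadata)) stop("metadata is required", call. = FALSE)

  a <- as_tibble(assessments)
  if (!"stratum" %in% names(a)) a$stratum <- NA_character_
  a <- a |>
    dplyr::mutate(
      review_id = as.character(.data$review_id),
      instrument = toupper(as.character(.data$instrument)),
      item_id = as.character(.data$item_id),
      stratum = dplyr::na_if(toupper(trimws(dplyr::coalesce(as.character(.data$stratum), ""))), ""),
      response = parse_response(.data$response)
    )
  m <- as_tibble(metadata) |>
    dplyr::mutate(review_id = as.character(.data$review_id),
                  design_mix = toupper(as.character(.data$design_mix)))

  v <- validate_assessment(a, m)
  if (nrow(v) > 0) {
    bad <- unique(v$review_id[!is.na(v$review_id)])
    warning(
      "dropping ", length(bad), " review(s) with validation violations: ",
      paste(utils::head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ...",
      call. = FALSE
    )
    a <- a |> dplyr::filter(!.data$review_id %in% bad)
    m <- m |> dplyr::filter(!.data$review_id %in% bad)
  }
  if (nrow(m) == 0) {
    return(tibble(
      comparison_id = integer(), review_id = character(),
      amstar_cat = character(), robis_cat = character(), applicable = logical()
    ))
  }

  w <- m |>
    dplyr::left_join(.wide_responses(a, "AMSTAR2", "a"), by = "review_id") |>
    dplyr::left_join(.wide_responses(a, "ROBIS", "r"), by = "review_id")
  both <- w$design_mix == "BOTH"
  # conjunctive stratum collapse for items 9 and 11 of mixed-design reviews
  strat_pos <- function(single, rct, nrsi, accept) {
    ifelse(both,
           rct %in% accept & nrsi %in% accept,
           single %in% accept)
  }
  bin <- function(x) ifelse(x, "POS", "NEG")
  pos <- function(x) x %in% c("Y", "PY")

  rows <- purrr::pmap(table, function(comparison_id, domain, domain_name, label,
                                      amstar_items, robis_items, rule, ...) {
    out <- tibble(
      comparison_id = comparison_id,
      review_id = w$review_id,
      applicable = TRUE
    )
    if (rule %in% c("DEFAULT_BINARY", "A_BINARY_PYCOLLAPSE", "G_MA_CONDITIONAL")) {
      av <- w[[paste0("a", amstar_items[1])]]
      rv <- w[[paste0("r", robis_items[1])]]
      if (rule == "G_MA_CONDITIONAL") out$applicable <- w$has_ma
      out$amstar_cat <- ifelse(out$applicable, bin(pos(av)), NA_character_)
      out$robis_cat <- ifelse(out$applicable, bin(pos(rv)), NA_character_)
    } else if (rule == "B_ORDINAL3_QUADRATIC") {
      out$amstar_cat <- w$a4
      out$robis_cat <- harmonize_rule_b(w$`r2.1`, w$`r2.2`, w$`r2.3`, w$`r2.4`)
    } else if (rule == "C_DESIGN_CONDITIONAL") {
      out$amstar_cat <- bin(strat_pos(w$a9, w$a9_RCT, w$a9_NRSI, c("Y", "PY")))
      out$robis_cat <- bin(pos(w$`r3.4`))
    } else if (rule == "E_MA_DESIGN_CONDITIONAL") {
      out$applicable <- w$has_ma
      robis_pos <- if (rule_e_mode == "ALL") {
        pos(w$`r4.3`) & pos(w$`r4.4`)
      } else {
        pos(w$`r4.3`) | pos(w$`r4.4`)
      }
      out$amstar_cat <- ifelse(
        out$applicable, bin(strat_pos(w$a11, w$a11_RCT, w$a11_NRSI, "Y")),
        NA_character_
      )
      out$robis_cat <- ifelse(out$applicable, bin(robis_pos), NA_character_)
    } else if (rule == "F_MA_COMPOSITE") {
      out$amstar_cat <- bin(ifelse(w$has_ma, w$a12 == "Y" & w$a13 == "Y", w$a13 == "Y"))
      out$robis_cat <- bin(pos(w$`r4.6`))
    } else {
      stop("unknown harmonization rule: ", rule, call. = FALSE)
    }
    out[c("comparison_id", "review_id", "amstar_cat", "robis_cat", "applicable")]
  })
  dplyr::bind_rows(rows)
}
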