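.amstar2_rating_levels <- c("CRITICALLY_LOW", "LOW", "MODERATE", "HIGH")

#' AMSTAR-2 overall confidence rating
#'
#' Computes the four-level overall confidence rating per review from the 16
#' AMSTAR-2 item responses. A "major flaw" is an `N` response; for the
#' design-stratified items (9 and 11) of reviews including both RCTs and
#' NRSI, the item counts as flawed when *any* stratum is `N` (the instrument
#' requires a positive judgement for both designs). Items answered `NA`
#' (meta-analysis-conditional items of reviews without a meta-analysis) are
#' excluded from both flaw counts. The rating rule is:
#'
#' * `HIGH` - no critical flaw and at most one non-critical flaw;
#' * `MODERATE` - no critical flaw and more than one non-critical flaw;
#' * `LOW` - exactly one critical flaw (regardless of non-critical flaws);
#' * `CRITICALLY_LOW` - more than one critical flaw.
#'
#' `PY` is an affirmative partial judgement and does not count as a flaw by
#' default. Because published guidance leaves room for a stricter reading on
#' the critical items, `strict_py_flaw = TRUE` counts `PY` on a critical
#' item as a flaw.
#'
#' @param assessments,metadata Long assessments and review metadata as for
#'   [validate_assessment()].
#' @param strict_py_flaw Count `PY` on critical items as a flaw? Default
#'   `FALSE`.
#' @param validate Validate first and fail on any violation? Default `TRUE`.
#' @return Tibble with one row per review: `review_id`, `critical_flaws`,
#'   `noncritical_flaws`, `rating` (ordered factor
#'   `CRITICALLY_LOW < LOW < MODERATE < HIGH`).
#' @examples
#' cohort <- simulate_cohort(n_reviews = 5, seed = 42)
#' amstar2_overall(cohort$assessments, cohort$metadata)
#' @export
amstar2_overall <- function(assessments, metadata, strict_py_flaw = FALSE,
                            validate = TRUE) {
  if (validate) {
    v <- validate_assessment(assessments, metadata)
    if (nrow(v) > 0) {
      stop(
        "invalid assessments (", nrow(v), " violation",
        if (nrow(v) > 1) "s", "); first: review ", v$review_id[1], ", ",
        v$instrument[1], " item ", v$item_id[1], ": ", v$issue[1],
        call. = FALSE
      )
    }
  }
  schema <- build_schema("AMSTAR2")
  flaws <- as_tibble(assessments) |>
    dplyr::mutate(
      review_id = as.character(.data$review_id),
      instrument = toupper(as.character(.data$instrument)),
      item_id = as.character(.data$item_id),
      response = parse_response(.data$response)
    ) |>
    dplyr::filter(.data$instrument == "AMSTAR2", .data$response != "NA") |>
    dplyr::left_join(schema[c("item_id", "critical")], by = "item_id") |>
    dplyr::group_by(.data$review_id, .data$item_id, .data$critical) |>
    # any-stratum N: one N in either design stratum flaws the whole item
    dplyr::summarise(
      flaw = any(.data$response == "N") ||
        (strict_py_flaw && .data$critical[1] && any(.data$response == "PY")),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$review_id) |>
    dplyr::summarise(
      critical_flaws = sum(.data$flaw & .data$critical),
      noncritical_flaws = sum(.data$flaw & !.data$critical),
      .groups = "drop"
    )
  flaws |>
    dplyr::mutate(
      rating = factor(
        dplyr::case_when(
          .data$critical_flaws > 1L ~ "CRITICALLY_LOW",
          .data$critical_flaws == 1L ~ "LOW",
          .data$noncritical_flaws > 1L ~ "MODERATE",
          TRUE ~ "HIGH"
        ),
        levels = .amstar2_rating_levels, ordered = TRUE
      )
    )
}
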