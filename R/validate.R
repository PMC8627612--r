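#' Validate paired assessments against the instrument schemas
#'
#' Checks a long-format assessment table and its review metadata against the
#' AMSTAR-2 and ROBIS schemas. Violations are returned as data, one row per
#' problem, never raised as errors: an empty result means the assessments are
#' valid. Checks cover unknown instruments/items, duplicated records, missing
#' responses, illegal response codes (including `PY` on items that do not
#' admit it), the `NA` token appearing anywhere except on meta-analysis-
#' conditional AMSTAR-2 items of reviews without a meta-analysis, and
#' missing or superfluous RCT/NRSI design strata on AMSTAR-2 items 9 and 11.
#'
#' @param assessments Tibble with columns `review_id`, `instrument`
#'   (`"AMSTAR2"` or `"ROBIS"`), `item_id`, `response` and optionally
#'   `stratum` (`"RCT"`/`"NRSI"`, empty otherwise). Responses are
#'   canonicalized with [parse_response()] before checking.
#' @param metadata Tibble with columns `review_id`, `has_ma` (logical) and
#'   `design_mix` (`"RCT_ONLY"`, `"NRSI_ONLY"` or `"BOTH"`).
#' @return A tibble with columns `review_id`, `instrument`, `item_id`,
#'   `stratum`, `issue`; zero rows when everything is valid.
#' @examples
#' cohort <- simulate_cohort(n_reviews = 4, seed = 1)
#' validate_assessment(cohort$assessments, cohort$metadata)
#' @export
validate_assessment <- function(assessments, metadata) {
  need <- c("review_id", "instrument", "item_id", "response")
  if (!all(need %in% names(assessments))) {
    stop("assessments must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(c("review_id", "has_ma", "design_mix") %in% names(metadata))) {
    stop("metadata must have columns review_id, has_ma, design_mix", call. = FALSE)
  }
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
    dplyr::mutate(
      review_id = as.character(.data$review_id),
      design_mix = toupper(as.character(.data$design_mix))
    )

  viol <- list()
  note <- function(df, issue) {
    if (nrow(df) == 0) return(NULL)
    tibble(
      review_id = df$review_id,
      instrument = if ("instrument" %in% names(df)) df$instrument else NA_character_,
      item_id = if ("item_id" %in% names(df)) df$item_id else NA_character_,
      stratum = if ("stratum" %in% names(df)) df$stratum else NA_character_,
      issue = issue
    )
  }

  # --- metadata-level checks -------------------------------------------------
  bad_meta <- m |> dplyr::filter(!.data$design_mix %in% c("RCT_ONLY", "NRSI_ONLY", "BOTH"))
  viol$design <- note(bad_meta, "illegal design_mix (expected RCT_ONLY, NRSI_ONLY or BOTH)")
  if (!is.logical(m$has_ma)) {
    viol$has_ma <- note(m, "has_ma must be TRUE or FALSE")
    m$has_ma <- NA
  } else {
    viol$has_ma <- note(dplyr::filter(m, is.na(.data$has_ma)), "has_ma must be TRUE or FALSE")
  }
  orphans <- a |>
    dplyr::distinct(.data$review_id) |>
    dplyr::anti_join(m, by = "review_id")
  viol$orphans <- note(orphans, "no metadata record for this review")

  # --- row-level checks ------------------------------------------------------
  bad_instr <- a |> dplyr::filter(!.data$instrument %in% c("AMSTAR2", "ROBIS"))
  viol$instr <- note(bad_instr, "unknown instrument (expected AMSTAR2 or ROBIS)")
  a <- a |> dplyr::filter(.data$instrument %in% c("AMSTAR2", "ROBIS"))

  schema <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(build_schema("AMSTAR2")), instrument = "AMSTAR2"),
    dplyr::mutate(as_tibble(build_schema("ROBIS")), instrument = "ROBIS")
  )
  a <- a |> dplyr::left_join(
    schema[c("instrument", "item_id", "critical", "ma_conditional", "allows_py",
             "stratified_by_design")],
    by = c("instrument", "item_id")
  )
  viol$item <- note(
    dplyr::filter(a, is.na(.data$allows_py)),
    "unknown item_id for this instrument"
  )
  a <- a |> dplyr::filter(!is.na(.data$allows_py))

  viol$stratok <- note(
    dplyr::filter(a, !is.na(.data$stratum) & !.data$stratum %in% c("RCT", "NRSI")),
    "illegal stratum (expected RCT or NRSI)"
  )
  viol$stratitem <- note(
    dplyr::filter(a, !is.na(.data$stratum) & !.data$stratified_by_design),
    "stratum given for an item that is not stratified by design"
  )
  dup <- a |>
    dplyr::count(.data$review_id, .data$instrument, .data$item_id, .data$stratum) |>
    dplyr::filter(.data$n > 1L)
  viol$dup <- note(dup, "duplicated record")

  # --- completeness: compare observed rows with the expected grid ------------
  reviews <- m |>
    dplyr::filter(
      .data$design_mix %in% c("RCT_ONLY", "NRSI_ONLY", "BOTH"),
      !is.na(.data$has_ma)
    )
  expected <- tidyr::crossing(
    reviews[c("review_id", "has_ma", "design_mix")],
    schema[c("instrument", "item_id", "ma_conditional", "allows_py",
             "stratified_by_design")]
  ) |>
    dplyr::mutate(
      # stratified items carry one row per design stratum, except item 11 of
      # a review without a meta-analysis, which collapses to a single NA row
      split = .data$stratified_by_design & .data$design_mix == "BOTH" &
        !(.data$ma_conditional & !.data$has_ma)
    )
  expected <- dplyr::bind_rows(
    expected |> dplyr::filter(!.data$split) |> dplyr::mutate(stratum = NA_character_),
    expected |> dplyr::filter(.data$split) |> dplyr::mutate(stratum = "RCT"),
    expected |> dplyr::filter(.data$split) |> dplyr::mutate(stratum = "NRSI")
  )
  key <- c("review_id", "instrument", "item_id", "stratum")
  obs <- a |>
    dplyr::semi_join(reviews, by = "review_id") |>
    dplyr::filter(is.na(.data$stratum) | .data$stratum %in% c("RCT", "NRSI")) |>
    dplyr::filter(!(!is.na(.data$stratum) & !.data$stratified_by_design))
  viol$missing <- note(
    dplyr::anti_join(expected, obs, by = key),
    "missing response"
  )
  viol$extra <- note(
    dplyr::anti_join(obs, expected, by = key),
    "superfluous record (stratum not expected for this review's design/meta-analysis status)"
  )

  # --- response legality -----------------------------------------------------
  checked <- a |>
    dplyr::inner_join(reviews[c("review_id", "has_ma")], by = "review_id") |>
    dplyr::mutate(
      legal = purrr::pmap_lgl(
        list(.data$instrument, .data$allows_py, .data$ma_conditional,
             .data$has_ma, .data$response),
        function(instrument, allows_py, ma_conditional, has_ma, response) {
          response %in% .legal_responses(instrument, allows_py, ma_conditional, has_ma)
        }
      )
    ) |>
    dplyr::filter(!.data$legal) |>
    dplyr::mutate(
      issue = dplyr::case_when(
        .data$instrument == "ROBIS" & .data$response == "NA" ~
          "NA is not a ROBIS response code",
        .data$response == "NA" & !.data$ma_conditional ~
          "NA on a non-conditional item",
        .data$response == "NA" & .data$ma_conditional & .data$has_ma ~
          "NA on a conditional item although the review has a meta-analysis",
        .data$ma_conditional & !.data$has_ma & .data$response != "NA" ~
          "must be NA: review has no meta-analysis",
        .data$response == "PY" & !.data$allows_py ~
          "item does not admit PY",
        TRUE ~ paste0("illegal response code: ", .data$response)
      )
    )
  viol$resp <- checked[c("review_id", "instrument", "item_id", "stratum", "issue")]

  out <- dplyr::bind_rows(viol)
  if (nrow(out) == 0) {
    out <- tibble(
      review_id = character(), instrument = character(), item_id = character(),
      stratum = character(), issue = character()
    )
  }
  dplyr::arrange(out, .data$review_id, .data$instrument, .data$item_id)
}
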