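.robis_domain_names <- c(
  "1" = "Study eligibility criteria",
  "2" = "Identification and selection of studies",
  "3" = "Data collection and study appraisal",
  "4" = "Synthesis and findings"
)

.amstar2_labels <- c(
  "1"  = "PICO components in research question and inclusion criteria",
  "2"  = "review methods established before conduct (protocol)",
  "3"  = "selection of study designs for inclusion explained",
  "4"  = "comprehensive literature search strategy",
  "5"  = "study selection performed in duplicate",
  "6"  = "data extraction performed in duplicate",
  "7"  = "list of excluded studies with justification",
  "8"  = "included studies described in adequate detail",
  "9"  = "satisfactory technique for assessing risk of bias",
  "10" = "sources of funding of included studies reported",
  "11" = "appropriate methods for statistical combination of results",
  "12" = "impact of risk of bias on synthesis results assessed",
  "13" = "risk of bias accounted for when interpreting results",
  "14" = "satisfactory explanation and discussion of heterogeneity",
  "15" = "publication bias investigated and its impact discussed",
  "16" = "potential sources of conflict of interest reported"
)

.robis_labels <- c(
  "1.1" = "adhered to predefined objectives and eligibility criteria",
  "1.2" = "eligibility criteria appropriate for the review question",
  "1.3" = "eligibility criteria unambiguous",
  "1.4" = "restrictions based on study characteristics appropriate",
  "1.5" = "restrictions based on sources of information appropriate",
  "2.1" = "appropriate range of databases/electronic sources searched",
  "2.2" = "methods additional to database searching used",
  "2.3" = "search terms and structure likely to retrieve eligible studies",
  "2.4" = "restrictions based on date, format or language appropriate",
  "2.5" = "efforts made to minimize error in study selection",
  "3.1" = "efforts made to minimize error in data collection",
  "3.2" = "sufficient study characteristics for interpretation",
  "3.3" = "all relevant study results collected for the synthesis",
  "3.4" = "risk of bias formally assessed with appropriate criteria",
  "3.5" = "efforts made to minimize error in risk-of-bias assessment",
  "4.1" = "synthesis included all studies it should",
  "4.2" = "predefined analyses reported or departures explained",
  "4.3" = "synthesis appropriate given questions, designs and outcomes",
  "4.4" = "between-study variation minimal or addressed",
  "4.5" = "findings robust (e.g. funnel plot, sensitivity analyses)",
  "4.6" = "biases in primary studies minimal or addressed"
)

#' Build an instrument schema
#'
#' Returns the fixed item schema of one of the two instruments as a tibble
#' with one row per item. AMSTAR-2 has 16 items of which seven are critical
#' (2, 4, 7, 9, 11, 13, 15), five admit a "partially yes" response (2, 4, 7,
#' 8, 9), three are assessed only when the review performed a meta-analysis
#' (11, 12, 15), and two (9, 11) may carry separate responses for randomised
#' trials (RCT) and non-randomised studies (NRSI) when a review includes
#' both designs. ROBIS has 21 items in four domains (5, 5, 5, 6 items), all
#' answered on the five-point scale `Y`/`PY`/`PN`/`N`/`NI`.
#'
#' The `domain` column carries the ROBIS domain for ROBIS items and, for
#' AMSTAR-2 items, the matched reporting domain used by the cross-instrument
#' comparisons (items 1-3 map to domain 1, 4-5 to 2, 6-10 to 3, 11-16 to 4).
#'
#' @param name Instrument name, `"AMSTAR2"` or `"ROBIS"`.
#' @return A tibble of class `instrument_schema` with columns `item_id`,
#'   `label`, `domain`, `domain_name`, `critical`, `ma_conditional`,
#'   `allows_py`, `stratified_by_design` and the list-column `responses`
#'   (legal response tokens per item). The instrument name is stored in the
#'   `"instrument"` attribute.
#' @examples
#' build_schema("AMSTAR2")
#' nrow(build_schema("ROBIS"))
#' @export
build_schema <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% c("AMSTAR2", "ROBIS")) {
    stop("unknown instrument name; expected \"AMSTAR2\" or \"ROBIS\"", call. = FALSE)
  }
  if (name == "AMSTAR2") {
    ids <- as.character(1:16)
    schema <- tibble(
      item_id = ids,
      label = unname(.amstar2_labels[ids]),
      domain = rep(1:4, times = c(3L, 2L, 5L, 6L)),
      critical = ids %in% c("2", "4", "7", "9", "11", "13", "15"),
      ma_conditional = ids %in% c("11", "12", "15"),
      allows_py = ids %in% c("2", "4", "7", "8", "9"),
      stratified_by_design = ids %in% c("9", "11")
    )
    schema$responses <- purrr::pmap(
      schema[c("allows_py", "ma_conditional")],
      function(allows_py, ma_conditional) {
        c("Y", if (allows_py) "PY", "N", if (ma_conditional) "NA")
      }
    )
  } else {
    ids <- names(.robis_labels)
    schema <- tibble(
      item_id = ids,
      label = unname(.robis_labels),
      domain = as.integer(substr(ids, 1L, 1L)),
      critical = FALSE,
      ma_conditional = FALSE,
      allows_py = TRUE,
      stratified_by_design = FALSE
    )
    schema$responses <- rep(list(c("Y", "PY", "PN", "N", "NI")), nrow(schema))
  }
  schema$domain_name <- unname(.robis_domain_names[as.character(schema$domain)])
  schema <- schema[c(
    "item_id", "label", "domain", "domain_name", "critical",
    "ma_conditional", "allows_py", "stratified_by_design", "responses"
  )]
  attr(schema, "instrument") <- name
  class(schema) <- c("instrument_schema", class(schema))
  schema
}

#' Export an instrument schema as JSON
#'
#' @param schema An `instrument_schema` from [build_schema()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
schema_to_json <- function(schema, path = NULL) {
  stopifnot(inherits(schema, "instrument_schema"))
  obj <- list(
    instrument = attr(schema, "instrument"),
    items = purrr::pmap(
      as_tibble(schema),
      function(item_id, label, domain, domain_name, critical, ma_conditional,
               allows_py, stratified_by_design, responses) {
        list(
          item_id = item_id, label = label, domain = domain,
          critical = critical, ma_conditional = ma_conditional,
          allows_py = allows_py, stratified_by_design = stratified_by_design,
          responses = as.list(responses)
        )
      }
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# legal responses for one item, given review metadata; returns character vector
.legal_responses <- function(instrument, allows_py, ma_conditional, has_ma) {
  if (instrument == "ROBIS") return(c("Y", "PY", "PN", "N", "NI"))
  if (ma_conditional && !has_ma) return("NA")
  c("Y", if (allows_py) "PY", "N")
}

#' Heuristic ROBIS domain-concern profile
#'
#' The published ROBIS procedure asks assessors to make a narrative judgement
#' of concern per domain; no algorithm maps item responses to that judgement.
#' This helper provides a mechanical stand-in only: a domain is `LOW` concern
#' when all its items are `Y`/`PY`, `HIGH` when any item is `N`/`PN`, and
#' `UNCLEAR` otherwise. It is not part of the instrument and is never used by
#' the agreement pipeline; call it with `acknowledge_heuristic = TRUE` to
#' confirm you want the unvalidated shortcut.
#'
#' @param assessments Long assessment tibble (see [read_assessments()]).
#' @param acknowledge_heuristic Must be set to `TRUE`.
#' @return Tibble with columns `review_id`, `domain`, `concern`.
#' @export
robis_concern_heuristic <- function(assessments, acknowledge_heuristic = FALSE) {
  if (!isTRUE(acknowledge_heuristic)) {
    stop(
      "this domain-concern profile is a mechanical heuristic, not the ",
      "published ROBIS judgement; set acknowledge_heuristic = TRUE to use it",
      call. = FALSE
    )
  }
  schema <- build_schema("ROBIS")
  assessments |>
    dplyr::filter(.data$instrument == "ROBIS") |>
    dplyr::mutate(response = parse_response(.data$response)) |>
    dplyr::left_join(schema[c("item_id", "domain")], by = "item_id") |>
    dplyr::group_by(.data$review_id, .data$domain) |>
    dplyr::summarise(
      concern = dplyr::case_when(
        all(.data$response %in% c("Y", "PY")) ~ "LOW",
        any(.data$response %in% c("N", "PN")) ~ "HIGH",
        TRUE ~ "UNCLEAR"
      ),
      .groups = "drop"
    )
}
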