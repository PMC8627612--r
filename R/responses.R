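#' Response codes used by AMSTAR-2 and ROBIS
#'
#' Both instruments record item-level judgements as short tokens. AMSTAR-2
#' uses `Y` and `N` everywhere, adds `PY` ("partially yes") on items 2, 4, 7,
#' 8 and 9, and uses the `NA` token on the meta-analysis-conditional items
#' (11, 12, 15) of reviews without a meta-analysis. ROBIS uses the five-point
#' alphabet `Y`, `PY`, `PN`, `N`, `NI` on all 21 items.
#'
#' @format A character vector of the six canonical tokens.
#' @export
response_codes <- c("Y", "PY", "PN", "N", "NI", "NA")

# canonical spellings accepted on input; keys are upper-cased, trimmed forms
.response_synonyms <- c(
  "Y" = "Y", "YES" = "Y",
  "PY" = "PY", "PARTIAL YES" = "PY", "PARTIALLY YES" = "PY",
  "PN" = "PN", "PARTIAL NO" = "PN", "PARTIALLY NO" = "PN",
  "N" = "N", "NO" = "N",
  "NI" = "NI", "NO INFORMATION" = "NI",
  "NA" = "NA", "NOT APPLICABLE" = "NA"
)

#' Canonicalize response tokens
#'
#' Maps free-form response spellings onto the canonical short tokens of
#' [response_codes]: matching is case-insensitive and accepts the common
#' long forms ("Yes", "Partially yes", "No information", "Not applicable").
#' An empty string or a missing value is read as the `NA` token
#' ("not applicable"). Unrecognized strings are returned unchanged so that
#' [validate_assessment()] can report them verbatim.
#'
#' @param x Character vector of raw responses.
#' @return Character vector of the same length with canonical tokens where
#'   recognized.
#' @examples
#' parse_response(c("yes", "Partially Yes", "no information", "", "weird"))
#' @export
parse_response <- function(x) {
  nms <- names(x)
  x <- as.character(x)
  key <- toupper(trimws(x))
  key[is.na(key) | key == ""] <- "NA"
  hit <- unname(.response_synonyms[key])
  out <- ifelse(is.na(hit), x, hit)
  names(out) <- nms
  out
}
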