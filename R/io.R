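#' Read and write assessment tables
#'
#' The on-disk interchange format is a pair of UTF-8 CSV files: a long
#' assessment table with columns `review_id`, `instrument` (`AMSTAR2` or
#' `ROBIS`), `item_id`, `stratum` (empty, `RCT` or `NRSI`) and `response`,
#' and a metadata table with columns `review_id`, `has_ma` (`true`/`false`)
#' and `design_mix` (`RCT_ONLY`, `NRSI_ONLY`, `BOTH`). Responses are
#' canonicalized with [parse_response()] on read.
#'
#' @param path File path.
#' @return `read_assessments()`: the long assessment tibble.
#'   `read_metadata()`: the metadata tibble with `has_ma` as logical.
#' @export
read_assessments <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("review_id", "instrument", "item_id", "response")
  if (!all(need %in% names(df))) {
    stop("assessment file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"stratum" %in% names(df)) df$stratum <- NA_character_
  df |>
    dplyr::mutate(
      instrument = toupper(.data$instrument),
      stratum = dplyr::na_if(toupper(trimws(dplyr::coalesce(.data$stratum, ""))), ""),
      response = parse_response(.data$response)
    ) |>
    dplyr::select("review_id", "instrument", "item_id", "stratum", "response")
}

#' @rdname read_assessments
#' @export
read_metadata <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("review_id", "has_ma", "design_mix")
  if (!all(need %in% names(df))) {
    stop("metadata file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df |>
    dplyr::mutate(
      has_ma = toupper(trimws(.data$has_ma)) %in% c("TRUE", "T", "YES", "1"),
      design_mix = toupper(trimws(.data$design_mix))
    ) |>
    dplyr::select("review_id", "has_ma", "design_mix")
}

#' @rdname read_assessments
#' @param assessments,metadata Tibbles as returned by the readers or by
#'   [simulate_cohort()].
#' @export
write_assessments <- function(assessments, path) {
  readr::write_csv(assessments, path, na = "")
  invisible(path)
}

#' @rdname read_assessments
#' @export
write_metadata <- function(metadata, path) {
  out <- dplyr::mutate(metadata, has_ma = tolower(as.character(.data$has_ma)))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes the assessment CSV, the metadata CSV and (when truth is retained)
#' the latent-truth table `truth.csv` (`review_id`, `construct_id`,
#' `latent`) into a directory.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    assessments = file.path(dir, "assessments.csv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_assessments(cohort$assessments, paths["assessments"])
  write_metadata(cohort$metadata, paths["metadata"])
  readr::write_csv(cohort$truth$states, paths["truth"])
  paths
}

#' JSON interchange for paired assessments
#'
#' One JSON object per review, carrying the metadata and both instruments'
#' responses; design-stratified AMSTAR-2 items appear as
#' `{"RCT": ..., "NRSI": ...}` objects.
#'
#' @param assessments,metadata Long assessments and metadata tibbles.
#' @param path Output (or input) file path.
#' @return `write_assessments_json()` returns `path` invisibly;
#'   `read_assessments_json()` returns a list with elements `assessments`
#'   and `metadata`.
#' @export
write_assessments_json <- function(assessments, metadata, path) {
  a <- as_tibble(assessments)
  if (!"stratum" %in% names(a)) a$stratum <- NA_character_
  reviews <- purrr::pmap(as_tibble(metadata), function(review_id, has_ma, design_mix) {
    sub <- a[a$review_id == review_id, ]
    pack <- function(instr) {
      rows <- sub[sub$instrument == instr, ]
      out <- list()
      for (item in unique(rows$item_id)) {
        r <- rows[rows$item_id == item, ]
        out[[item]] <- if (nrow(r) == 1L && is.na(r$stratum[1])) {
          r$response[1]
        } else {
          as.list(setNames(r$response, r$stratum))
        }
      }
      out
    }
    list(
      review_id = review_id, has_ma = has_ma, design_mix = design_mix,
      amstar = pack("AMSTAR2"), robis = pack("ROBIS")
    )
  })
  jsonlite::write_json(reviews, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_assessments_json
#' @export
read_assessments_json <- function(path) {
  reviews <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- purrr::map_dfr(reviews, function(rv) {
    unpack <- function(instr_list, instr) {
      purrr::imap_dfr(instr_list, function(resp, item) {
        if (is.list(resp)) {
          tibble(instrument = instr, item_id = item,
                 stratum = names(resp),
                 response = unlist(resp, use.names = FALSE))
        } else {
          tibble(instrument = instr, item_id = item,
                 stratum = NA_character_, response = resp)
        }
      })
    }
    dplyr::bind_rows(unpack(rv$amstar, "AMSTAR2"), unpack(rv$robis, "ROBIS")) |>
      dplyr::mutate(review_id = rv$review_id, .before = 1)
  })
  meta <- purrr::map_dfr(reviews, function(rv) {
    tibble(review_id = rv$review_id, has_ma = isTRUE(rv$has_ma),
           design_mix = rv$design_mix)
  })
  list(
    assessments = dplyr::mutate(rows, response = parse_response(.data$response)),
    metadata = meta
  )
}

#' Write and re-read a reliability report
#'
#' CSV or JSON is chosen by the file extension (`.csv`/`.json`). JSON
#' reports round-trip: [read_report()] restores the numeric columns exactly
#' as stored.
#'
#' @param report An `agreement_report` from [run_reliability()].
#' @param path Output path ending in `.csv` or `.json`.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   report tibble.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as_tibble(report)
  if (ext == "csv") {
    readr::write_csv(df, path, na = "")
  } else if (ext == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    stop("unsupported report format: .", ext, " (use .csv or .json)",
         call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    as_tibble(jsonlite::fromJSON(path))
  } else if (ext == "csv") {
    readr::read_csv(path, col_types = readr::cols())
  } else {
    stop("unsupported report format: .", ext, call. = FALSE)
  }
}
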