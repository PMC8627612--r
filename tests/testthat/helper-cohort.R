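# Builders for small hand-crafted cohorts.
#
# make_assessment() produces one review with every item "Y" (conditional
# AMSTAR-2 items "NA" when has_ma = FALSE; stratified items split into
# RCT/NRSI rows when design_mix = "BOTH"), then applies the overrides given
# in `amstar` / `robis` as named lists: amstar = list(`2` = "N") or, for a
# stratified item of a mixed-design review, list(`9` = c(RCT = "Y", NRSI = "N")).

make_assessment <- function(review_id = "R1", has_ma = TRUE,
                            design_mix = "RCT_ONLY",
                            amstar = list(), robis = list()) {
  am_ids <- as.character(1:16)
  conditional <- c("11", "12", "15")
  stratified <- c("9", "11")
  rows <- list()
  for (id in am_ids) {
    default <- if (id %in% conditional && !has_ma) "NA" else "Y"
    value <- if (!is.null(amstar[[id]])) amstar[[id]] else default
    if (id %in% stratified && design_mix == "BOTH" &&
        !(id %in% conditional && !has_ma)) {
      if (length(value) == 1L) value <- c(RCT = unname(value), NRSI = unname(value))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        review_id = review_id, instrument = "AMSTAR2", item_id = id,
        stratum = names(value), response = unname(value)
      )
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        review_id = review_id, instrument = "AMSTAR2", item_id = id,
        stratum = NA_character_, response = unname(value[1])
      )
    }
  }
  ro_ids <- names(srconcord:::.robis_labels)
  for (id in ro_ids) {
    value <- if (!is.null(robis[[id]])) robis[[id]] else "Y"
    rows[[length(rows) + 1L]] <- tibble::tibble(
      review_id = review_id, instrument = "ROBIS", item_id = id,
      stratum = NA_character_, response = value
    )
  }
  list(
    assessments = dplyr::bind_rows(rows),
    metadata = tibble::tibble(review_id = review_id, has_ma = has_ma,
                              design_mix = design_mix)
  )
}

bind_cohort <- function(...) {
  parts <- list(...)
  list(
    assessments = dplyr::bind_rows(lapply(parts, `[[`, "assessments")),
    metadata = dplyr::bind_rows(lapply(parts, `[[`, "metadata"))
  )
}

# Independent brute-force oracle for the weighted agreement coefficient:
# plain loops over pairs and categories, no shared code with the package.
oracle_gwet <- function(a, b, categories, W = NULL) {
  q <- length(categories)
  if (is.null(W)) W <- diag(q)
  n <- length(a)
  ai <- match(a, categories)
  bi <- match(b, categories)
  pa <- 0
  for (i in seq_len(n)) pa <- pa + W[ai[i], bi[i]]
  pa <- pa / n
  pik <- numeric(q)
  for (k in seq_len(q)) {
    for (i in seq_len(n)) {
      pik[k] <- pik[k] + (ai[i] == k) + (bi[i] == k)
    }
  }
  pik <- pik / (2 * n)
  Tw <- sum(W)
  pe <- Tw / (q * (q - 1)) * sum(pik * (1 - pik))
  list(pa = pa, pe = pe, ac = (pa - pe) / (1 - pe))
}
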