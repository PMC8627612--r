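.design_levels <- c("RCT_ONLY", "NRSI_ONLY", "BOTH")

# constructs = connected components of instrument items linked by the
# comparison table (ROBIS 4.4 serves two comparisons, which fuses the
# item-11 and item-14 comparisons into one latent construct); every
# unmatched item forms its own construct
.construct_map <- function(table = comparison_table()) {
  comp_items <- purrr::pmap(table, function(comparison_id, amstar_items,
                                            robis_items, ...) {
    c(paste0("A", amstar_items), paste0("R", robis_items))
  })
  # union comparisons sharing any item
  group <- seq_along(comp_items)
  repeat {
    changed <- FALSE
    for (i in seq_along(comp_items)) {
      for (j in seq_along(comp_items)) {
        if (group[i] != group[j] &&
            length(intersect(comp_items[[i]], comp_items[[j]])) > 0) {
          group[group == group[j]] <- group[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp_construct <- paste0("g", match(group, unique(group)))
  matched <- purrr::map2_dfr(comp_items, comp_construct, function(items, cid) {
    tibble(
      instrument = ifelse(substr(items, 1, 1) == "A", "AMSTAR2", "ROBIS"),
      item_id = substring(items, 2),
      construct_id = cid
    )
  }) |> dplyr::distinct()
  un <- unmatched_items(table)
  singles <- dplyr::bind_rows(
    tibble(instrument = "AMSTAR2", item_id = un$amstar,
           construct_id = paste0("uA", un$amstar)),
    tibble(instrument = "ROBIS", item_id = un$robis,
           construct_id = paste0("uR", un$robis))
  )
  dplyr::bind_rows(matched, singles)
}

.check_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(nm, " must be a probability in [0, 1]", call. = FALSE)
  }
}

#' Simulate a cohort of paired AMSTAR-2/ROBIS assessments
#'
#' Generates synthetic paired assessments from a single-factor latent-quality
#' model. Each review draws a latent quality `u ~ Beta(quality_alpha,
#' quality_beta)` (the defaults are strongly left-skewed, emulating cohorts
#' in which high-quality reviews are rare), a meta-analysis indicator and a
#' study-design composition. Each methodological construct - one per matched
#' comparison group, one per unmatched item - is latently "met" with
#' probability `u`, with a "partially met" state carved out of the met mass
#' with probability `py_prob`. Both instruments' items observe their
#' construct's latent state: with probability `concordance` the response is
#' the deterministic emission of the latent state (met gives `Y`; partially
#' met gives `PY` where the item admits it, else `Y`; unmet gives `N` on
#' AMSTAR-2 and `PN`/`N`/`NI` with probabilities 0.3/0.5/0.2 on ROBIS), and
#' otherwise it is redrawn from the item's response alphabet (uniformly, or
#' by an adjacent-category error when `noise = "adjacent"`). Meta-analysis-
#' conditional AMSTAR-2 items are set to `NA` for reviews without a
#' meta-analysis; design-stratified items are drawn once per stratum for
#' mixed-design reviews.
#'
#' A single RNG stream is used with a fixed draw order (quality, then
#' meta-analysis indicators, then design mixes, then latent states, then
#' ROBIS unmet emissions, then noise flips and redraws, all in deterministic
#' row order), so a given `seed` reproduces the cohort exactly.
#'
#' @param n_reviews Number of reviews (default 101, the size of the
#'   motivating survey's sample).
#' @param quality_alpha,quality_beta Beta shape parameters of the latent
#'   quality distribution (defaults 1.2 and 6.0).
#' @param concordance Probability that an item response follows the latent
#'   truth rather than being redrawn; 1 gives perfectly concordant
#'   instruments. Default 0.9.
#' @param p_ma Probability that a review includes a meta-analysis (default 0.8).
#' @param design_mix_probs Probabilities of `RCT_ONLY`, `NRSI_ONLY`, `BOTH`
#'   (default 0.15, 0.55, 0.30).
#' @param py_prob Probability that a met construct is only partially met
#'   (default 0.25).
#' @param noise `"uniform"` (default) redraws discordant responses uniformly
#'   from the item alphabet; `"adjacent"` moves one step on the item's
#'   ordered scale instead.
#' @param seed Optional integer seed; the global RNG state is left untouched.
#' @return An object of class `synthetic_cohort`: a list with `assessments`
#'   (long tibble), `metadata`, `truth` (list with `quality` and per-construct
#'   `states`) and `config`.
#' @examples
#' cohort <- simulate_cohort(n_reviews = 8, seed = 1)
#' cohort$metadata
#' @export
simulate_cohort <- function(n_reviews = 101, quality_alpha = 1.2,
                            quality_beta = 6, concordance = 0.9, p_ma = 0.8,
                            design_mix_probs = c(RCT_ONLY = 0.15,
                                                 NRSI_ONLY = 0.55,
                                                 BOTH = 0.30),
                            py_prob = 0.25, noise = c("uniform", "adjacent"),
                            seed = NULL) {
  noise <- match.arg(noise)
  if (!is.numeric(n_reviews) || length(n_reviews) != 1L || is.na(n_reviews) ||
      n_reviews < 1 || n_reviews != round(n_reviews)) {
    stop("n_reviews must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(quality_alpha) || quality_alpha <= 0 ||
      !is.numeric(quality_beta) || quality_beta <= 0) {
    stop("quality_alpha and quality_beta must be positive", call. = FALSE)
  }
  .check_prob(concordance, "concordance")
  .check_prob(p_ma, "p_ma")
  .check_prob(py_prob, "py_prob")
  if (length(design_mix_probs) != 3L || any(design_mix_probs < 0) ||
      abs(sum(design_mix_probs) - 1) > 1e-8) {
    stop("design_mix_probs must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  config <- list(
    n_reviews = as.integer(n_reviews), quality_alpha = quality_alpha,
    quality_beta = quality_beta, concordance = concordance, p_ma = p_ma,
    design_mix_probs = unname(design_mix_probs), py_prob = py_prob,
    noise = noise, seed = seed
  )
  gen <- function() .simulate_cohort_impl(config)
  cohort <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  cohort$config <- config
  class(cohort) <- "synthetic_cohort"
  cohort
}

.simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_reviews
  id_width <- max(4L, nchar(as.character(n)))
  reviews <- tibble(
    review_id = sprintf("SR%0*d", id_width, seq_len(n)),
    quality = rbeta(n, cfg$quality_alpha, cfg$quality_beta)
  )
  reviews$has_ma <- runif(n) < cfg$p_ma
  reviews$design_mix <- .design_levels[
    1L + findInterval(runif(n), cumsum(cfg$design_mix_probs)[1:2])
  ]

  cmap <- .construct_map()
  constructs <- sort(unique(cmap$construct_id))
  latents <- tidyr::crossing(
    reviews[c("review_id", "quality")],
    construct_id = constructs
  ) |> dplyr::arrange(.data$review_id, .data$construct_id)
  met <- runif(nrow(latents)) < latents$quality
  part <- runif(nrow(latents)) < cfg$py_prob
  latents$latent <- dplyr::case_when(
    met & part ~ "partial",
    met ~ "met",
    TRUE ~ "unmet"
  )

  schema <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(build_schema("AMSTAR2")), instrument = "AMSTAR2"),
    dplyr::mutate(as_tibble(build_schema("ROBIS")), instrument = "ROBIS")
  )
  items <- schema[c("instrument", "item_id", "ma_conditional", "allows_py",
                    "stratified_by_design")] |>
    dplyr::left_join(cmap, by = c("instrument", "item_id"))

  obs <- tidyr::crossing(
    reviews[c("review_id", "has_ma", "design_mix")],
    items
  ) |>
    dplyr::mutate(
      not_assessed = .data$instrument == "AMSTAR2" & .data$ma_conditional & !.data$has_ma,
      split = .data$instrument == "AMSTAR2" & .data$stratified_by_design &
        .data$design_mix == "BOTH" & !.data$not_assessed
    )
  obs <- dplyr::bind_rows(
    obs |> dplyr::filter(!.data$split) |> dplyr::mutate(stratum = NA_character_),
    obs |> dplyr::filter(.data$split) |> dplyr::mutate(stratum = "RCT"),
    obs |> dplyr::filter(.data$split) |> dplyr::mutate(stratum = "NRSI")
  ) |>
    dplyr::arrange(.data$review_id, .data$instrument, .data$item_id, .data$stratum) |>
    dplyr::left_join(latents[c("review_id", "construct_id", "latent")],
                     by = c("review_id", "construct_id"))

  nr <- nrow(obs)
  robis <- obs$instrument == "ROBIS"
  # deterministic emission of the latent state
  unmet_draw <- runif(nr)  # consumed only by ROBIS unmet rows
  robis_unmet <- c("PN", "N", "NI")[1L + findInterval(unmet_draw, c(0.3, 0.8))]
  emitted <- dplyr::case_when(
    obs$not_assessed ~ "NA",
    obs$latent == "met" ~ "Y",
    obs$latent == "partial" & obs$allows_py ~ "PY",
    obs$latent == "partial" ~ "Y",
    robis ~ robis_unmet,
    TRUE ~ "N"
  )
  # discordance: keep the emission with probability `concordance`, else redraw
  flip <- runif(nr) >= cfg$concordance & !obs$not_assessed
  redraw_u <- runif(nr)
  if (cfg$noise == "uniform") {
    alen <- ifelse(robis, 5L, ifelse(obs$allows_py, 3L, 2L))
    pick <- pmin(alen, 1L + floor(redraw_u * alen))
    redrawn <- dplyr::case_when(
      robis ~ c("Y", "PY", "PN", "N", "NI")[pick],
      obs$allows_py ~ c("Y", "PY", "N")[pick],
      TRUE ~ c("Y", "N")[pick]
    )
  } else {
    # adjacent-category error on the item's ordered scale, forced inward at
    # the ends
    scale_r <- c("N", "PN", "NI", "PY", "Y")
    scale_a3 <- c("N", "PY", "Y")
    scale_a2 <- c("N", "Y")
    step_on <- function(scale, resp, u) {
      pos <- match(resp, scale)
      dir <- ifelse(u < 0.5, -1L, 1L)
      dir[pos == 1L] <- 1L
      dir[pos == length(scale)] <- -1L
      scale[pos + dir]
    }
    redrawn <- emitted
    i5 <- robis & flip
    i3 <- !robis & obs$allows_py & flip
    i2 <- !robis & !obs$allows_py & flip
    redrawn[i5] <- step_on(scale_r, emitted[i5], redraw_u[i5])
    redrawn[i3] <- step_on(scale_a3, emitted[i3], redraw_u[i3])
    redrawn[i2] <- step_on(scale_a2, emitted[i2], redraw_u[i2])
  }
  obs$response <- ifelse(flip, redrawn, emitted)

  list(
    assessments = obs[c("review_id", "instrument", "item_id", "stratum", "response")],
    metadata = reviews[c("review_id", "has_ma", "design_mix")],
    truth = list(
      quality = reviews[c("review_id", "quality")],
      states = latents[c("review_id", "construct_id", "latent")]
    )
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic paired-assessment cohort: ", nrow(x$metadata), " reviews (",
      sum(x$metadata$has_ma), " with meta-analysis), concordance = ",
      x$config$concordance, "\n", sep = "")
  invisible(x)
}

#' Prevalence calibration of the synthetic-cohort generator
#'
#' Simulates a large cohort under the given configuration and reports the
#' prevalence of each AMSTAR-2 overall rating and the share of reviews with
#' an all-positive ROBIS profile (every item `Y`/`PY`, the mechanical
#' analogue of a low risk-of-bias profile). Under the default configuration
#' high-confidence AMSTAR-2 ratings are rare (a few percent at most),
#' matching the strongly left-skewed quality observed in applied cohorts.
#'
#' @param n_reviews Cohort size for the calibration run (default 10000).
#' @param ... Passed to [simulate_cohort()].
#' @param seed Optional integer seed.
#' @return One-row tibble with columns `n_reviews`, `share_high`,
#'   `share_moderate`, `share_low`, `share_critically_low`,
#'   `share_robis_all_positive`.
#' @examples
#' calibrate_prevalence(n_reviews = 500, seed = 3)
#' @export
calibrate_prevalence <- function(n_reviews = 10000, ..., seed = NULL) {
  cohort <- simulate_cohort(n_reviews = n_reviews, ..., seed = seed)
  ratings <- amstar2_overall(cohort$assessments, cohort$metadata, validate = FALSE)
  shares <- prop.table(table(factor(ratings$rating, levels = .amstar2_rating_levels)))
  robis_pos <- cohort$assessments |>
    dplyr::filter(.data$instrument == "ROBIS") |>
    dplyr::group_by(.data$review_id) |>
    dplyr::summarise(all_pos = all(.data$response %in% c("Y", "PY")), .groups = "drop")
  tibble(
    n_reviews = as.integer(n_reviews),
    share_high = unname(shares["HIGH"]),
    share_moderate = unname(shares["MODERATE"]),
    share_low = unname(shares["LOW"]),
    share_critically_low = unname(shares["CRITICALLY_LOW"]),
    share_robis_all_positive = mean(robis_pos$all_pos)
  )
}
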