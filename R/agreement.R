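#' Quadratic agreement weights
#'
#' Agreement weight matrix for `q` ordered categories with
#' `w[k, l] = 1 - (k - l)^2 / (q - 1)^2`: full credit on the diagonal,
#' partial credit for near-misses, none between the extreme categories. For
#' `q = 2` this reduces to identity weights.
#'
#' @param q Number of ordered categories (at least 2).
#' @return A symmetric `q x q` matrix with unit diagonal.
#' @examples
#' quadratic_weights(3)
#' @export
quadratic_weights <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || q < 2 || q != round(q)) {
    stop("q must be an integer >= 2", call. = FALSE)
  }
  k <- seq_len(q)
  1 - outer(k, k, function(a, b) (a - b)^2) / (q - 1)^2
}

#' Identity (unweighted) agreement weights
#'
#' @inheritParams quadratic_weights
#' @return The `q x q` identity matrix.
#' @export
identity_weights <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || q < 2 || q != round(q)) {
    stop("q must be an integer >= 2", call. = FALSE)
  }
  diag(q)
}

.band_labels <- c("POOR", "SLIGHT", "FAIR", "MODERATE", "SUBSTANTIAL", "ALMOST_PERFECT")

#' Agreement band thresholds
#'
#' The qualitative bands used to label chance-corrected agreement
#' coefficients, on half-open intervals `(lo, hi]`: poor (<= 0), slight
#' (0, 0.20], fair (0.20, 0.40], moderate (0.40, 0.60], substantial
#' (0.60, 0.80] and almost perfect (0.80, 1].
#'
#' @return Tibble with columns `band`, `lo`, `hi`.
#' @export
agreement_bands <- function() {
  tibble(
    band = .band_labels,
    lo = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8),
    hi = c(0, 0.2, 0.4, 0.6, 0.8, 1)
  )
}

#' Classify a coefficient into an agreement band
#'
#' @param estimate Numeric vector of agreement coefficients (each at most 1).
#' @return Character vector of band labels (see [agreement_bands()]).
#' @examples
#' classify_band(c(0.87, 0.6, 0.18, 0))
#' @export
classify_band <- function(estimate) {
  if (any(is.na(estimate))) stop("estimate contains NA", call. = FALSE)
  if (any(estimate > 1 + 1e-9)) stop("agreement coefficients cannot exceed 1", call. = FALSE)
  estimate <- pmin(estimate, 1)
  as.character(cut(
    estimate,
    breaks = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, 1),
    labels = .band_labels,
    right = TRUE
  ))
}

# integer-coded core: a, b in 1..q; returns list of sufficient statistics
# plus leave-one-out coefficients (NULL unless jackknife = TRUE)
.gwet_core <- function(a, b, q, W, jackknife = FALSE) {
  n <- length(a)
  f <- sum(W) / (q * (q - 1))
  wab <- W[cbind(a, b)]
  Sw <- sum(wab)
  pa <- Sw / n
  Ck <- tabulate(a, q) + tabulate(b, q)
  pik <- Ck / (2 * n)
  pe <- f * sum(pik * (1 - pik))
  if (pe >= 1 - 1e-12) {
    stop("chance agreement pe = 1: coefficient undefined (pa = ",
         format(pa), ", category propensities ",
         paste(format(pik), collapse = ", "), ")", call. = FALSE)
  }
  ac <- (pa - pe) / (1 - pe)
  out <- list(pa = pa, pe = pe, ac = ac, n = n, q = q)
  if (jackknife) {
    idx <- seq_len(n)
    Da <- matrix(0, n, q); Da[cbind(idx, a)] <- 1
    Db <- matrix(0, n, q); Db[cbind(idx, b)] <- 1
    P <- (matrix(Ck, n, q, byrow = TRUE) - (Da + Db)) / (2 * (n - 1))
    pa_i <- (Sw - wab) / (n - 1)
    pe_i <- f * rowSums(P * (1 - P))
    degen <- pe_i >= 1 - 1e-12
    if (any(degen)) {
      stop("degenerate leave-one-out subset(s) at index: ",
           paste(which(degen), collapse = ", "), call. = FALSE)
    }
    ac_i <- (pa_i - pe_i) / (1 - pe_i)
    out$ac_loo <- ac_i
    out$se <- sqrt((n - 1) / n * sum((ac_i - mean(ac_i))^2))
  }
  out
}

.resolve_pairs <- function(pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs)
  pairs <- as_tibble(pairs)
  cols <- if (all(c("amstar_cat", "robis_cat") %in% names(pairs))) {
    c("amstar_cat", "robis_cat")
  } else {
    names(pairs)[1:2]
  }
  a <- as.character(pairs[[cols[1]]])
  b <- as.character(pairs[[cols[2]]])
  if (anyNA(a) || anyNA(b)) {
    stop("pairs contain missing ratings; filter non-applicable reviews first",
         call. = FALSE)
  }
  list(a = a, b = b)
}

#' Gwet's chance-corrected agreement coefficient
#'
#' Computes Gwet's agreement coefficient between two raters (here, the two
#' harmonized instruments) over `n` rated subjects. With category propensities
#' `pi_k = (1/2n) sum_i [1(a_i = k) + 1(b_i = k)]`, observed weighted
#' agreement `pa = (1/n) sum_i w[a_i, b_i]` and chance agreement
#' `pe = (T_w / (q (q - 1))) sum_k pi_k (1 - pi_k)` (`T_w` the sum of all
#' weights), the coefficient is `AC = (pa - pe) / (1 - pe)`. Identity weights
#' give the unweighted first-order coefficient AC1; a weight matrix such as
#' [quadratic_weights()] gives the weighted generalization AC2.
#'
#' The standard error is the delete-one jackknife estimate and the
#' confidence interval is Wald-normal, `AC +/- z * se`, with the upper bound
#' truncated at 1 (the lower bound is not truncated).
#'
#' @param pairs Two-column data frame, matrix or tibble of paired ratings;
#'   columns `amstar_cat`/`robis_cat` are used when present, otherwise the
#'   first two columns.
#' @param categories Character vector fixing the category set and (for
#'   weighted coefficients) its order. Defaults to the sorted distinct
#'   observed ratings; pass the full design scale explicitly when a category
#'   may be unobserved.
#' @param weights `NULL` for identity weights, the string `"quadratic"`, or
#'   a `q x q` symmetric weight matrix with unit diagonal.
#' @param conf_level Confidence level, default 0.95.
#' @param ci Compute the jackknife standard error and interval? Requires at
#'   least 3 pairs. Default `TRUE`.
#' @return An object of class `gwet_agreement`: a list with elements
#'   `estimate`, `pa`, `pe`, `se`, `ci_low`, `ci_high`, `conf_level`, `n`,
#'   `q`, `categories`, `weighting`, `band`.
#' @examples
#' pairs <- data.frame(
#'   a = c("POS", "POS", "POS", "NEG"),
#'   b = c("POS", "POS", "NEG", "NEG")
#' )
#' gwet_ac(pairs)
#' @export
gwet_ac <- function(pairs, categories = NULL, weights = NULL,
                    conf_level = 0.95, ci = TRUE) {
  p <- .resolve_pairs(pairs)
  if (length(p$a) < 2L) {
    stop("insufficient data: at least 2 pairs are required", call. = FALSE)
  }
  if (is.null(categories)) categories <- sort(unique(c(p$a, p$b)))
  if (!all(c(p$a, p$b) %in% categories)) {
    stop("ratings outside the category set: ",
         paste(setdiff(unique(c(p$a, p$b)), categories), collapse = ", "),
         call. = FALSE)
  }
  q <- length(categories)
  if (q < 2L) stop("at least 2 categories are required", call. = FALSE)
  if (is.null(weights)) {
    W <- identity_weights(q); weighting <- "IDENTITY"
  } else if (identical(weights, "quadratic")) {
    W <- quadratic_weights(q); weighting <- "QUADRATIC"
  } else {
    W <- as.matrix(weights); weighting <- "CUSTOM"
    if (!isTRUE(all.equal(dim(W), c(q, q))) || !isTRUE(all.equal(W, t(W))) ||
        !isTRUE(all.equal(unname(diag(W)), rep(1, q))) || any(W < 0 | W > 1)) {
      stop("weights must be a symmetric q x q matrix with unit diagonal in [0, 1]",
           call. = FALSE)
    }
    if (isTRUE(all.equal(unname(W), unname(identity_weights(q))))) weighting <- "IDENTITY"
    else if (isTRUE(all.equal(unname(W), unname(quadratic_weights(q))))) weighting <- "QUADRATIC"
  }
  a <- match(p$a, categories)
  b <- match(p$b, categories)
  do_jack <- isTRUE(ci) && length(a) >= 3L
  core <- .gwet_core(a, b, q, W, jackknife = do_jack)
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- list(
    estimate = core$ac,
    pa = core$pa,
    pe = core$pe,
    se = if (do_jack) core$se else NA_real_,
    ci_low = if (do_jack) core$ac - z * core$se else NA_real_,
    ci_high = if (do_jack) min(1, core$ac + z * core$se) else NA_real_,
    conf_level = conf_level,
    n = core$n,
    q = q,
    categories = categories,
    weighting = weighting,
    band = classify_band(core$ac)
  )
  class(out) <- "gwet_agreement"
  out
}

#' Jackknife standard error and confidence interval for Gwet's coefficient
#'
#' Delete-one jackknife: with leave-one-pair-out coefficients `AC_(-i)`,
#' `se = sqrt(((n - 1)/n) * sum_i (AC_(-i) - mean)^2)` and the interval is
#' `AC +/- z_(1 - alpha/2) * se`, upper bound truncated at 1.
#'
#' @inheritParams gwet_ac
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return Named list with `se`, `ci_low`, `ci_high`.
#' @export
jackknife_ci <- function(pairs, categories = NULL, weights = NULL, alpha = 0.05) {
  p <- .resolve_pairs(pairs)
  if (length(p$a) < 3L) {
    stop("jackknife requires at least 3 pairs", call. = FALSE)
  }
  res <- gwet_ac(pairs, categories = categories, weights = weights,
                 conf_level = 1 - alpha, ci = TRUE)
  list(se = res$se, ci_low = res$ci_low, ci_high = res$ci_high)
}

#' @export
print.gwet_agreement <- function(x, digits = 2, ...) {
  cat("Gwet's agreement coefficient (",
      if (x$weighting == "IDENTITY") "AC1, unweighted"
      else paste0("AC2, ", tolower(x$weighting), " weights"),
      ")\n", sep = "")
  cat("  n = ", x$n, " pairs, q = ", x$q, " categories (",
      paste(x$categories, collapse = " < "), ")\n", sep = "")
  cat("  pa = ", format(round_half_up(x$pa, 4)), ", pe = ",
      format(round_half_up(x$pe, 4)), "\n", sep = "")
  cat("  AC = ", format(round_half_up(x$estimate, digits)), sep = "")
  if (!is.na(x$se)) {
    cat(" (", 100 * x$conf_level, "% CI ",
        format(round_half_up(x$ci_low, digits)), " to ",
        format(round_half_up(x$ci_high, digits)), ")", sep = "")
  }
  cat("  [", x$band, "]\n", sep = "")
  invisible(x)
}

#' @rdname gwet_ac
#' @param x A `gwet_agreement` object.
#' @param ... Unused.
#' @export
tidy.gwet_agreement <- function(x, ...) {
  tibble(
    estimate = x$estimate,
    std.error = x$se,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    band = x$band
  )
}

#' @rdname gwet_ac
#' @export
glance.gwet_agreement <- function(x, ...) {
  tibble(
    estimate = x$estimate, pa = x$pa, pe = x$pe, se = x$se,
    n = x$n, q = x$q, weighting = x$weighting,
    conf_level = x$conf_level, band = x$band
  )
}

#' Round half away from zero
#'
#' Reporting convention for coefficients and interval bounds: ties round
#' away from zero (0.005 -> 0.01), unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
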