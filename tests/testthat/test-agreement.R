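test_that("quadratic weights follow the closed form", {
  expect_equal(quadratic_weights(2), diag(2))
  w3 <- quadratic_weights(3)
  expect_equal(w3[1, 2], 0.75)
  expect_equal(w3[2, 3], 0.75)
  expect_equal(w3[1, 3], 0)
  expect_equal(diag(w3), rep(1, 3))
  expect_equal(w3, t(w3))
  expect_error(quadratic_weights(1), "q must be")
})

test_that("the four-pair worked example reproduces the closed-form AC1", {
  pairs <- data.frame(a = c("P", "P", "P", "N"), b = c("P", "P", "N", "N"))
  res <- gwet_ac(pairs, categories = c("N", "P"))
  expect_equal(res$pa, 0.75)
  # pe = sum_k pi_k (1 - pi_k) with pi = (0.625, 0.375)
  expect_equal(res$pe, 0.46875)
  expect_equal(res$estimate, 0.28125 / 0.53125)
  # jackknife leave-one-out coefficients are {1/3, 1/3, 1, 7/13}
  expect_equal(res$se, 0.4715788, tolerance = 1e-6)
  expect_lt(res$ci_low, res$estimate)
  expect_gt(res$ci_high, res$estimate)
})

test_that("AC1 agrees exactly with brute force on all 2^8 binary configurations", {
  configs <- expand.grid(rep(list(c("NEG", "POS")), 8), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(configs))) {
    a <- unlist(configs[i, 1:4], use.names = FALSE)
    b <- unlist(configs[i, 5:8], use.names = FALSE)
    o <- oracle_gwet(a, b, c("NEG", "POS"))
    res <- gwet_ac(data.frame(a, b), categories = c("NEG", "POS"), ci = FALSE)
    expect_equal(res$pa, o$pa)
    expect_equal(res$pe, o$pe)
    expect_equal(res$estimate, o$ac)
  }
})

test_that("weighted AC2 agrees with brute force on random ordinal samples", {
  set.seed(14)
  cats <- c("N", "PY", "Y")
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    a <- sample(cats, n, replace = TRUE)
    b <- sample(cats, n, replace = TRUE)
    o <- oracle_gwet(a, b, cats, quadratic_weights(3))
    res <- gwet_ac(data.frame(a, b), categories = cats, weights = "quadratic",
                   ci = FALSE)
    expect_equal(res$estimate, o$ac)
  }
})

test_that("degenerate and undersized inputs raise structured errors", {
  expect_error(gwet_ac(data.frame(a = "POS", b = "POS")), "at least 2 pairs")
  one_cat <- data.frame(a = rep("POS", 5), b = rep("POS", 5))
  # a single observed category still works when the scale is design-fixed
  res <- gwet_ac(one_cat, categories = c("NEG", "POS"))
  expect_equal(res$estimate, 1)
  expect_error(gwet_ac(one_cat), "at least 2 categories")
  with_na <- data.frame(a = c("POS", NA), b = c("POS", "NEG"))
  expect_error(gwet_ac(with_na), "missing ratings")
})

test_that("the coefficient is symmetric in raters and invariant to pair order", {
  set.seed(99)
  a <- sample(c("NEG", "POS"), 30, replace = TRUE)
  b <- sample(c("NEG", "POS"), 30, replace = TRUE)
  base <- gwet_ac(data.frame(a, b), categories = c("NEG", "POS"))
  swapped <- gwet_ac(data.frame(b, a), categories = c("NEG", "POS"))
  expect_equal(swapped$estimate, base$estimate)
  expect_equal(swapped$se, base$se)
  perm <- sample(30)
  shuffled <- gwet_ac(data.frame(a = a[perm], b = b[perm]),
                      categories = c("NEG", "POS"))
  expect_equal(shuffled$estimate, base$estimate)
  expect_equal(shuffled$se, base$se)
})

test_that("perfect agreement and chance-level agreement hit the fixed points", {
  concordant <- data.frame(a = c("NEG", "POS", "POS", "NEG"),
                           b = c("NEG", "POS", "POS", "NEG"))
  res <- gwet_ac(concordant, categories = c("NEG", "POS"))
  expect_equal(res$estimate, 1)
  expect_equal(res$se, 0)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)
  # three-level all-concordant with quadratic weights
  tri <- data.frame(a = c("N", "PY", "Y", "Y"), b = c("N", "PY", "Y", "Y"))
  expect_equal(
    gwet_ac(tri, categories = c("N", "PY", "Y"), weights = "quadratic")$estimate, 1
  )
  # pa == pe gives exactly zero
  p <- data.frame(a = c("POS", "POS", "NEG", "NEG"),
                  b = c("POS", "NEG", "POS", "NEG"))
  res0 <- gwet_ac(p, categories = c("NEG", "POS"), ci = FALSE)
  expect_equal(res0$pa, res0$pe)
  expect_equal(res0$estimate, 0)
})

test_that("quadratic AC2 dominates AC1 when all disagreements are adjacent", {
  set.seed(7)
  cats <- c("N", "PY", "Y")
  for (rep in 1:20) {
    a <- sample(cats, 25, replace = TRUE)
    shift <- sample(c(0, 1, -1), 25, replace = TRUE, prob = c(0.6, 0.2, 0.2))
    b <- cats[pmin(3, pmax(1, match(a, cats) + shift))]
    ac1 <- gwet_ac(data.frame(a, b), categories = cats, ci = FALSE)$estimate
    ac2 <- gwet_ac(data.frame(a, b), categories = cats, weights = "quadratic",
                   ci = FALSE)$estimate
    expect_gte(ac2, ac1)
  }
})

test_that("jackknife se is close to the bootstrap se on the worked example", {
  pairs <- data.frame(a = c("P", "P", "P", "N"), b = c("P", "P", "N", "N"))
  jack <- jackknife_ci(pairs, categories = c("N", "P"))
  set.seed(2024)
  boot <- replicate(1e4, {
    idx <- sample(4, replace = TRUE)
    gwet_ac(pairs[idx, ], categories = c("N", "P"), ci = FALSE)$estimate
  })
  expect_lt(abs(jack$se - stats::sd(boot)) / stats::sd(boot), 0.25)
})

test_that("band classification uses half-open intervals with POOR at zero", {
  expect_equal(classify_band(0.87), "ALMOST_PERFECT")
  expect_equal(classify_band(0.6), "MODERATE")
  expect_equal(classify_band(0.18), "SLIGHT")
  expect_equal(classify_band(0), "POOR")
  expect_equal(classify_band(-0.5), "POOR")
  # boundaries belong to the lower band
  expect_equal(
    classify_band(c(0.2, 0.4, 0.8, 1, 0.2000001)),
    c("SLIGHT", "FAIR", "SUBSTANTIAL", "ALMOST_PERFECT", "FAIR")
  )
  expect_error(classify_band(1.2), "cannot exceed 1")
  # every value in (-1, 1] receives exactly one label
  grid <- seq(-0.999, 1, by = 0.001)
  expect_false(any(is.na(classify_band(grid))))
})

test_that("tidy and glance return one-row broom-style summaries", {
  pairs <- data.frame(a = c("P", "P", "P", "N"), b = c("P", "P", "N", "N"))
  res <- gwet_ac(pairs, categories = c("N", "P"))
  td <- tidy(res)
  expect_equal(nrow(td), 1L)
  expect_named(td, c("estimate", "std.error", "conf.low", "conf.high", "band"))
  gl <- glance(res)
  expect_equal(gl$n, 4L)
  expect_equal(gl$weighting, "IDENTITY")
})

test_that("reporting rounds half away from zero", {
  expect_equal(round_half_up(c(0.005, -0.005, 0.985), 2), c(0.01, -0.01, 0.99))
  expect_equal(round_half_up(0.444999, 2), 0.44)
})
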