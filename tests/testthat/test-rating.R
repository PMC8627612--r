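rating_of <- function(one, ...) {
  as.character(amstar2_overall(one$assessments, one$metadata, ...)$rating)
}

test_that("the four-way confidence rule reproduces the canonical examples", {
  expect_equal(rating_of(make_assessment()), "HIGH")
  expect_equal(rating_of(make_assessment(amstar = list(`2` = "N"))), "LOW")
  expect_equal(
    rating_of(make_assessment(amstar = list(`2` = "N", `4` = "N"))),
    "CRITICALLY_LOW"
  )
  expect_equal(
    rating_of(make_assessment(amstar = list(`1` = "N", `3` = "N", `5` = "N"))),
    "MODERATE"
  )
  # exactly one non-critical flaw still allows HIGH
  expect_equal(rating_of(make_assessment(amstar = list(`1` = "N"))), "HIGH")
})

test_that("the rule is exhaustively correct over all flaw-count combinations", {
  critical <- c("2", "4", "7", "9", "11", "13", "15")
  noncritical <- setdiff(as.character(1:16), critical)
  parts <- list()
  expected <- character()
  for (cf in 0:7) {
    for (nf in 0:9) {
      id <- sprintf("R_%d_%d", cf, nf)
      flaws <- c(critical[seq_len(cf)], noncritical[seq_len(nf)])
      overrides <- stats::setNames(as.list(rep("N", length(flaws))), flaws)
      parts[[id]] <- make_assessment(id, amstar = overrides)
      expected[id] <-
        if (cf > 1) "CRITICALLY_LOW" else if (cf == 1) "LOW" else if (nf > 1) "MODERATE" else "HIGH"
    }
  }
  cohort <- do.call(bind_cohort, parts)
  res <- amstar2_overall(cohort$assessments, cohort$metadata)
  got <- stats::setNames(as.character(res$rating), res$review_id)
  expect_equal(got[names(expected)], expected)
  # flaw counts are recovered exactly
  cf_nf <- do.call(rbind, strsplit(sub("R_", "", res$review_id), "_"))
  expect_equal(res$critical_flaws, as.integer(cf_nf[, 1]))
  expect_equal(res$noncritical_flaws, as.integer(cf_nf[, 2]))
})

test_that("flipping any single N to Y never worsens the rating", {
  set.seed(31)
  levels_ord <- c("CRITICALLY_LOW", "LOW", "MODERATE", "HIGH")
  for (rep in 1:20) {
    responses <- stats::setNames(
      as.list(sample(c("Y", "N"), 16, replace = TRUE)), as.character(1:16)
    )
    base <- rating_of(make_assessment(amstar = responses))
    for (id in names(responses)) {
      if (responses[[id]] == "N") {
        upgraded <- responses
        upgraded[[id]] <- "Y"
        up <- rating_of(make_assessment(amstar = upgraded))
        expect_gte(match(up, levels_ord), match(base, levels_ord))
      }
    }
  }
})

test_that("excluding NA conditional items is equivalent to scoring them Y", {
  # brute force over all response assignments of 6 of the other items (the
  # rest held at Y): has_ma = FALSE with 11, 12, 15 = NA must match
  # has_ma = TRUE with 11, 12, 15 = Y
  varying <- c("1", "2", "4", "5", "13", "16")
  grid <- expand.grid(rep(list(c("Y", "N")), length(varying)),
                      stringsAsFactors = FALSE)
  names(grid) <- varying
  parts_ma <- list()
  parts_noma <- list()
  for (i in seq_len(nrow(grid))) {
    overrides <- as.list(unlist(grid[i, ]))
    id <- sprintf("G%03d", i)
    parts_ma[[id]] <- make_assessment(paste0(id, "ma"), has_ma = TRUE,
                                      amstar = overrides)
    parts_noma[[id]] <- make_assessment(paste0(id, "no"), has_ma = FALSE,
                                        amstar = overrides)
  }
  with_ma <- do.call(bind_cohort, parts_ma)
  without_ma <- do.call(bind_cohort, parts_noma)
  r1 <- amstar2_overall(with_ma$assessments, with_ma$metadata)
  r2 <- amstar2_overall(without_ma$assessments, without_ma$metadata)
  expect_equal(
    as.character(r1$rating[order(r1$review_id)]),
    as.character(r2$rating[order(r2$review_id)])
  )
})

test_that("stratified items flaw on any N stratum; strict mode flags critical PY", {
  mixed_flaw <- make_assessment(design_mix = "BOTH",
                                amstar = list(`9` = c(RCT = "Y", NRSI = "N")))
  expect_equal(rating_of(mixed_flaw), "LOW")
  mixed_ok <- make_assessment(design_mix = "BOTH",
                              amstar = list(`9` = c(RCT = "Y", NRSI = "PY")))
  expect_equal(rating_of(mixed_ok), "HIGH")

  py_crit <- make_assessment(amstar = list(`2` = "PY"))
  expect_equal(rating_of(py_crit), "HIGH")
  expect_equal(rating_of(py_crit, strict_py_flaw = TRUE), "LOW")

  invalid <- make_assessment(amstar = list(`1` = "PY"))
  expect_error(amstar2_overall(invalid$assessments, invalid$metadata),
               "invalid assessments")
})
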