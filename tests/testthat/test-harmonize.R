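robis_codes <- c("Y", "PY", "PN", "N", "NI")

test_that("the header rule maps ROBIS and AMSTAR-2 responses to the binary scale", {
  expect_equal(
    harmonize_robis_default(robis_codes),
    c("POS", "POS", "NEG", "NEG", "NEG")
  )
  expect_error(harmonize_robis_default("NA"), "ROBIS")
  expect_equal(harmonize_amstar_default(c("Y", "PY", "N")), c("POS", "POS", "NEG"))
  expect_error(harmonize_amstar_default("NA"), "not harmonizable")
})

test_that("rule b matches an exhaustive independent truth table (625 tuples)", {
  grid <- expand.grid(r21 = robis_codes, r22 = robis_codes,
                      r23 = robis_codes, r24 = robis_codes,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 625L)
  got <- harmonize_rule_b(grid$r21, grid$r22, grid$r23, grid$r24)
  # oracle written straight from the footnote text, independent of the
  # package's vectorized implementation
  oracle <- apply(grid, 1, function(r) {
    pos <- r %in% c("Y", "PY")
    if (all(pos)) "Y" else if (pos[3] && pos[4]) "PY" else "N"
  })
  expect_equal(got, unname(oracle))
  expect_equal(harmonize_rule_b("Y", "Y", "Y", "PY"), "Y")
  expect_equal(harmonize_rule_b("N", "Y", "Y", "PY"), "PY")
  expect_equal(harmonize_rule_b("Y", "Y", "N", "Y"), "N")
  expect_error(harmonize_rule_b("Y", "Y", "Y", "NA"), "2.4")
})

test_that("rule b is monotone under sub-item upgrades", {
  ord <- c(N = 1, PY = 2, Y = 3)
  upgrade_chain <- list(c("N", "PY"), c("PN", "PY"), c("NI", "PY"), c("PY", "Y"))
  grid <- expand.grid(r21 = robis_codes, r22 = robis_codes,
                      r23 = robis_codes, r24 = robis_codes,
                      stringsAsFactors = FALSE)
  for (slot in 1:4) {
    for (ch in upgrade_chain) {
      low <- grid
      low[[slot]] <- ch[1]
      high <- grid
      high[[slot]] <- ch[2]
      lo <- harmonize_rule_b(low$r21, low$r22, low$r23, low$r24)
      hi <- harmonize_rule_b(high$r21, high$r22, high$r23, high$r24)
      expect_true(all(ord[hi] >= ord[lo]))
    }
  }
})

test_that("rule c matches exhaustive enumeration over designs and responses", {
  amstar9 <- c("Y", "PY", "N")
  # single-design reviews: default binary on both sides
  for (design in c("RCT_ONLY", "NRSI_ONLY")) {
    for (a9 in amstar9) {
      for (r34 in robis_codes) {
        got <- harmonize_rule_c(a9, r34, design)
        expect_equal(got$amstar, if (a9 %in% c("Y", "PY")) "POS" else "NEG")
        expect_equal(got$robis, if (r34 %in% c("Y", "PY")) "POS" else "NEG")
        expect_true(got$applicable)
      }
    }
  }
  # mixed designs: conjunctive over strata
  for (rct in amstar9) {
    for (nrsi in amstar9) {
      for (r34 in robis_codes) {
        got <- harmonize_rule_c(c(RCT = rct, NRSI = nrsi), r34, "BOTH")
        both_pos <- rct %in% c("Y", "PY") && nrsi %in% c("Y", "PY")
        expect_equal(got$amstar, if (both_pos) "POS" else "NEG")
        expect_equal(got$robis, if (r34 %in% c("Y", "PY")) "POS" else "NEG")
      }
    }
  }
  expect_error(harmonize_rule_c(c(RCT = "Y"), "Y", "BOTH"), "stratum")
  # worked cases
  expect_equal(harmonize_rule_c(c(RCT = "Y", NRSI = "PY"), "Y", "BOTH")[1:2],
               list(amstar = "POS", robis = "POS"))
  expect_equal(harmonize_rule_c(c(RCT = "Y", NRSI = "N"), "PY", "BOTH")[1:2],
               list(amstar = "NEG", robis = "POS"))
  expect_equal(harmonize_rule_c("PY", "NI", "RCT_ONLY")[1:2],
               list(amstar = "POS", robis = "NEG"))
})

test_that("rule e gates on meta-analysis and combines ROBIS 4.3/4.4", {
  expect_equal(
    harmonize_rule_e("Y", "Y", "Y", has_ma = FALSE, design_mix = "RCT_ONLY"),
    list(amstar = NA_character_, robis = NA_character_, applicable = FALSE)
  )
  # exhaustive over single designs, item-11 responses and both ROBIS items
  for (a11 in c("Y", "N")) {
    for (r43 in robis_codes) {
      for (r44 in robis_codes) {
        got <- harmonize_rule_e(a11, r43, r44, TRUE, "RCT_ONLY")
        expect_equal(got$amstar, if (a11 == "Y") "POS" else "NEG")
        expect_equal(
          got$robis,
          if (r43 %in% c("Y", "PY") && r44 %in% c("Y", "PY")) "POS" else "NEG"
        )
        any_mode <- harmonize_rule_e(a11, r43, r44, TRUE, "RCT_ONLY",
                                     robis_mode = "ANY")
        expect_equal(
          any_mode$robis,
          if (r43 %in% c("Y", "PY") || r44 %in% c("Y", "PY")) "POS" else "NEG"
        )
      }
    }
  }
  # mixed design: both strata must be an unqualified Y
  for (rct in c("Y", "N")) {
    for (nrsi in c("Y", "N")) {
      got <- harmonize_rule_e(c(RCT = rct, NRSI = nrsi), "Y", "Y", TRUE, "BOTH")
      expect_equal(got$amstar, if (rct == "Y" && nrsi == "Y") "POS" else "NEG")
    }
  }
  expect_equal(harmonize_rule_e("Y", "PY", "Y", TRUE, "RCT_ONLY")[1:2],
               list(amstar = "POS", robis = "POS"))
  expect_equal(harmonize_rule_e("N", "Y", "Y", TRUE, "NRSI_ONLY")[1:2],
               list(amstar = "NEG", robis = "POS"))
})

test_that("rule f compares item 13 alone without a meta-analysis", {
  for (a13 in c("Y", "N")) {
    for (r46 in robis_codes) {
      got <- harmonize_rule_f("NA", a13, r46, has_ma = FALSE)
      expect_equal(got$amstar, if (a13 == "Y") "POS" else "NEG")
      expect_equal(got$robis, if (r46 %in% c("Y", "PY")) "POS" else "NEG")
      for (a12 in c("Y", "N")) {
        got2 <- harmonize_rule_f(a12, a13, r46, has_ma = TRUE)
        expect_equal(got2$amstar,
                     if (a12 == "Y" && a13 == "Y") "POS" else "NEG")
      }
    }
  }
  expect_equal(harmonize_rule_f("NA", "Y", "PY", FALSE)[1:2],
               list(amstar = "POS", robis = "POS"))
  expect_equal(harmonize_rule_f("N", "Y", "Y", TRUE)[1:2],
               list(amstar = "NEG", robis = "POS"))
  expect_equal(harmonize_rule_f("Y", "Y", "NI", TRUE)[1:2],
               list(amstar = "POS", robis = "NEG"))
  expect_error(harmonize_rule_f("Y", "Y", "Y", FALSE), "must be NA")
  expect_error(harmonize_rule_f("NA", "Y", "Y", TRUE), "although")
})

test_that("restricted rules reduce to the default binary rule", {
  # rule c on single-design reviews equals the default rule
  for (a in c("Y", "PY", "N")) {
    for (r in robis_codes) {
      got <- harmonize_rule_c(a, r, "RCT_ONLY")
      expect_equal(got$amstar, harmonize_amstar_default(a))
      expect_equal(got$robis, harmonize_robis_default(r))
    }
  }
  # rule e with a meta-analysis and a single design equals the default rule
  # applied to (item 11; 4.3 AND 4.4)
  for (a in c("Y", "N")) {
    for (r43 in robis_codes) {
      for (r44 in robis_codes) {
        got <- harmonize_rule_e(a, r43, r44, TRUE, "NRSI_ONLY")
        combined <- if (harmonize_robis_default(r43) == "POS" &&
                        harmonize_robis_default(r44) == "POS") "POS" else "NEG"
        expect_equal(got$amstar, harmonize_amstar_default(a))
        expect_equal(got$robis, combined)
      }
    }
  }
})

test_that("harmonize_all applies meta-analysis gating per comparison", {
  parts <- list()
  for (i in 1:10) {
    parts[[i]] <- make_assessment(sprintf("R%02d", i), has_ma = i > 4)
  }
  cohort <- do.call(bind_cohort, parts)
  pairs <- harmonize_all(cohort$assessments, cohort$metadata)
  counts <- pairs |>
    dplyr::filter(applicable) |>
    dplyr::count(comparison_id)
  expect_equal(counts$n[counts$comparison_id == 8], 6L)
  expect_equal(counts$n[counts$comparison_id == 11], 6L)
  # items 12+13 vs 4.6 falls back to item 13 alone, so stays at 10
  expect_equal(counts$n[counts$comparison_id == 9], 10L)
  # ungated comparisons keep everyone
  expect_equal(counts$n[counts$comparison_id == 1], 10L)
  expect_true(all(
    pairs |>
      dplyr::count(comparison_id) |>
      dplyr::pull(n) == 10L
  ))
})

test_that("concordant positive instruments harmonize to concordant pairs", {
  cohort <- bind_cohort(
    make_assessment("A", design_mix = "BOTH"),
    make_assessment("B", has_ma = FALSE),
    make_assessment("C")
  )
  pairs <- harmonize_all(cohort$assessments, cohort$metadata)
  app <- pairs[pairs$applicable, ]
  expect_true(all(app$amstar_cat == app$robis_cat))
})

test_that("reviews with violations are dropped with a warning", {
  good <- make_assessment("G")
  bad <- make_assessment("B", amstar = list(`1` = "PY"))
  cohort <- bind_cohort(good, bad)
  expect_warning(
    pairs <- harmonize_all(cohort$assessments, cohort$metadata),
    "dropping 1 review"
  )
  expect_equal(unique(pairs$review_id), "G")
})
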