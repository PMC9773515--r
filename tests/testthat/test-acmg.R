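test_that("evidence-code tokens parse and format as an exact round trip", {
  ps3 <- parse_code("PS3")
  expect_equal(c(ps3$base, ps3$strength, ps3$direction),
               c("PS3", "strong", "pathogenic"))
  pm2p <- parse_code("PM2_P")
  expect_equal(c(pm2p$base, pm2p$strength), c("PM2", "supporting"))
  ps4m <- parse_code("PS4_M")
  expect_equal(c(ps4m$base, ps4m$strength), c("PS4", "moderate"))
  expect_error(parse_code("XX9"), "XX9")
  expect_error(parse_code("PS3_Q"), "suffix")
  expect_error(parse_code(""), "empty")

  bases <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  for (b in bases) {
    for (s in c("supporting", "moderate", "strong", "very_strong")) {
      code <- acmg_code(b, s)
      back <- parse_code(format_code(code))
      expect_equal(back$base, code$base)
      expect_equal(back$strength, code$strength)
      expect_equal(back$direction, code$direction)
    }
  }
})

test_that("point values follow the supporting/moderate/strong/very-strong scale", {
  expect_equal(points_for(acmg_code("PS3")), 4)
  expect_equal(points_for(acmg_code("BS3")), -4)
  expect_equal(points_for(acmg_code("PM1", "supporting")), 1)
  expect_equal(points_for(acmg_code("PVS1")), 8)
  expect_equal(points_for(acmg_code("BA1")), -8)
  expect_equal(points_for(acmg_code("BP4")), -1)
  expect_equal(points_for(acmg_code("PS4", "moderate")), 2)
})

test_that("point totals map to the five classes and are permutation-invariant", {
  lp <- classify_variant("PS3,PM2_P,PS4_M,PP3,PM1_P")
  expect_equal(lp$points, 9L)
  expect_equal(lp$category, "LP")
  expect_equal(classify_variant("PM2_P,PP3,PS3,PM1_P,PS4_M")$points, 9L)

  expect_equal(classify_variant()$category, "VUS")
  expect_equal(classify_variant("BS3")$category, "LB")
  expect_equal(classify_variant("PVS1,PM1")$category, "P")      # 10
  expect_equal(classify_variant("PS3,PM2")$category, "LP")      # 6
  expect_equal(classify_variant("PS3,PM2_P")$category, "VUS")   # 5
  expect_equal(classify_variant("BP4")$category, "LB")          # -1
  expect_equal(classify_variant("BS3,BS2,PP1")$category, "B")   # -7
  expect_equal(classify_variant("BS3,BP4,PP1,PM2")$category, "LB") # -2
  expect_error(classify_variant("PS3,PS3"), "more than once")
})

test_that("adding evidence moves the class monotonically", {
  rank <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)
  set.seed(99)
  bases <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  for (rep in 1:50) {
    chosen <- sample(bases, sample(0:6, 1))
    codes <- lapply(chosen, acmg_code)
    base_cat <- rank[[classify_variant(codes)$category]]
    addable <- setdiff(bases, chosen)
    extra <- acmg_code(sample(addable, 1))
    new_cat <- rank[[classify_variant(c(codes, list(extra)))$category]]
    if (extra$direction == "pathogenic") {
      expect_gte(new_cat, base_cat)
    } else {
      expect_lte(new_cat, base_cat)
    }
  }
})

test_that("functional evidence codes follow the calibrated tier rules", {
  cal <- strong_calibration()
  ps3 <- functional_evidence_code("deleterious_protein", 4.511, cal)
  expect_equal(c(ps3$base, ps3$strength), c("PS3", "strong"))
  ps3m <- functional_evidence_code("deleterious_protein", 1.669, cal)
  expect_equal(c(ps3m$base, ps3m$strength), c("PS3", "moderate"))
  bs3 <- functional_evidence_code("neutral", -0.3, cal)
  expect_equal(c(bs3$base, bs3$strength), c("BS3", "strong"))
  expect_null(functional_evidence_code("deleterious_splice", NA, cal))
  expect_null(functional_evidence_code("intermediate", 0.2, cal))
  expect_warning(
    expect_null(functional_evidence_code("unscored", NA, cal)),
    "no function score")

  weak <- compute_oddspath(concordant_controls(3, 3, 0))
  expect_error(functional_evidence_code("neutral", -1, weak),
               "strong evidence")
})

test_that("catalog reclassification applies PS3/BS3 and conserves variants", {
  cal <- strong_calibration()
  vus <- abnormal_vus_table()
  res <- reclassify_catalog(vus, cal)
  expect_equal(res$n_ps3_strong, 14)
  expect_equal(res$n_ps3_moderate_eligible, 10)
  expect_equal(res$n_bs3, 0)
  expect_equal(res$n_previously_classified + res$newly_plp + res$newly_blb +
                 res$remaining_vus, nrow(vus))
  # PS3 strong only at or above the cutoff
  got_ps3 <- res$audit$code_added == "PS3"
  expect_true(all(res$audit$lof_score[got_ps3] >= 1.7))
  expect_true(all(res$audit$lof_score[!got_ps3] < 1.7))

  # a catalog with no VUS yields an empty summary
  plp <- vus
  plp$classification <- "LP"
  res0 <- reclassify_catalog(plp, cal)
  expect_equal(res0$n_vus, 0)
  expect_equal(nrow(res0$audit), 0)

  nocls <- vus
  nocls$classification[2] <- NA
  expect_error(reclassify_catalog(nocls, cal), "prior classification")
})

test_that("depletion test matches the exact binomial and brute force", {
  expect_equal(depletion_test(34, 682, 351, 5130),
               binomial_two_sided(34, 682, 351 / 5130))
  # at the modal count the two-sided p is 1
  p0 <- 0.3
  mode_k <- which.max(dbinom(0:20, 20, p0)) - 1
  expect_equal(depletion_test(mode_k, 20, 3, 10), 1)
  # tiny case against full enumeration
  expect_equal(depletion_test(1, 4, 1, 2), oracle_binom(1, 4, 0.5))
  expect_error(depletion_test(1, 4, 0, 2), "\\(0, 1\\)")
  expect_error(depletion_test(1, 4, 2, 2), "\\(0, 1\\)")
})
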