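test_that("Fisher two-sided p agrees with independent oracles", {
  tables <- list(c(12, 1, 2, 10), c(11, 0, 2, 4), c(38, 0, 30, 16),
                 c(9, 19, 1, 37), c(5, 5, 5, 5), c(0, 7, 3, 2))
  for (t in tables) {
    expect_equal(fisher_two_sided(t[1], t[2], t[3], t[4]),
                 oracle_fisher(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
    expect_equal(fisher_two_sided(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
  set.seed(5)
  for (rep in 1:50) {
    t <- rpois(4, 20)
    expect_equal(fisher_two_sided(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Fisher test is invariant to transposition and row+column swap,
           and degenerate margins give p = 1", {
  set.seed(11)
  for (rep in 1:40) {
    t <- matrix(rpois(4, 8), 2)
    p <- fisher_two_sided(t)
    expect_equal(fisher_two_sided(t(t)), p)
    expect_equal(fisher_two_sided(t[2:1, 2:1]), p)
    expect_gte(p, 0); expect_lte(p, 1)
  }
  expect_equal(fisher_two_sided(3, 0, 5, 0), 1)
  expect_equal(fisher_two_sided(0, 0, 2, 3), 1)
  expect_equal(fisher_two_sided(0, 0, 0, 0), 1)
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_two_sided(1.5, 2, 3, 4), "integers")
})

test_that("Fisher test equals exhaustive enumeration for all tables with N <= 12", {
  for (N in 1:12) {
    for (a_c in 0:N) {          # column margin
      for (r1 in 0:N) {         # row margin
        for (a in max(0, a_c - (N - r1)):min(a_c, r1)) {
          b <- r1 - a; cc <- a_c - a; d <- N - r1 - cc
          expect_equal(fisher_two_sided(a, b, cc, d),
                       oracle_fisher(a, b, cc, d), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("exact binomial two-sided p matches enumeration and base R", {
  expect_equal(binomial_two_sided(2, 10, 0.5), oracle_binom(2, 10, 0.5))
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(1:25, 1)
    x <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_two_sided(x, n, p0), oracle_binom(x, n, p0),
                 tolerance = 1e-12)
    expect_equal(binomial_two_sided(x, n, p0),
                 stats::binom.test(x, n, p0)$p.value, tolerance = 1e-10)
  }
  # modal observation carries no evidence
  expect_equal(binomial_two_sided(which.max(dbinom(0:30, 30, 0.4)) - 1,
                                  30, 0.4), 1)
  # central method is the capped doubled tail
  expect_equal(binomial_two_sided(2, 10, 0.5, method = "central"),
               min(1, 2 * pbinom(2, 10, 0.5)))
  expect_error(binomial_two_sided(5, 10, 0), "p0")
  expect_error(binomial_two_sided(11, 10, 0.5), "x must be")
})

test_that("2x2 odds ratio and Woolf interval behave as the closed form", {
  r <- odds_ratio_2x2(12, 1, 2, 10)
  expect_equal(r$odds_ratio, 60)
  expect_false(r$continuity_corrected)
  expect_equal(r$ci_low, exp(log(60) - qnorm(0.975) *
                               sqrt(1 / 12 + 1 + 1 / 2 + 1 / 10)))
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  expect_equal(odds_ratio_2x2(5, 5, 5, 5)$odds_ratio, 1)
  rz <- odds_ratio_2x2(10, 0, 5, 5)
  expect_true(rz$continuity_corrected)
  expect_true(is.finite(rz$ci_high))
})

test_that("logistic fit with one binary covariate reproduces the sample odds
           ratio to six significant digits", {
  # carriers: 12 cases / 1 control; non-carriers: 2 cases / 10 controls
  cohort <- data.frame(
    sex = "female",
    msh2_mis_deleterious = rep(c(1, 0), c(13, 12)),
    crc_dx = c(rep(1, 12), 0, rep(1, 2), rep(0, 10))
  )
  fit <- fit_cancer_association(cohort, "CRC",
                                features = "msh2_mis_deleterious",
                                include_sex = FALSE)
  expect_equal(signif(fit$odds_ratio, 6), signif(60, 6))
  expect_equal(signif(fit$odds_ratio, 6),
               signif(odds_ratio_2x2(12, 1, 2, 10)$odds_ratio, 6))
})

test_that("null features cover 1 and separation is flagged, never silent", {
  set.seed(31)
  n <- 20000
  cohort <- data.frame(sex = "female",
                       msh2_mis_deleterious = rbinom(n, 1, 0.3),
                       crc_dx = rbinom(n, 1, 0.2))
  fit <- fit_cancer_association(cohort, "CRC",
                                features = "msh2_mis_deleterious",
                                include_sex = FALSE)
  expect_true(fit$ci_low < 1 && fit$ci_high > 1)

  sep <- data.frame(sex = "female",
                    msh2_mis_deleterious = rep(c(1, 0), each = 30),
                    crc_dx = rep(c(1, 0), each = 30))
  fit_sep <- fit_cancer_association(sep, "CRC",
                                    features = "msh2_mis_deleterious",
                                    include_sex = FALSE)
  expect_true(fit_sep$separation)

  empty <- data.frame(sex = "female",
                      msh2_mis_deleterious = rbinom(100, 1, 0.5),
                      msh2_mis_neutral = 0,
                      crc_dx = rbinom(100, 1, 0.3))
  expect_warning(
    fit2 <- fit_cancer_association(
      empty, "CRC",
      features = c("msh2_mis_deleterious", "msh2_mis_neutral"),
      include_sex = FALSE),
    "empty feature")
  expect_equal(nrow(fit2), 1)
})

test_that("Wald 95% intervals attain nominal coverage under the null", {
  set.seed(41)
  hits <- 0L
  reps <- 1000L
  n <- 500L
  for (r in seq_len(reps)) {
    cohort <- data.frame(sex = "female",
                         msh2_mis_deleterious = rbinom(n, 1, 0.5),
                         crc_dx = rbinom(n, 1, 0.3))
    fit <- fit_cancer_association(cohort, "CRC",
                                  features = "msh2_mis_deleterious",
                                  include_sex = FALSE)
    if (fit$ci_low <= 1 && 1 <= fit$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.93)
  expect_lte(hits / reps, 0.97)
})

test_that("exclusion rules reshape the cohort before fitting", {
  cohort <- data.frame(
    sex = "female",
    msh2_mis_deleterious = c(1, 1, 1, 0, 0, 0, 1, 0),
    msh2_mis_neutral = 0,
    msh2_other_plp = 0,
    mlh1_plp = c(0, 0, 1, 0, 0, 0, 0, 1),
    msh6_plp = 0, pms2_plp = 0,
    non_ls_plp = c(0, 1, 0, 0, 0, 0, 0, 0),
    crc_dx = c(1, 1, 1, 0, 1, 0, 0, 0),
    uec_dx = 0
  )
  fit <- suppressWarnings(fit_cancer_association(
    cohort, "CRC", features = c("msh2_mis_deleterious", "mlh1_plp"),
    include_sex = FALSE))
  # row 2 dropped (non-LS P/LP with a VUS), row 3 re-assigned to MLH1
  expect_equal(attr(fit, "n"), 7)
  expect_equal(fit$n_carriers[fit$term == "msh2_mis_deleterious"], 2)
  expect_equal(fit$n_carriers[fit$term == "mlh1_plp"], 2)
})
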