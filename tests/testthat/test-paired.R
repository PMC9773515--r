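test_that("sole-MSH2-missense selection is exact, idempotent and order-invariant", {
  pc <- toy_paired(c(3, -0.5, 2), c(TRUE, FALSE, TRUE))
  # add a second germline finding (MLH1 P/LP) to case 3 -> excluded
  extra <- pc$germline[1, ]
  extra$individual_id <- pc$cases$individual_id[3]
  extra$gene <- "MLH1"; extra$hgvs_c <- "c.999G>A"
  extra$consequence <- "truncating"; extra$classification <- "P"
  pc$germline <- rbind(pc$germline, extra)

  sel <- select_sole_msh2_missense_cases(pc)
  expect_equal(sort(sel$cases$individual_id), c("C001", "C002"))
  sel2 <- select_sole_msh2_missense_cases(sel)
  expect_identical(sel2$cases, sel$cases)
  shuffled <- paired_cohort(pc$cases[c(3, 1, 2), ],
                            pc$germline[c(4, 2, 3, 1), ], pc$somatic)
  expect_equal(sort(select_sole_msh2_missense_cases(shuffled)$cases$individual_id),
               c("C001", "C002"))
  empty <- select_sole_msh2_missense_cases(
    paired_cohort(pc$cases[0, ], pc$germline[0, ], pc$somatic[0, ]))
  expect_equal(nrow(empty$cases), 0)
})

test_that("second-hit enrichment reproduces the clinical contingency structure", {
  # 13 deleterious germline carriers, 12 with a second hit;
  # 12 neutral carriers, 2 with a second hit
  lof <- c(rep(2.5, 13), rep(-0.5, 12))
  hit <- c(rep(TRUE, 12), FALSE, rep(TRUE, 2), rep(FALSE, 10))
  res <- second_hit_analysis(toy_paired(lof, hit))
  expect_equal(as.vector(res$table), c(12, 2, 1, 10))
  expect_equal(round(res$p_value, 5), 0.00021)

  # hits everywhere -> no signal
  res1 <- second_hit_analysis(toy_paired(c(2, 2, -1, -1), rep(TRUE, 4)))
  expect_equal(res1$p_value, 1)

  # hand-enumerated toy: del {hit, no-hit}, neutral {hit, no-hit}
  res2 <- second_hit_analysis(toy_paired(c(2, 2, -1, -1),
                                         c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(as.vector(res2$table), c(1, 1, 1, 1))
  expect_equal(res2$p_value, oracle_fisher(1, 1, 1, 1))

  # EPCAM structural variants count as second hits
  pc <- toy_paired(c(2, -1), c(FALSE, FALSE))
  pc$cases$epcam_structural_variant <- c(TRUE, FALSE)
  expect_equal(as.vector(second_hit_analysis(pc)$table), c(1, 0, 0, 1))

  # LOH events count only when configured in
  pc2 <- toy_paired(c(2, -1), c(TRUE, FALSE), hit_type = "loh")
  expect_equal(as.vector(second_hit_analysis(pc2)$table), c(1, 0, 0, 1))
  expect_equal(as.vector(second_hit_analysis(pc2, include_loh = FALSE)$table),
               c(0, 0, 1, 1))

  # intermediate germline tiers are excluded and logged
  pc3 <- toy_paired(c(2, 0.2, -1), c(TRUE, TRUE, FALSE))
  res3 <- second_hit_analysis(pc3)
  expect_equal(sum(res3$table), 2)
  expect_equal(res3$excluded$not_scored_or_intermediate, 1)
})

test_that("MSI analysis excludes methylated tumors and codes MSI-low as unstable", {
  # 11 deleterious all MSI-high; 6 neutral with 2 unstable (one MSI_low);
  # plus one methylated and one unassayed case, both excluded
  lof <- c(rep(2.5, 11), rep(-0.5, 6), -0.5, 2.5)
  msi <- c(rep("MSI_high", 11), "MSI_high", "MSI_low", rep("MSS", 4),
           "MSI_high", "not_assayed")
  meth <- c(rep(FALSE, 17), TRUE, FALSE)
  pc <- toy_paired(lof, rep(FALSE, 19), msi = msi, meth = meth)
  res <- msi_analysis(pc)
  expect_equal(as.vector(res$table), c(11, 2, 0, 4))
  expect_equal(round(res$p_value, 4), 0.0063)
  expect_equal(res$excluded$mlh1_hypermethylated, 1)
  expect_equal(res$excluded$msi_not_assayed, 1)

  # both groups fully unstable -> p = 1
  res1 <- msi_analysis(toy_paired(c(2, -1), c(FALSE, FALSE),
                                  msi = c("MSI_high", "MSI_high"),
                                  meth = FALSE))
  expect_equal(res1$p_value, 1)

  allm <- toy_paired(c(2, -1), c(FALSE, FALSE),
                     msi = c("MSI_high", "MSS"), meth = TRUE)
  expect_error(msi_analysis(allm), "no evaluable cases")
})

test_that("somatic-coincidence grouping reproduces the published tables", {
  # 46 disruptive-somatic-missense tumors (30 with other-LS somatic
  # mutations, methylation assayed in 38 with 1 positive) and 38
  # neutral-only tumors (38/38 other-LS, assayed in 28 with 9 positive)
  n <- 84
  ids <- sprintf("S%03d", 1:n)
  disruptive <- c(rep(TRUE, 46), rep(FALSE, 38))
  other_ls <- c(rep(TRUE, 30), rep(FALSE, 16), rep(TRUE, 38))
  assayed <- c(rep(TRUE, 38), rep(FALSE, 8), rep(TRUE, 28), rep(FALSE, 10))
  meth <- c(rep(c(TRUE, FALSE), c(1, 45)), rep(c(TRUE, FALSE), c(9, 29)))
  cases <- data.frame(individual_id = ids, msi_status = "MSI_high",
                      mlh1_promoter_hypermethylated = ifelse(assayed, meth, NA),
                      epcam_structural_variant = FALSE)
  germline <- data.frame(individual_id = character(0), gene = character(0),
                         hgvs_c = character(0), consequence = character(0),
                         classification = character(0),
                         lof_score = numeric(0),
                         spliceai_deltamax = numeric(0))
  som_mis <- data.frame(individual_id = ids, gene = "MSH2",
                        event_type = "mutation",
                        hgvs_c = sprintf("c.%d_m", 1:n),
                        consequence = "missense", classification = "VUS",
                        lof_score = ifelse(disruptive, 2.5, -0.5),
                        spliceai_deltamax = 0.01)
  som_ols <- data.frame(individual_id = ids[other_ls], gene = "MSH6",
                        event_type = "mutation",
                        hgvs_c = sprintf("c.%d_o", which(other_ls)),
                        consequence = "truncating", classification = "P",
                        lof_score = NA_real_, spliceai_deltamax = NA_real_)
  pc <- paired_cohort(cases, germline, rbind(som_mis, som_ols))

  res <- somatic_coincidence_analysis(pc)
  expect_equal(res$n_disruptive, 46)
  expect_equal(res$n_neutral, 38)
  expect_equal(as.vector(res$other_ls$table), c(38, 30, 0, 16))
  expect_equal(signif(res$other_ls$p_value, 3), 2.70e-5)
  expect_equal(as.vector(res$methylation$table), c(9, 1, 19, 37))
  expect_equal(round(res$methylation$p_value, 4), 0.0013)

  # a neutral-missense tumor with another somatic MSH2 P/LP leaves the
  # neutral group
  extra <- som_ols[1, ]
  extra$individual_id <- ids[47]; extra$gene <- "MSH2"
  extra$hgvs_c <- "c.trunc47"
  pc2 <- paired_cohort(cases, germline, rbind(som_mis, som_ols, extra))
  res2 <- somatic_coincidence_analysis(pc2)
  expect_equal(res2$n_neutral, 37)
  expect_equal(res2$n_total, res$n_total)

  # empty result when no somatic MSH2 missense exists
  pc3 <- paired_cohort(cases, germline, som_ols)
  expect_equal(somatic_coincidence_analysis(pc3)$n_total, 0)
})

test_that("paired-cohort TSV round trip preserves the three tables", {
  pc <- toy_paired(c(2.5, -0.5, 0.2), c(TRUE, FALSE, TRUE),
                   msi = c("MSI_high", "MSS", "not_assayed"),
                   meth = c(TRUE, FALSE, NA))
  dir <- withr::local_tempdir()
  write_paired_cohort(pc, dir)
  back <- read_paired_cohort(dir)
  expect_equal(back$cases[order(back$cases$individual_id), ],
               pc$cases[order(pc$cases$individual_id), ],
               ignore_attr = TRUE)
  expect_equal(back$germline[order(back$germline$individual_id), ],
               pc$germline[order(pc$germline$individual_id), ],
               ignore_attr = TRUE)
  bs <- back$somatic[order(back$somatic$individual_id), ]
  ps <- pc$somatic[order(pc$somatic$individual_id), ]
  expect_equal(bs, ps, ignore_attr = TRUE)
})
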