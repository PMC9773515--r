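# Independent oracles and small fixture builders used across the suite.

# Fisher two-sided p by direct combinatorial enumeration: probability of a
# table with margins fixed is choose(r1, a) * choose(r2, c) / choose(N, a+c).
# Plain choose() arithmetic, exact for the small totals used in tests;
# deliberately avoids dhyper(), the implementation's code path.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; m <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || m == 0 || (b + d) == 0) return(1)
  ks <- max(0, m - r2):min(m, r1)
  probs <- choose(r1, ks) * choose(r2, m - ks) / choose(N, m)
  pobs <- choose(r1, a) * choose(r2, m - a) / choose(N, m)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Binomial two-sided p by full-outcome enumeration with plain choose().
oracle_binom <- function(x, n, p0) {
  ks <- 0:n
  probs <- choose(n, ks) * p0^ks * (1 - p0)^(n - ks)
  min(1, sum(probs[probs <= probs[x + 1] * (1 + 1e-7)]))
}

# A random but valid variant catalog for round-trip and property tests.
random_catalog <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    gene = sample(c("MSH2", "MLH1", "MSH6", "PMS2"), n, replace = TRUE),
    hgvs_c = sprintf("c.%d%s>%s", sample.int(10 * n, n),
                     sample(c("A", "C", "G", "T"), n, TRUE),
                     sample(c("A", "C", "G", "T"), n, TRUE)),
    hgvs_p = sprintf("p.(Xx%d)", seq_len(n)),
    consequence = sample(c("missense", "truncating", "other"), n, TRUE),
    classification = sample(c("B", "LB", "VUS", "LP", "P"), n, TRUE),
    lof_score = ifelse(runif(n) < 0.1, NA, round(rnorm(n, 0.5, 1.5), 6)),
    spliceai_deltamax = ifelse(runif(n) < 0.1, NA, round(runif(n), 6)),
    gnomad_af = ifelse(runif(n) < 0.7, NA, signif(runif(n, 0, 1e-3), 5)),
    stringsAsFactors = FALSE
  )
}

# Control set matching the calibration study conditions: n_p pathogenic
# (n_int of them intermediate-scoring), n_b benign neutral, all concordant.
concordant_controls <- function(n_p = 22, n_b = 26, n_int = 1) {
  data.frame(
    classification = c(rep(c("P", "LP"), length.out = n_p),
                       rep(c("B", "LB"), length.out = n_b)),
    tier = c(rep("deleterious_protein", n_p - n_int),
             rep("intermediate", n_int),
             rep("neutral", n_b)),
    uses_functional_evidence = FALSE,
    stringsAsFactors = FALSE
  )
}

# Minimal paired cohort built from per-case vectors.
toy_paired <- function(germline_lof, second_hit,
                       msi = NULL, meth = NA, epcam = FALSE,
                       hit_type = "mutation") {
  n <- length(germline_lof)
  ids <- sprintf("C%03d", seq_len(n))
  if (is.null(msi)) msi <- rep("MSS", n)
  cases <- data.frame(individual_id = ids, msi_status = msi,
                      mlh1_promoter_hypermethylated = rep_len(meth, n),
                      epcam_structural_variant = rep_len(epcam, n),
                      stringsAsFactors = FALSE)
  germline <- data.frame(individual_id = ids, gene = "MSH2",
                         hgvs_c = sprintf("c.%dA>G", seq_len(n)),
                         consequence = "missense", classification = "VUS",
                         lof_score = germline_lof,
                         spliceai_deltamax = 0.01,
                         stringsAsFactors = FALSE)
  hit_type <- rep_len(hit_type, n)
  i <- which(second_hit)
  k <- length(i)
  somatic <- data.frame(
    individual_id = ids[i], gene = rep("MSH2", k),
    event_type = ifelse(hit_type[i] == "loh", "loh", "mutation"),
    hgvs_c = ifelse(hit_type[i] == "loh", NA, sprintf("c.%d_som", i)),
    consequence = rep("truncating", k),
    classification = ifelse(hit_type[i] == "loh", "VUS", "P"),
    lof_score = rep(NA_real_, k),
    spliceai_deltamax = rep(NA_real_, k),
    stringsAsFactors = FALSE
  )
  paired_cohort(cases, germline, somatic)
}

# Calibration object with strong evidence both ways, for the ACMG engine.
strong_calibration <- function() {
  compute_oddspath(curate_controls(concordant_controls()))
}
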