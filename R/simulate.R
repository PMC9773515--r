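# Synthetic cohort generator. Emulates the statistical structure the
# analyses assume -- bimodal function-score distributions, a curated control
# mix, logistic penetrance, and conditional two-hit / MSI structure -- so
# every pipeline stage is testable without protected clinical data. All
# identifiers are placeholder strings; no sequence context is simulated.

#' Simulation configuration
#'
#' All generator parameters with defaults emulating the clinical cohort the
#' pipeline was designed around. LoF scores are drawn from a two-component
#' normal mixture (neutral component near 0, deleterious component in the
#' abnormal range); splice-disruption scores place a configurable mass above
#' the deleterious cutoff. Carrier cancer outcomes are drawn from a logistic
#' model whose odds ratios are configuration, so parameter recovery is
#' testable. Each sub-generator uses its own RNG stream split
#' deterministically from the master seed, so adding one generator does not
#' perturb the others. A fixed seed gives byte-identical output.
#'
#' @param seed Master RNG seed (integer).
#' @param n_variants Catalog size.
#' @param frac_deleterious Fraction of variants in the protein-deleterious
#'   score component (default 298/5130, the abnormal-by-assay rate among
#'   unobserved missense SNVs).
#' @param lof_neutral_mean,lof_neutral_sd,lof_deleterious_mean,lof_deleterious_sd
#'   Mixture component parameters for the LoF score.
#' @param frac_splice_disruptive Fraction of variants with deltaMax at or
#'   above 0.5 (default 53/5130).
#' @param frac_vus Fraction of catalog variants left as VUS; the remainder
#'   are classified concordantly with their score component (P/LP for
#'   deleterious, B/LB for neutral) except for \code{n_discordant} injected
#'   discordants.
#' @param n_discordant Number of score-discordant classified variants.
#' @param n_carriers Germline cohort size.
#' @param sex_ratio_female Proportion female (default 11687/13916).
#' @param baseline_crc_female,baseline_crc_male Baseline colorectal cancer
#'   rates for the reference (no-feature) group, by sex.
#' @param baseline_uec_female Baseline uterine/endometrial cancer rate
#'   (females; males never have the outcome).
#' @param or_crc,or_uec Named odds-ratio vectors over
#'   [association_features()].
#' @param feature_prevalence Named probabilities (summing to at most 1) that
#'   a carrier falls in each feature category; the remainder carry none.
#' @param non_ls_plp_rate Rate of co-occurring P/LP findings in
#'   non-Lynch-syndrome genes (exercises the exclusion rules).
#' @param n_paired Paired tumor-normal cohort size.
#' @param frac_paired_sole_msh2_missense Fraction of paired cases whose sole
#'   germline finding is an MSH2 missense variant.
#' @param frac_germline_deleterious Among those, fraction with a
#'   functionally deleterious germline variant (default 13/25).
#' @param second_hit_rate_deleterious,second_hit_rate_neutral Somatic
#'   second-hit probabilities by germline tier (defaults 0.92 / 0.17).
#' @param loh_fraction_of_hits Fraction of second hits realized as LOH
#'   rather than point mutation.
#' @param epcam_sv_rate Rate of EPCAM structural variants among second hits.
#' @param msi_given_two_hits,msi_given_no_hit MSI probability conditional on
#'   carrying / lacking a biallelic MSH2 (or equivalent) explanation.
#' @param msi_low_fraction Among unstable tumors, fraction rated MSI-low.
#' @param msi_not_assayed_rate Fraction of tumors without MSI testing.
#' @param mlh1_methylation_rate MLH1 promoter hypermethylation rate among
#'   tumors lacking an MSH2 two-hit explanation.
#' @param methylation_assayed_rate Fraction of tumors with MLH1 methylation
#'   testing.
#' @param somatic_msh2_missense_rate Rate of somatic MSH2 missense variants
#'   per case.
#' @param frac_somatic_missense_deleterious Among those, fraction
#'   functionally disruptive (default 46/84).
#' @param other_ls_somatic_given_unexplained,other_ls_somatic_given_disruptive
#'   Probability of a somatic mutation in another LS gene when the MSH2
#'   somatic missense burden is neutral-only (MMR deficiency must be
#'   explained elsewhere) versus disruptive.
#' @param control_set_spec Named vector \code{n_pathogenic},
#'   \code{n_benign}, \code{n_pathogenic_intermediate} for the calibration
#'   control draw.
#' @return Validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(
    seed = 1L,
    n_variants = 2000L,
    frac_deleterious = 298 / 5130,
    lof_neutral_mean = -0.3, lof_neutral_sd = 0.15,
    lof_deleterious_mean = 2.5, lof_deleterious_sd = 1.0,
    frac_splice_disruptive = 53 / 5130,
    frac_vus = 0.90,
    n_discordant = 0L,
    n_carriers = 20000L,
    sex_ratio_female = 11687 / 13916,
    baseline_crc_female = 0.089,
    baseline_crc_male = 0.383,
    baseline_uec_female = 0.095,
    or_crc = c(msh2_mis_deleterious = 2.53, msh2_mis_neutral = 1.0,
               msh2_other_plp = 8.10, mlh1_plp = 14.4,
               msh6_plp = 2.5, pms2_plp = 1.5),
    or_uec = c(msh2_mis_deleterious = 5.56, msh2_mis_neutral = 1.0,
               msh2_other_plp = 11.9, mlh1_plp = 5.0,
               msh6_plp = 13.2, pms2_plp = 2.0),
    feature_prevalence = c(msh2_mis_deleterious = 0.02,
                           msh2_mis_neutral = 0.12,
                           msh2_other_plp = 0.15, mlh1_plp = 0.15,
                           msh6_plp = 0.15, pms2_plp = 0.10),
    non_ls_plp_rate = 0.05,
    n_paired = 1604L,
    frac_paired_sole_msh2_missense = 25 / 1604,
    frac_germline_deleterious = 13 / 25,
    second_hit_rate_deleterious = 0.92,
    second_hit_rate_neutral = 0.17,
    loh_fraction_of_hits = 0.3,
    epcam_sv_rate = 0.05,
    msi_given_two_hits = 0.95,
    msi_given_no_hit = 0.25,
    msi_low_fraction = 0.1,
    msi_not_assayed_rate = 0.03,
    mlh1_methylation_rate = 0.30,
    methylation_assayed_rate = 0.7,
    somatic_msh2_missense_rate = 84 / 1604,
    frac_somatic_missense_deleterious = 46 / 84,
    other_ls_somatic_given_unexplained = 0.97,
    other_ls_somatic_given_disruptive = 0.65,
    control_set_spec = c(n_pathogenic = 22L, n_benign = 26L,
                         n_pathogenic_intermediate = 1L)) {
  cfg <- as.list(environment())
  props <- c("frac_deleterious", "frac_splice_disruptive", "frac_vus",
             "sex_ratio_female", "baseline_crc_female", "baseline_crc_male",
             "baseline_uec_female", "non_ls_plp_rate",
             "frac_paired_sole_msh2_missense", "frac_germline_deleterious",
             "second_hit_rate_deleterious", "second_hit_rate_neutral",
             "loh_fraction_of_hits", "epcam_sv_rate", "msi_given_two_hits",
             "msi_given_no_hit", "msi_low_fraction", "msi_not_assayed_rate",
             "mlh1_methylation_rate", "methylation_assayed_rate",
             "somatic_msh2_missense_rate",
             "frac_somatic_missense_deleterious",
             "other_ls_somatic_given_unexplained",
             "other_ls_somatic_given_disruptive")
  for (p in props) {
    v <- cfg[[p]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("configuration proportion out of [0, 1]: ", p)
    }
  }
  stopifnot(cfg$lof_neutral_sd > 0, cfg$lof_deleterious_sd > 0,
            cfg$n_variants >= 1, cfg$n_carriers >= 1, cfg$n_paired >= 0,
            sum(cfg$feature_prevalence) <= 1,
            all(cfg$or_crc > 0), all(cfg$or_uec > 0),
            all(c("n_pathogenic", "n_benign", "n_pathogenic_intermediate")
                %in% names(cfg$control_set_spec)))
  if (abs(cfg$seed) >= 2^31 - 5000) stop("seed too large")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "simulation_config"
  cfg
}

# One RNG stream per sub-generator, split deterministically from the master
# seed: offsets keep the derived seeds inside 32-bit integer range.
sub_seed <- function(config, stream) {
  offsets <- c(catalog = 101L, controls = 211L, germline = 307L,
               paired = 401L)
  as.integer(config$seed + offsets[[stream]])
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic variant catalog
#'
#' LoF scores come from the configured two-component normal mixture;
#' deltaMax scores place \code{frac_splice_disruptive} of the mass above the
#' splice cutoff, the rest mostly below 0.2 with a thin intermediate tail.
#' Classifications leave \code{frac_vus} as VUS and assign the rest
#' concordantly with the generating component (P/LP for
#' deleterious-component variants, B/LB otherwise), with
#' \code{n_discordant} deliberate discordants. The generating component is
#' echoed per record in \code{truth_component} so tier recovery is
#' testable. HGVS strings are unique placeholders.
#'
#' @param config A [simulation_config()].
#' @return Variant catalog data frame (see [read_variant_table()]) with
#'   extra columns \code{truth_component} and \code{evidence_codes}.
#' @export
gen_catalog <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(sub_seed(config, "catalog"))
  n <- config$n_variants
  is_del <- stats::rbinom(n, 1, config$frac_deleterious) == 1
  lof <- ifelse(is_del,
                stats::rnorm(n, config$lof_deleterious_mean,
                             config$lof_deleterious_sd),
                stats::rnorm(n, config$lof_neutral_mean,
                             config$lof_neutral_sd))
  is_splice <- stats::rbinom(n, 1, config$frac_splice_disruptive) == 1
  dm <- ifelse(is_splice,
               stats::runif(n, 0.5, 1),
               pmin(stats::rbeta(n, 0.5, 18), 0.499))
  component <- ifelse(is_splice, "splice",
                      ifelse(is_del, "deleterious", "neutral"))
  is_vus <- stats::rbinom(n, 1, config$frac_vus) == 1
  deleterious_truth <- component != "neutral"
  cls <- ifelse(is_vus, "VUS",
                ifelse(deleterious_truth,
                       sample(c("P", "LP"), n, replace = TRUE),
                       sample(c("B", "LB"), n, replace = TRUE)))
  if (config$n_discordant > 0) {
    idx <- which(!is_vus)
    flip <- utils::head(idx, config$n_discordant)
    cls[flip] <- ifelse(deleterious_truth[flip],
                        sample(c("B", "LB"), length(flip), replace = TRUE),
                        sample(c("P", "LP"), length(flip), replace = TRUE))
  }
  # prior (non-functional) evidence-code profiles for the VUS: rare-variant
  # population evidence is common; phenotype and computational evidence less
  # so, the latter correlated with true deleteriousness
  codes <- character(n)
  pm2 <- stats::rbinom(n, 1, 0.8) == 1
  pp4 <- stats::rbinom(n, 1, 0.2) == 1
  pp3 <- stats::rbinom(n, 1, ifelse(deleterious_truth, 0.5, 0.05)) == 1
  ps4m <- stats::rbinom(n, 1, ifelse(deleterious_truth, 0.10, 0.01)) == 1
  bp4 <- !pp3 & stats::rbinom(n, 1, ifelse(deleterious_truth, 0.02, 0.2)) == 1
  for (i in which(is_vus)) {
    toks <- c(if (pm2[i]) "PM2_P", if (pp4[i]) "PP4", if (pp3[i]) "PP3",
              if (ps4m[i]) "PS4_M", if (bp4[i]) "BP4")
    codes[i] <- paste(toks, collapse = ",")
  }
  data.frame(
    gene = "MSH2",
    hgvs_c = sprintf("c.%d%s>%s", seq_len(n),
                     sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     sample(c("A", "C", "G", "T"), n, replace = TRUE)),
    hgvs_p = sprintf("p.(Sv%05d)", seq_len(n)),
    consequence = "missense",
    classification = cls,
    lof_score = lof,
    spliceai_deltamax = dm,
    gnomad_af = NA_real_,
    evidence_codes = codes,
    truth_component = component,
    stringsAsFactors = FALSE
  )
}

#' Draw a calibration control set from a catalog
#'
#' Selects \code{n_pathogenic} P/LP variants with abnormal (protein-
#' deleterious) scores -- of which \code{n_pathogenic_intermediate} have
#' their scores moved into the intermediate band -- and \code{n_benign}
#' B/LB variants with neutral scores. All are flagged as classified without
#' functional evidence, making them usable calibration controls.
#'
#' @param config A [simulation_config()].
#' @param catalog Catalog from [gen_catalog()].
#' @return Control data frame: catalog columns plus
#'   \code{uses_functional_evidence = FALSE}.
#' @export
gen_control_set <- function(config, catalog) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(sub_seed(config, "controls"))
  spec <- config$control_set_spec
  cat_t <- annotate_tiers(catalog)
  # prefer variants already classified concordantly; top up from the
  # score-concordant pool, which the curated control table then labels
  pool <- function(tiers, classes) {
    classified <- which(cat_t$classification %in% classes &
                          cat_t$tier %in% tiers)
    extra <- which(cat_t$classification == "VUS" & cat_t$tier %in% tiers)
    c(classified, extra)
  }
  path_pool <- pool("deleterious_protein", c("P", "LP"))
  benign_pool <- pool("neutral", c("B", "LB"))
  n_p <- spec[["n_pathogenic"]]; n_b <- spec[["n_benign"]]
  n_int <- spec[["n_pathogenic_intermediate"]]
  if (n_int > n_p) stop("n_pathogenic_intermediate exceeds n_pathogenic")
  if (length(path_pool) < n_p || length(benign_pool) < n_b) {
    stop("catalog has too few score-concordant variants for the ",
         "requested control set")
  }
  pick_p <- path_pool[seq_len(n_p)]
  pick_b <- benign_pool[seq_len(n_b)]
  controls <- cat_t[c(pick_p, pick_b), , drop = FALSE]
  controls$classification <- rep(c("P", "B"), c(n_p, n_b))
  controls$classification[seq_len(n_p)] <-
    sample(c("P", "LP"), n_p, replace = TRUE)
  controls$classification[n_p + seq_len(n_b)] <-
    sample(c("B", "LB"), n_b, replace = TRUE)
  if (n_int > 0) {
    i <- seq_len(n_int)  # first of the pathogenic picks
    controls$lof_score[i] <- stats::runif(n_int, 0.05, 0.35)
    controls$spliceai_deltamax[i] <- stats::runif(n_int, 0, 0.15)
  }
  controls$tier <- NULL
  controls$mechanism <- NULL
  controls$uses_functional_evidence <- FALSE
  rownames(controls) <- NULL
  controls
}

#' Generate a synthetic germline carrier cohort
#'
#' Each carrier receives a sex, at most one carrier-feature category
#' (sampled from \code{feature_prevalence}; MSH2 missense carriers are
#' linked to a concordant catalog variant), and cancer outcomes drawn from
#' the logistic model \eqn{logit(p) = logit(baseline_{sex}) + \sum_f x_f
#' \log OR_f} with the configured odds-ratio tables. Uterine/endometrial
#' outcomes are structurally female-only.
#'
#' @param config A [simulation_config()].
#' @param catalog Catalog from [gen_catalog()].
#' @return Carrier table: \code{individual_id}, \code{sex}, feature 0/1
#'   columns, \code{non_ls_plp}, \code{variant_hgvs_c}, and outcomes
#'   \code{crc_dx}, \code{uec_dx}, \code{other_cancer_dx}.
#' @export
gen_germline_cohort <- function(config, catalog) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(sub_seed(config, "germline"))
  n <- config$n_carriers
  feats <- association_features()
  prev <- config$feature_prevalence[feats]
  category <- sample(c(feats, "none"), n, replace = TRUE,
                     prob = c(prev, 1 - sum(prev)))
  sex <- ifelse(stats::rbinom(n, 1, config$sex_ratio_female) == 1,
                "female", "male")
  X <- vapply(feats, function(f) as.integer(category == f), integer(n))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, feats))

  cat_t <- annotate_tiers(catalog)
  del_pool <- cat_t$hgvs_c[cat_t$tier %in%
                             c("deleterious_protein", "deleterious_splice") &
                             cat_t$classification == "VUS"]
  neu_pool <- cat_t$hgvs_c[cat_t$tier == "neutral" &
                             cat_t$classification == "VUS"]
  variant <- rep(NA_character_, n)
  pick <- function(pool, k) if (length(pool)) sample(pool, k, replace = TRUE)
                            else rep(NA_character_, k)
  i_del <- category == "msh2_mis_deleterious"
  i_neu <- category == "msh2_mis_neutral"
  variant[i_del] <- pick(del_pool, sum(i_del))
  variant[i_neu] <- pick(neu_pool, sum(i_neu))

  draw_outcome <- function(baseline, ors) {
    eta <- logit(baseline) + as.vector(X %*% log(ors[feats]))
    stats::rbinom(n, 1, inv_logit(eta))
  }
  base_crc <- ifelse(sex == "female", config$baseline_crc_female,
                     config$baseline_crc_male)
  crc <- draw_outcome(base_crc, config$or_crc)
  uec <- integer(n)
  fem <- sex == "female"
  if (any(fem)) {
    eta <- logit(config$baseline_uec_female) +
      as.vector(X[fem, , drop = FALSE] %*% log(config$or_uec[feats]))
    uec[fem] <- stats::rbinom(sum(fem), 1, inv_logit(eta))
  }
  other <- stats::rbinom(n, 1, ifelse(fem, 0.496, 0.407))
  out <- data.frame(individual_id = sprintf("G%06d", seq_len(n)),
                    sex = sex, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X))
  out$non_ls_plp <- stats::rbinom(n, 1, config$non_ls_plp_rate)
  out$variant_hgvs_c <- variant
  out$crc_dx <- crc
  out$uec_dx <- uec
  out$other_cancer_dx <- other
  out
}

#' Generate a synthetic paired tumor-normal cohort
#'
#' Emulates the conditional two-hit structure: a configurable fraction of
#' cases have a sole germline MSH2 missense variant (deleterious with
#' probability \code{frac_germline_deleterious}, drawn from the catalog by
#' tier); somatic MSH2 second hits arrive at tier-dependent rates and are
#' realized as P/LP point mutations, LOH events, or EPCAM structural
#' variants; MSI depends on whether a biallelic MSH2 explanation exists;
#' MLH1 promoter hypermethylation is injected among tumors lacking one;
#' somatic MSH2 missense variants (neutral or disruptive) drive the
#' somatic-coincidence structure. Truth labels are carried in
#' \code{germline$truth_tier}.
#'
#' @param config A [simulation_config()].
#' @param catalog Catalog from [gen_catalog()].
#' @return A [paired_cohort()].
#' @export
gen_paired_cohort <- function(config, catalog) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(sub_seed(config, "paired"))
  n <- config$n_paired
  ids <- sprintf("T%06d", seq_len(n))
  cat_t <- annotate_tiers(catalog)
  del_pool <- cat_t[cat_t$tier == "deleterious_protein", , drop = FALSE]
  neu_pool <- cat_t[cat_t$tier == "neutral", , drop = FALSE]
  if (nrow(del_pool) == 0L || nrow(neu_pool) == 0L) {
    stop("catalog lacks deleterious or neutral variants for the paired draw")
  }

  sole <- stats::rbinom(n, 1, config$frac_paired_sole_msh2_missense) == 1
  g_del <- sole & stats::rbinom(n, 1, config$frac_germline_deleterious) == 1

  pick_row <- function(pool, k) pool[sample.int(nrow(pool), k, replace = TRUE), ]
  gv <- rbind(
    if (any(g_del)) cbind(pick_row(del_pool, sum(g_del)),
                          individual_id = ids[g_del]),
    if (any(sole & !g_del)) cbind(pick_row(neu_pool, sum(sole & !g_del)),
                                  individual_id = ids[sole & !g_del])
  )
  germline <- if (is.null(gv)) {
    data.frame(individual_id = character(0), gene = character(0),
               hgvs_c = character(0), consequence = character(0),
               classification = character(0), lof_score = numeric(0),
               spliceai_deltamax = numeric(0), truth_tier = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      individual_id = gv$individual_id,
      gene = "MSH2", hgvs_c = gv$hgvs_c, consequence = "missense",
      classification = "VUS",
      lof_score = gv$lof_score, spliceai_deltamax = gv$spliceai_deltamax,
      truth_tier = gv$tier,
      stringsAsFactors = FALSE
    )
  }

  hit_rate <- ifelse(g_del, config$second_hit_rate_deleterious,
                     config$second_hit_rate_neutral)
  hit <- sole & stats::rbinom(n, 1, hit_rate) == 1
  hit_kind <- ifelse(stats::rbinom(n, 1, config$epcam_sv_rate) == 1, "epcam",
                     ifelse(stats::rbinom(n, 1,
                                          config$loh_fraction_of_hits) == 1,
                            "loh", "mutation"))
  epcam_sv <- hit & hit_kind == "epcam"

  som_mis <- stats::rbinom(n, 1, config$somatic_msh2_missense_rate) == 1
  som_mis_del <- som_mis &
    stats::rbinom(n, 1, config$frac_somatic_missense_deleterious) == 1

  explained <- (g_del & hit) | som_mis_del
  other_ls_rate <- ifelse(som_mis & !som_mis_del,
                          config$other_ls_somatic_given_unexplained,
                          ifelse(som_mis_del,
                                 config$other_ls_somatic_given_disruptive,
                                 ifelse(sole & !g_del & !hit, 0.3, 0.1)))
  other_ls <- stats::rbinom(n, 1, other_ls_rate) == 1
  other_ls_gene <- sample(c("MSH6", "MLH1", "PMS2"), n, replace = TRUE)

  meth_assayed <- stats::rbinom(n, 1, config$methylation_assayed_rate) == 1
  meth <- !explained & stats::rbinom(n, 1, config$mlh1_methylation_rate) == 1
  mlh1_meth <- ifelse(meth_assayed, meth, NA)

  mmrd <- explained | other_ls | meth
  msi_p <- ifelse(mmrd, config$msi_given_two_hits, config$msi_given_no_hit)
  unstable <- stats::rbinom(n, 1, msi_p) == 1
  msi_low <- stats::rbinom(n, 1, config$msi_low_fraction) == 1
  msi <- ifelse(unstable, ifelse(msi_low, "MSI_low", "MSI_high"), "MSS")
  msi[stats::rbinom(n, 1, config$msi_not_assayed_rate) == 1] <- "not_assayed"

  blank_som <- function(k) data.frame(
    individual_id = character(k), gene = character(k),
    event_type = character(k), hgvs_c = character(k),
    consequence = character(k), classification = character(k),
    lof_score = numeric(k), spliceai_deltamax = numeric(k),
    stringsAsFactors = FALSE)
  som_list <- list()
  i_mut <- which(hit & hit_kind == "mutation")
  if (length(i_mut)) {
    s <- blank_som(length(i_mut))
    s$individual_id <- ids[i_mut]; s$gene <- "MSH2"
    s$event_type <- "mutation"
    s$hgvs_c <- sprintf("c.%d_somhit", i_mut)
    s$consequence <- "truncating"
    s$classification <- sample(c("P", "LP"), length(i_mut), replace = TRUE)
    s$lof_score <- NA_real_; s$spliceai_deltamax <- NA_real_
    som_list$hit_mut <- s
  }
  i_loh <- which(hit & hit_kind == "loh")
  if (length(i_loh)) {
    s <- blank_som(length(i_loh))
    s$individual_id <- ids[i_loh]; s$gene <- "MSH2"
    s$event_type <- "loh"; s$hgvs_c <- NA_character_
    s$consequence <- "other"; s$classification <- "VUS"
    s$lof_score <- NA_real_; s$spliceai_deltamax <- NA_real_
    som_list$hit_loh <- s
  }
  i_sm <- which(som_mis)
  if (length(i_sm)) {
    from_del <- som_mis_del[i_sm]
    rows <- rbind(
      if (any(from_del)) pick_row(del_pool, sum(from_del)),
      if (any(!from_del)) pick_row(neu_pool, sum(!from_del))
    )
    s <- blank_som(length(i_sm))
    s$individual_id <- ids[c(i_sm[from_del], i_sm[!from_del])]
    s$gene <- "MSH2"; s$event_type <- "mutation"
    s$hgvs_c <- paste0(rows$hgvs_c, "_som")
    s$consequence <- "missense"; s$classification <- "VUS"
    s$lof_score <- rows$lof_score
    s$spliceai_deltamax <- rows$spliceai_deltamax
    som_list$som_mis <- s
  }
  i_ols <- which(other_ls)
  if (length(i_ols)) {
    s <- blank_som(length(i_ols))
    s$individual_id <- ids[i_ols]; s$gene <- other_ls_gene[i_ols]
    s$event_type <- "mutation"
    s$hgvs_c <- sprintf("c.%d_ols", i_ols)
    s$consequence <- "truncating"
    s$classification <- sample(c("P", "LP"), length(i_ols), replace = TRUE)
    s$lof_score <- NA_real_; s$spliceai_deltamax <- NA_real_
    som_list$other_ls <- s
  }
  somatic <- if (length(som_list)) do.call(rbind, som_list) else blank_som(0)
  rownames(somatic) <- NULL

  cases <- data.frame(
    individual_id = ids,
    msi_status = msi,
    mlh1_promoter_hypermethylated = mlh1_meth,
    epcam_structural_variant = epcam_sv,
    stringsAsFactors = FALSE
  )
  paired_cohort(cases, germline, somatic)
}

#' Generate the full synthetic study
#'
#' Runs all four sub-generators on one configuration.
#'
#' @param config A [simulation_config()].
#' @return List of class \code{"synthetic_cohort"}: \code{catalog},
#'   \code{controls}, \code{germline_cohort}, \code{paired_cohort},
#'   \code{config}.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  catalog <- gen_catalog(config)
  structure(list(catalog = catalog,
                 controls = gen_control_set(config, catalog),
                 germline_cohort = gen_germline_cohort(config, catalog),
                 paired_cohort = gen_paired_cohort(config, catalog),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort (seed %d): %d variants, %d controls, %d carriers, %d paired cases\n",
              x$config$seed, nrow(x$catalog), nrow(x$controls),
              nrow(x$germline_cohort), nrow(x$paired_cohort$cases)))
  invisible(x)
}
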