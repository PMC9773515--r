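# Functional-evidence assignment and cohort-level reclassification.

#' Functional evidence code for a tiered variant
#'
#' Applies the calibrated functional-evidence rules. A protein-deleterious
#' variant with LoF score at or above \code{ps3_strong_cutoff} (default 1.7,
#' the lowest score among the pathogenic validation variants) receives PS3
#' at strong; one with LoF between the deleterious cutoff and
#' \code{ps3_strong_cutoff} is PS3-moderate-eligible; a variant functionally
#' normal by both measures receives BS3 at strong. Splice-predicted and
#' intermediate variants receive no code from this pipeline: the underlying
#' assay is cDNA-based and blind to splicing, so splice predictions feed
#' computational evidence upstream, not PS3.
#'
#' @param tier Functional tier (see [assign_tier()]).
#' @param lof_score The variant's LoF score.
#' @param calibration An \code{"oddspath"} object; both directions must have
#'   reached at least strong evidence for PS3/BS3 use.
#' @param ps3_strong_cutoff LoF score needed for PS3 at full strength.
#' @return An [acmg_code()] or \code{NULL} when no functional code applies.
#' @export
functional_evidence_code <- function(tier, lof_score, calibration,
                                     ps3_strong_cutoff = 1.7) {
  check_calibration_strength(calibration)
  if (tier == "unscored") {
    warning("variant has no function score; no functional evidence applied")
    return(NULL)
  }
  if (tier == "deleterious_protein") {
    if (!is.na(lof_score) && lof_score >= ps3_strong_cutoff) {
      return(acmg_code("PS3", "strong"))
    }
    return(acmg_code("PS3", "moderate"))
  }
  if (tier == "neutral") return(acmg_code("BS3", "strong"))
  NULL
}

check_calibration_strength <- function(calibration) {
  if (!inherits(calibration, "oddspath")) {
    stop("calibration must be an oddspath object from compute_oddspath()")
  }
  ok <- function(st, dir) {
    !is.null(st) && st$direction == dir &&
      st$level %in% c("strong", "very_strong")
  }
  if (!ok(calibration$strength_abnormal, "pathogenic") ||
      !ok(calibration$strength_normal, "benign")) {
    stop("calibration has not established strong evidence in both score ",
         "directions; PS3/BS3 cannot be applied at strong")
  }
  invisible(TRUE)
}

#' Reclassify the standing VUS in a variant catalog
#'
#' For every variant of uncertain significance, computes the functional tier,
#' adds the applicable functional evidence code to the variant's existing
#' (non-functional) codes, and re-runs the point-based classification.
#' PS3 at full strength is added only for LoF scores at or above
#' \code{ps3_strong_cutoff}; variants in the abnormal range below that cutoff
#' are reported as PS3-moderate-eligible but, conservatively, not
#' reclassified unless \code{apply_ps3_moderate = TRUE} (they scored below
#' every control used to establish the calibration). BS3 is added for
#' variants functionally normal by both measures.
#'
#' @param catalog Variant catalog data frame with \code{classification} and
#'   an \code{evidence_codes} column of comma-separated tokens (empty for
#'   none); see [parse_codes()].
#' @param calibration An \code{"oddspath"} object with strong evidence both
#'   ways.
#' @param cutoffs A [tier_cutoffs()] list.
#' @param ps3_strong_cutoff LoF score needed for PS3 at full strength.
#' @param apply_ps3_moderate Apply PS3 at moderate for the eligible band.
#' @return Object of class \code{"reclassification"}: summary counts, the
#'   remaining-VUS split, and a per-variant \code{audit} data frame with the
#'   codes before/after, points and classes. Categories partition the
#'   catalog: previously classified + newly P/LP + newly B/LB + remaining
#'   VUS equals the catalog size.
#' @export
reclassify_catalog <- function(catalog, calibration, cutoffs = tier_cutoffs(),
                               ps3_strong_cutoff = 1.7,
                               apply_ps3_moderate = FALSE) {
  check_calibration_strength(calibration)
  if (is.null(catalog$classification) || anyNA(catalog$classification)) {
    stop("every variant must carry a prior classification")
  }
  if (is.null(catalog$evidence_codes)) catalog$evidence_codes <- ""
  if (is.null(catalog$tier)) catalog <- annotate_tiers(catalog, cutoffs)

  is_vus <- catalog$classification == "VUS"
  vus <- catalog[is_vus, , drop = FALSE]
  n_prev <- sum(!is_vus)

  nv <- nrow(vus)
  audit <- data.frame(
    hgvs_c = vus$hgvs_c,
    old_class = vus$classification,
    tier = vus$tier,
    lof_score = vus$lof_score,
    codes_before = ifelse(is.na(vus$evidence_codes), "", vus$evidence_codes),
    code_added = rep("", nv),
    ps3_moderate_eligible = rep(FALSE, nv),
    points = rep(NA_integer_, nv),
    new_class = rep(NA_character_, nv),
    stringsAsFactors = FALSE
  )

  for (i in seq_len(nrow(vus))) {
    tier <- vus$tier[i]
    lof <- vus$lof_score[i]
    added <- NULL
    if (tier == "deleterious_protein") {
      if (!is.na(lof) && lof >= ps3_strong_cutoff) {
        added <- acmg_code("PS3", "strong")
      } else {
        audit$ps3_moderate_eligible[i] <- TRUE
        if (apply_ps3_moderate) added <- acmg_code("PS3", "moderate")
      }
    } else if (tier == "neutral") {
      added <- acmg_code("BS3", "strong")
    }
    codes <- parse_codes(audit$codes_before[i])
    if (!is.null(added)) {
      codes <- c(codes, list(added))
      audit$code_added[i] <- format_code(added)
    }
    cls <- classify_variant(codes)
    audit$points[i] <- cls$points
    audit$new_class[i] <- cls$category
  }

  newly_plp <- sum(audit$new_class %in% c("P", "LP"))
  newly_blb <- sum(audit$new_class %in% c("B", "LB"))
  remaining <- audit$new_class == "VUS"
  split <- c(
    intermediate_score = sum(remaining & audit$tier == "intermediate"),
    abnormal_insufficient = sum(remaining & audit$tier %in%
                                  c("deleterious_protein", "deleterious_splice")),
    normal_insufficient = sum(remaining & audit$tier == "neutral"),
    unscored = sum(remaining & audit$tier == "unscored")
  )

  res <- list(
    n_catalog = nrow(catalog),
    n_previously_classified = n_prev,
    n_vus = nrow(vus),
    newly_plp = newly_plp,
    newly_blb = newly_blb,
    remaining_vus = sum(remaining),
    remaining_split = split,
    n_ps3_strong = sum(audit$code_added == "PS3"),
    n_bs3 = sum(audit$code_added == "BS3"),
    n_ps3_moderate_eligible = sum(audit$ps3_moderate_eligible),
    audit = audit
  )
  class(res) <- "reclassification"
  stopifnot(res$n_previously_classified + res$newly_plp + res$newly_blb +
              res$remaining_vus == res$n_catalog)
  res
}

#' @export
print.reclassification <- function(x, ...) {
  cat("Catalog reclassification\n")
  cat(sprintf("  %d variants: %d previously classified, %d VUS\n",
              x$n_catalog, x$n_previously_classified, x$n_vus))
  cat(sprintf("  functional codes added: %d PS3 (strong), %d BS3; %d PS3-moderate-eligible\n",
              x$n_ps3_strong, x$n_bs3, x$n_ps3_moderate_eligible))
  cat(sprintf("  newly P/LP: %d; newly B/LB: %d; remaining VUS: %d\n",
              x$newly_plp, x$newly_blb, x$remaining_vus))
  cat("  remaining VUS split:",
      paste(names(x$remaining_split), x$remaining_split, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Depletion of functionally abnormal variants among observed VUS
#'
#' Two-sided exact binomial test of the abnormal count among observed
#' variants against the abnormal rate in a reference set of unobserved
#' variants (patient-ascertained variant pools are expected to be depleted
#' of deleterious alleles, since those accrue evidence and leave the VUS
#' pool).
#'
#' @param n_abnormal_obs Abnormal variants among those observed.
#' @param n_obs Observed variants.
#' @param n_abnormal_ref,n_ref Abnormal and total counts in the reference
#'   set, defining the null rate \code{p0 = n_abnormal_ref / n_ref}.
#' @param method Two-sidedness convention, see [binomial_two_sided()].
#' @return The two-sided p-value.
#' @examples
#' depletion_test(34, 682, 351, 5130)
#' @export
depletion_test <- function(n_abnormal_obs, n_obs, n_abnormal_ref, n_ref,
                           method = "minlike") {
  if (n_ref <= 0) stop("n_ref must be positive")
  p0 <- n_abnormal_ref / n_ref
  if (p0 <= 0 || p0 >= 1) stop("reference abnormal rate must lie in (0, 1)")
  binomial_two_sided(n_abnormal_obs, n_obs, p0, method = method)
}
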