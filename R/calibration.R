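# OddsPath calibration of functional evidence against curated controls.

#' Curate functional-evidence-free control variants
#'
#' Keeps only previously classified variants whose clinical interpretation
#' was reached without any prior functional evidence (e.g. using population
#' frequency, family history, or tumor characteristics alone). Using such
#' controls avoids the circularity of validating one functional assay with
#' classifications that leaned on another, mechanistically similar assay.
#'
#' @param controls Data frame of classified variants with a logical column
#'   \code{uses_functional_evidence}; classifications must be P/LP or B/LB,
#'   never VUS.
#' @return The retained controls, with attribute \code{counts} giving the
#'   P/LP and B/LB tallies. Errors if no usable control remains.
#' @export
curate_controls <- function(controls) {
  if (is.null(controls$uses_functional_evidence)) {
    stop("controls must carry a logical uses_functional_evidence column")
  }
  bad <- which(!controls$classification %in% c("P", "LP", "B", "LB"))
  if (length(bad)) {
    stop("control variants must be classified P/LP or B/LB; offending row ",
         bad[1])
  }
  keep <- controls[!controls$uses_functional_evidence, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no usable controls")
  attr(keep, "counts") <- c(
    p_lp = sum(keep$classification %in% c("P", "LP")),
    b_lb = sum(keep$classification %in% c("B", "LB"))
  )
  keep
}

#' OddsPath: odds of pathogenicity implied by a functional assay
#'
#' Quantifies the strength of evidence a functional score provides, per
#' score direction, from a curated control set. The prior \eqn{P_1} is the
#' proportion of pathogenic variants among all scored controls (variants
#' with intermediate scores stay in the prior). For each direction the
#' posterior \eqn{P_2} is the proportion pathogenic among controls whose
#' tier falls in that direction (abnormal = protein- or splice-deleterious;
#' normal = neutral; intermediates enter neither posterior). When a
#' direction's discordant cell is zero, the posterior is recomputed as if
#' one additional inconsistent variant were present (denominator + 1,
#' discordant cell = 1) and the correction is flagged. Then
#' \deqn{OddsPath = P_2 (1 - P_1) / ((1 - P_2) P_1).}
#'
#' @param controls Curated control data frame (see [curate_controls()]) with
#'   score columns, or a precomputed \code{tier} column.
#' @param cutoffs A [tier_cutoffs()] list, used when tiers must be computed.
#' @return An object of class \code{"oddspath"}: all counts, the prior and
#'   posteriors, the OddsPath per direction, correction flags, and the
#'   mapped evidence strengths.
#' @examples
#' ctl <- data.frame(
#'   classification = rep(c("P", "B"), c(4, 4)),
#'   tier = c(rep("deleterious_protein", 4), rep("neutral", 4))
#' )
#' compute_oddspath(ctl)
#' @export
compute_oddspath <- function(controls, cutoffs = tier_cutoffs()) {
  if (is.null(controls$tier)) controls <- annotate_tiers(controls, cutoffs)
  unscored <- controls$tier == "unscored"
  if (any(unscored)) {
    warning(sum(unscored), " unscored control(s) excluded from calibration")
    controls <- controls[!unscored, , drop = FALSE]
  }
  is_path <- controls$classification %in% c("P", "LP")
  is_benign <- controls$classification %in% c("B", "LB")
  if (!any(is_path) || !any(is_benign)) {
    stop("calibration needs at least one pathogenic and one benign control")
  }
  abnormal <- controls$tier %in% c("deleterious_protein", "deleterious_splice")
  normal <- controls$tier == "neutral"
  inter <- controls$tier == "intermediate"

  n_path <- sum(is_path); n_benign <- sum(is_benign)
  p1 <- n_path / (n_path + n_benign)

  posterior <- function(n_concordant, n_discordant) {
    # n_concordant: pathogenic count in the cell; n_discordant: benign count
    # (for the abnormal direction) or vice versa handled by the caller.
    n <- n_concordant + n_discordant
    if (n == 0L) return(list(p2 = NA_real_, corrected = FALSE))
    if (n_discordant == 0L) {
      list(p2 = n_concordant / (n + 1), corrected = TRUE)
    } else {
      list(p2 = n_concordant / n, corrected = FALSE)
    }
  }
  oddspath <- function(p2) p2 * (1 - p1) / ((1 - p2) * p1)

  ab <- posterior(sum(is_path & abnormal), sum(is_benign & abnormal))
  # Normal direction: the proportion pathogenic among neutral-scoring
  # controls; the discordant cell is the pathogenic one.
  n_path_normal <- sum(is_path & normal)
  n_benign_normal <- sum(is_benign & normal)
  if (n_path_normal + n_benign_normal == 0L) {
    nm <- list(p2 = NA_real_, corrected = FALSE)
  } else if (n_path_normal == 0L) {
    nm <- list(p2 = 1 / (n_benign_normal + 1), corrected = TRUE)
  } else {
    nm <- list(p2 = n_path_normal / (n_path_normal + n_benign_normal),
               corrected = FALSE)
  }
  if (is.na(ab$p2)) warning("no control scored in the abnormal direction")
  if (is.na(nm$p2)) warning("no control scored in the normal direction")

  op_ab <- if (is.na(ab$p2)) NA_real_ else oddspath(ab$p2)
  op_nm <- if (is.na(nm$p2)) NA_real_ else oddspath(nm$p2)

  res <- list(
    n_path = n_path, n_benign = n_benign,
    n_path_abnormal = sum(is_path & abnormal),
    n_benign_abnormal = sum(is_benign & abnormal),
    n_path_normal = n_path_normal, n_benign_normal = n_benign_normal,
    n_intermediate = sum(inter),
    p1 = p1, p2_abnormal = ab$p2, p2_normal = nm$p2,
    oddspath_abnormal = op_ab, oddspath_normal = op_nm,
    correction_applied_abnormal = ab$corrected,
    correction_applied_normal = nm$corrected,
    strength_abnormal = if (is.na(op_ab)) NULL else map_strength(op_ab),
    strength_normal = if (is.na(op_nm)) NULL else map_strength(op_nm)
  )
  class(res) <- "oddspath"
  res
}

#' @export
print.oddspath <- function(x, ...) {
  cat("OddsPath calibration\n")
  cat(sprintf("  controls: %d P/LP, %d B/LB (prior P1 = %.4f), %d intermediate\n",
              x$n_path, x$n_benign, x$p1, x$n_intermediate))
  fmt <- function(op, p2, corr, st) {
    if (is.na(op)) return("not estimable (no scored controls)")
    sprintf("%.4g (P2 = %.4f%s) -> %s %s", op, p2,
            if (corr) ", +1-inconsistent correction" else "",
            st$direction, st$level)
  }
  cat("  abnormal scores:", fmt(x$oddspath_abnormal, x$p2_abnormal,
                                x$correction_applied_abnormal,
                                x$strength_abnormal), "\n")
  cat("  normal scores:  ", fmt(x$oddspath_normal, x$p2_normal,
                                x$correction_applied_normal,
                                x$strength_normal), "\n")
  invisible(x)
}

#' Map an OddsPath value to an ACMG evidence strength
#'
#' Step thresholds on the pathogenic side: 2.08 supporting, 4.33 moderate,
#' 18.7 strong, 350 very strong; the benign side uses the reciprocal bounds.
#' Values between 1/2.08 and 2.08 are indeterminate and carry no evidence.
#' The mapping is monotone and mirror-symmetric: the strength of \code{x}
#' toward pathogenic equals the strength of \code{1/x} toward benign.
#'
#' @param oddspath Positive odds of pathogenicity.
#' @param thresholds Named increasing vector of pathogenic-side bounds.
#' @return List with \code{direction} (pathogenic / benign / indeterminate)
#'   and \code{level} (supporting / moderate / strong / very_strong / none),
#'   of class \code{"evidence_strength"}.
#' @export
map_strength <- function(oddspath,
                         thresholds = c(supporting = 2.08, moderate = 4.33,
                                        strong = 18.7, very_strong = 350)) {
  if (length(oddspath) != 1L || is.na(oddspath) || oddspath <= 0) {
    stop("oddspath must be a single positive number")
  }
  stopifnot(!is.unsorted(thresholds))
  level_for <- function(v) {
    hit <- which(v >= thresholds)
    if (length(hit)) names(thresholds)[max(hit)] else "none"
  }
  if (oddspath >= thresholds[["supporting"]]) {
    out <- list(direction = "pathogenic", level = level_for(oddspath))
  } else if (oddspath <= 1 / thresholds[["supporting"]]) {
    out <- list(direction = "benign", level = level_for(1 / oddspath))
  } else {
    out <- list(direction = "indeterminate", level = "none")
  }
  class(out) <- "evidence_strength"
  out
}

#' @export
print.evidence_strength <- function(x, ...) {
  cat("evidence strength:", x$direction, x$level, "\n")
  invisible(x)
}

#' Recall of known pathogenic variants by the function scores
#'
#' Among variants already classified P/LP, the fraction whose functional tier
#' is deleterious (protein or splice mechanism). Splice-predicted variants
#' count as true positives even though downstream PS3 assignment is
#' protein-score-driven.
#'
#' @param known_plp Data frame of P/LP variants with score columns or a
#'   \code{tier} column.
#' @param cutoffs A [tier_cutoffs()] list.
#' @return List with \code{recall}, counts \code{n}, \code{n_deleterious},
#'   and the protein/splice \code{split}.
#' @export
validation_recall <- function(known_plp, cutoffs = tier_cutoffs()) {
  if (nrow(known_plp) == 0L) stop("empty validation set")
  if (!all(known_plp$classification %in% c("P", "LP"))) {
    stop("validation set must contain only P/LP variants")
  }
  if (is.null(known_plp$tier)) known_plp <- annotate_tiers(known_plp, cutoffs)
  n_protein <- sum(known_plp$tier == "deleterious_protein")
  n_splice <- sum(known_plp$tier == "deleterious_splice")
  list(recall = (n_protein + n_splice) / nrow(known_plp),
       n = nrow(known_plp), n_deleterious = n_protein + n_splice,
       split = c(protein = n_protein, splice = n_splice))
}
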