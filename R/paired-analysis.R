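# Joint germline-somatic two-hit analyses.

#' Select cases whose sole germline finding is one MSH2 missense variant
#'
#' Keeps individuals with exactly one germline finding among the Lynch
#' syndrome genes, that finding being an MSH2 missense variant. The
#' selection is deterministic, idempotent and order-invariant.
#'
#' @param pc A [paired_cohort()].
#' @return The selected sub-cohort (class \code{"paired_cohort"}).
#' @export
select_sole_msh2_missense_cases <- function(pc) {
  stopifnot(inherits(pc, "paired_cohort"))
  g <- pc$germline[pc$germline$gene %in% LS_GENES, , drop = FALSE]
  if (nrow(g) == 0L) return(subset_paired_cohort(pc, character(0)))
  counts <- table(g$individual_id)
  sole <- names(counts)[counts == 1]
  keep <- g$individual_id %in% sole & g$gene == "MSH2" &
    g$consequence == "missense"
  subset_paired_cohort(pc, g$individual_id[keep])
}

germline_tier_by_case <- function(pc, cutoffs) {
  g <- pc$germline
  data.frame(individual_id = g$individual_id,
             tier = assign_tier(g$lof_score, g$spliceai_deltamax, cutoffs),
             stringsAsFactors = FALSE)
}

paired_test <- function(tab, p, excluded, what) {
  structure(list(table = tab, p_value = p, excluded = excluded, what = what),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(x$what, "\n")
  print(x$table)
  cat(sprintf("two-sided Fisher's exact p = %.3g", x$p_value))
  if (length(x$excluded) && sum(unlist(x$excluded)) > 0) {
    cat("  (excluded:", paste(names(x$excluded), unlist(x$excluded),
                              sep = "=", collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' Somatic second-hit enrichment by germline functional tier
#'
#' Under the two-hit model, individuals who inherited a functionally
#' deleterious first hit should more often show a pathogenic somatic second
#' hit in the same gene. A second hit is any somatic MSH2 P/LP mutation, a
#' somatic MSH2 LOH event (included by default, configurable), or an EPCAM
#' structural variant (which silences MSH2). Cases with intermediate or
#' unscored germline tiers are excluded and their count reported.
#'
#' @param pc A sole-MSH2-missense sub-cohort from
#'   [select_sole_msh2_missense_cases()].
#' @param include_loh Count somatic MSH2 LOH as a second hit.
#' @param cutoffs A [tier_cutoffs()] list.
#' @return A \code{"paired_test"}: 2x2 table (rows deleterious/neutral
#'   germline tier, columns second hit yes/no) and the two-sided Fisher p.
#' @export
second_hit_analysis <- function(pc, include_loh = TRUE,
                                cutoffs = tier_cutoffs()) {
  tiers <- germline_tier_by_case(pc, cutoffs)
  som <- pc$somatic
  hit_mut <- som$gene == "MSH2" & som$event_type == "mutation" &
    som$classification %in% c("P", "LP")
  hit_loh <- include_loh & som$gene == "MSH2" & som$event_type == "loh"
  hit_ids <- unique(som$individual_id[hit_mut | hit_loh])
  epcam <- pc$cases$individual_id[pc$cases$epcam_structural_variant %in% TRUE]
  hit_ids <- union(hit_ids, epcam)

  grp <- ifelse(tiers$tier %in% c("deleterious_protein", "deleterious_splice"),
                "deleterious",
                ifelse(tiers$tier == "neutral", "neutral", NA))
  excluded <- c(not_scored_or_intermediate = sum(is.na(grp)))
  use <- !is.na(grp)
  hit <- tiers$individual_id %in% hit_ids
  tab <- matrix(c(sum(grp == "deleterious" & hit, na.rm = TRUE),
                  sum(grp == "deleterious" & !hit & use),
                  sum(grp == "neutral" & hit, na.rm = TRUE),
                  sum(grp == "neutral" & !hit & use)),
                nrow = 2, byrow = TRUE,
                dimnames = list(germline = c("deleterious", "neutral"),
                                second_hit = c("yes", "no")))
  paired_test(tab, fisher_two_sided(tab), as.list(excluded),
              "Somatic second hit in MSH2 by germline functional tier")
}

#' Tumor microsatellite instability by germline functional tier
#'
#' Cross-tabulates MSI status (MSI-high or MSI-low = unstable, vs MSS)
#' against the germline tier, after excluding individuals whose tumors carry
#' MLH1 promoter hypermethylation -- an independent somatic epigenetic
#' mechanism sufficient to cause MMR deficiency and MSI regardless of MSH2
#' status. Cases whose MSI was not assayed are excluded with a logged count.
#'
#' @inheritParams second_hit_analysis
#' @return A \code{"paired_test"} with the 2x2 table and Fisher p.
#' @export
msi_analysis <- function(pc, cutoffs = tier_cutoffs()) {
  tiers <- germline_tier_by_case(pc, cutoffs)
  cases <- pc$cases
  meth <- cases$individual_id[cases$mlh1_promoter_hypermethylated %in% TRUE]
  not_assayed <- cases$individual_id[cases$msi_status == "not_assayed"]
  excluded <- list(mlh1_hypermethylated = length(intersect(tiers$individual_id, meth)),
                   msi_not_assayed = length(setdiff(
                     intersect(tiers$individual_id, not_assayed), meth)))
  drop <- union(meth, not_assayed)
  tiers <- tiers[!tiers$individual_id %in% drop, , drop = FALSE]
  grp <- ifelse(tiers$tier %in% c("deleterious_protein", "deleterious_splice"),
                "deleterious",
                ifelse(tiers$tier == "neutral", "neutral", NA))
  excluded$not_scored_or_intermediate <- sum(is.na(grp))
  tiers <- tiers[!is.na(grp), , drop = FALSE]
  grp <- grp[!is.na(grp)]
  if (nrow(tiers) == 0L) stop("no evaluable cases")
  msi <- cases$msi_status[match(tiers$individual_id, cases$individual_id)]
  unstable <- msi %in% c("MSI_high", "MSI_low")
  tab <- matrix(c(sum(grp == "deleterious" & unstable),
                  sum(grp == "deleterious" & !unstable),
                  sum(grp == "neutral" & unstable),
                  sum(grp == "neutral" & !unstable)),
                nrow = 2, byrow = TRUE,
                dimnames = list(germline = c("deleterious", "neutral"),
                                msi = c("unstable", "MSS")))
  paired_test(tab, fisher_two_sided(tab), excluded,
              "Tumor MSI by germline functional tier (MLH1-methylated excluded)")
}

#' Somatic-coincidence analysis among tumors with somatic MSH2 missense
#'
#' Groups individuals carrying at least one somatic MSH2 missense variant
#' into those with a functionally disruptive one versus those whose somatic
#' MSH2 missense variants are exclusively neutral (and who carry no other
#' somatic MSH2 P/LP mutation -- in such tumors the MMR deficiency must be
#' explained elsewhere). Two contingency tests follow: (A) somatic
#' mutations in the other Lynch genes (MSH6, MLH1, PMS2) by group; (B)
#' MLH1 promoter hypermethylation by group, restricted to cases in which
#' MLH1 methylation was assayed. Also flags sporadic (Lynch-like)
#' candidates: two or more somatic MSH2 hits, at least one functionally
#' deleterious, with no deleterious germline variant.
#'
#' @param pc A [paired_cohort()] (the full cohort, not a subset).
#' @param cutoffs A [tier_cutoffs()] list.
#' @return List of class \code{"somatic_coincidence"}: group sizes, the two
#'   \code{"paired_test"} results (\code{other_ls}, \code{methylation}),
#'   and \code{sporadic_candidates}. When no tumor carries a somatic MSH2
#'   missense variant the result is empty (\code{n_total = 0}).
#' @export
somatic_coincidence_analysis <- function(pc, cutoffs = tier_cutoffs()) {
  som <- pc$somatic
  mis <- som$gene == "MSH2" & som$event_type == "mutation" &
    som$consequence == "missense"
  if (!any(mis)) {
    return(structure(list(n_total = 0L, n_disruptive = 0L, n_neutral = 0L,
                          other_ls = NULL, methylation = NULL,
                          sporadic_candidates = character(0)),
                     class = "somatic_coincidence"))
  }
  mtier <- assign_tier(som$lof_score[mis], som$spliceai_deltamax[mis], cutoffs)
  mis_ids <- som$individual_id[mis]
  deleterious <- mtier %in% c("deleterious_protein", "deleterious_splice")
  ids <- unique(mis_ids)
  has_disruptive <- ids %in% mis_ids[deleterious]
  all_neutral <- vapply(ids, function(id) {
    all(mtier[mis_ids == id] == "neutral")
  }, logical(1))
  # other somatic MSH2 P/LP mutations, beyond the neutral missense themselves
  other_plp <- som$gene == "MSH2" & som$event_type == "mutation" &
    som$classification %in% c("P", "LP") & !mis
  neutral_grp <- all_neutral & !ids %in% som$individual_id[other_plp]
  group <- ifelse(has_disruptive, "disruptive",
                  ifelse(neutral_grp, "neutral", NA))
  keep <- !is.na(group)
  ids <- ids[keep]; group <- group[keep]

  other_ls_ids <- unique(som$individual_id[som$gene %in%
                                             c("MSH6", "MLH1", "PMS2") &
                                             som$event_type == "mutation"])
  other <- ids %in% other_ls_ids
  tab_a <- matrix(c(sum(group == "neutral" & other),
                    sum(group == "neutral" & !other),
                    sum(group == "disruptive" & other),
                    sum(group == "disruptive" & !other)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(group = c("neutral", "disruptive"),
                                  other_ls_somatic = c("yes", "no")))
  test_a <- paired_test(tab_a, fisher_two_sided(tab_a), list(),
                        "Somatic mutation in another LS gene by MSH2 somatic missense group")

  meth <- pc$cases$mlh1_promoter_hypermethylated[
    match(ids, pc$cases$individual_id)]
  assayed <- !is.na(meth)
  tab_b <- matrix(c(sum(group == "neutral" & assayed & meth),
                    sum(group == "neutral" & assayed & !meth),
                    sum(group == "disruptive" & assayed & meth),
                    sum(group == "disruptive" & assayed & !meth)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(group = c("neutral", "disruptive"),
                                  mlh1_methylated = c("yes", "no")))
  test_b <- paired_test(tab_b, fisher_two_sided(tab_b),
                        list(methylation_not_assayed = sum(!assayed)),
                        "MLH1 promoter hypermethylation by MSH2 somatic missense group")

  # sporadic Lynch-like candidates
  msh2_hits <- som$gene == "MSH2" &
    (som$event_type == "loh" |
       (som$event_type == "mutation" &
          (som$classification %in% c("P", "LP") |
             assign_tier(som$lof_score, som$spliceai_deltamax, cutoffs) %in%
               c("deleterious_protein", "deleterious_splice"))))
  hit_counts <- table(som$individual_id[msh2_hits])
  del_som_ids <- unique(c(mis_ids[deleterious],
                          som$individual_id[som$gene == "MSH2" &
                                              som$event_type == "mutation" &
                                              som$classification %in% c("P", "LP")]))
  g <- pc$germline
  g_del <- unique(g$individual_id[
    assign_tier(g$lof_score, g$spliceai_deltamax, cutoffs) %in%
      c("deleterious_protein", "deleterious_splice") |
      g$classification %in% c("P", "LP")])
  sporadic <- names(hit_counts)[hit_counts >= 2]
  sporadic <- sporadic[sporadic %in% del_som_ids & !sporadic %in% g_del]

  structure(list(n_total = length(ids) + sum(!keep),
                 n_disruptive = sum(group == "disruptive"),
                 n_neutral = sum(group == "neutral"),
                 other_ls = test_a, methylation = test_b,
                 sporadic_candidates = sporadic),
            class = "somatic_coincidence")
}

#' @export
print.somatic_coincidence <- function(x, ...) {
  cat(sprintf("somatic MSH2 missense carriers: %d disruptive, %d neutral-only\n",
              x$n_disruptive, x$n_neutral))
  if (!is.null(x$other_ls)) { print(x$other_ls); print(x$methylation) }
  cat(sprintf("sporadic (Lynch-like) candidates: %d\n",
              length(x$sporadic_candidates)))
  invisible(x)
}
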