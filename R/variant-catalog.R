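# Domain constants shared across the package.

#' Lynch syndrome mismatch-repair genes
#'
#' The four mismatch-repair genes whose germline inactivation causes Lynch
#' syndrome. \code{EPCAM} is accepted in catalogs and tumor tables because
#' structural variants in its 3' end silence the downstream \code{MSH2} copy.
#'
#' @format Character vectors.
#' @name gene-sets
NULL

#' @rdname gene-sets
#' @export
LS_GENES <- c("MSH2", "MLH1", "MSH6", "PMS2")

#' @rdname gene-sets
#' @export
CATALOG_GENES <- c(LS_GENES, "EPCAM")

#' Five-tier clinical classification labels, benign to pathogenic
#' @export
CLINICAL_CLASSES <- c("B", "LB", "VUS", "LP", "P")

#' Functional tier labels
#' @export
FUNCTION_TIERS <- c("deleterious_protein", "deleterious_splice",
                    "intermediate", "neutral", "unscored")

CONSEQUENCES <- c("missense", "truncating", "other")

#' Functional tier score cutoffs
#'
#' Cutoffs that band a variant's two function scores. The loss-of-function
#' (LoF) score comes from a deep mutational scan of MSH2 protein function
#' (unitless enrichment scale, higher = more damaging); the deltaMax score is
#' a splice-disruption probability in [0, 1] from a sequence-based predictor.
#' Defaults: LoF >= 0.4 or deltaMax >= 0.5 is deleterious; LoF in [0, 0.4) or
#' deltaMax in [0.2, 0.5) is intermediate; LoF < 0 and deltaMax < 0.2 is
#' functionally neutral. Thresholds are inclusive on the deleterious side, so
#' LoF exactly 0 bands intermediate.
#'
#' @param lof_deleterious LoF score at or above which protein function is
#'   called deleterious.
#' @param lof_neutral LoF score below which (splice permitting) the variant is
#'   protein-neutral.
#' @param splice_deleterious deltaMax at or above which the variant is called
#'   splice-disruptive.
#' @param splice_neutral deltaMax below which the variant is splice-neutral.
#' @return A named list of the four cutoffs.
#' @export
tier_cutoffs <- function(lof_deleterious = 0.4, lof_neutral = 0,
                         splice_deleterious = 0.5, splice_neutral = 0.2) {
  stopifnot(lof_neutral <= lof_deleterious,
            splice_neutral <= splice_deleterious)
  list(lof_deleterious = lof_deleterious, lof_neutral = lof_neutral,
       splice_deleterious = splice_deleterious, splice_neutral = splice_neutral)
}

#' Assign a functional tier from the two function scores
#'
#' Bands each variant by its deep-mutational-scan LoF score and SpliceAI
#' deltaMax score. Splice attribution takes precedence: deltaMax at or above
#' the splice cutoff gives \code{deleterious_splice} regardless of the LoF
#' score; otherwise an LoF score at or above its cutoff gives
#' \code{deleterious_protein}; otherwise if either score falls in its
#' intermediate band the tier is \code{intermediate} (the more severe of two
#' conflicting bands wins -- a variant is only called neutral when both
#' measures are normal); otherwise \code{neutral}. A variant with neither
#' score is \code{unscored}.
#'
#' @param lof_score Numeric vector of LoF scores; \code{NA} = not scored.
#' @param spliceai_deltamax Numeric vector in [0, 1]; \code{NA} = not scored.
#' @param cutoffs A [tier_cutoffs()] list.
#' @return Character vector of tiers (see \code{FUNCTION_TIERS}).
#' @examples
#' assign_tier(c(4.511, -0.5, 0.2, -0.5), c(0.01, 0.05, 0.1, 0.9))
#' @export
assign_tier <- function(lof_score, spliceai_deltamax = NA_real_,
                        cutoffs = tier_cutoffs()) {
  n <- max(length(lof_score), length(spliceai_deltamax))
  lof <- rep_len(as.numeric(lof_score), n)
  dm <- rep_len(as.numeric(spliceai_deltamax), n)
  bad <- which(!is.na(dm) & (dm < 0 | dm > 1))
  if (length(bad)) {
    stop("spliceai_deltamax outside [0, 1] at position ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  tier <- rep("unscored", n)
  scored <- !is.na(lof) | !is.na(dm)
  splice_del <- !is.na(dm) & dm >= cutoffs$splice_deleterious
  prot_del <- !splice_del & !is.na(lof) & lof >= cutoffs$lof_deleterious
  inter <- !splice_del & !prot_del &
    ((!is.na(lof) & lof >= cutoffs$lof_neutral & lof < cutoffs$lof_deleterious) |
     (!is.na(dm) & dm >= cutoffs$splice_neutral & dm < cutoffs$splice_deleterious))
  tier[scored] <- "neutral"
  tier[inter] <- "intermediate"
  tier[prot_del] <- "deleterious_protein"
  tier[splice_del] <- "deleterious_splice"
  tier
}

#' Mechanism attributed to a functional tier
#'
#' @param tier Character vector of tiers.
#' @return \code{"splice"} for \code{deleterious_splice}, \code{"protein"} for
#'   \code{deleterious_protein}, \code{"none"} otherwise.
#' @export
tier_mechanism <- function(tier) {
  out <- rep("none", length(tier))
  out[tier == "deleterious_splice"] <- "splice"
  out[tier == "deleterious_protein"] <- "protein"
  out
}

#' Annotate a variant catalog with tiers and mechanisms
#'
#' @param catalog Variant catalog data frame (see [read_variant_table()]).
#' @param cutoffs A [tier_cutoffs()] list.
#' @return The catalog with \code{tier} and \code{mechanism} columns added.
#' @export
annotate_tiers <- function(catalog, cutoffs = tier_cutoffs()) {
  catalog$tier <- assign_tier(catalog$lof_score, catalog$spliceai_deltamax,
                              cutoffs)
  catalog$mechanism <- tier_mechanism(catalog$tier)
  catalog
}

#' Cross-tabulate functional tiers by attributed mechanism
#'
#' Each variant is counted exactly once; splice-disruptive variants are
#' counted under the splice mechanism before the protein score is considered
#' (the splice-first precedence of [assign_tier()]). Counts always sum to the
#' catalog size.
#'
#' @param catalog Variant catalog data frame; tiers are computed from the
#'   score columns unless a \code{tier} column is already present.
#' @param cutoffs A [tier_cutoffs()] list.
#' @return A contingency \code{table} of tier (rows) by mechanism (columns),
#'   with all levels present even when empty.
#' @export
count_by_mechanism <- function(catalog, cutoffs = tier_cutoffs()) {
  if (is.null(catalog$tier)) catalog <- annotate_tiers(catalog, cutoffs)
  tier <- factor(catalog$tier, levels = FUNCTION_TIERS)
  mech <- factor(tier_mechanism(as.character(tier)),
                 levels = c("protein", "splice", "none"))
  table(tier = tier, mechanism = mech)
}

# -- catalog validation and TSV I/O ------------------------------------------

CATALOG_COLUMNS <- c("gene", "hgvs_c", "hgvs_p", "consequence",
                     "classification", "lof_score", "spliceai_deltamax",
                     "gnomad_af")

validate_catalog <- function(catalog, context = "variant table") {
  missing_cols <- setdiff(CATALOG_COLUMNS, names(catalog))
  if (length(missing_cols)) {
    stop(context, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  fail <- function(rows, what) {
    stop(context, ": ", what, " at row ",
         paste(utils::head(rows, 5L), collapse = ", "))
  }
  bad <- which(!catalog$gene %in% CATALOG_GENES)
  if (length(bad)) fail(bad, paste0("unknown gene symbol (",
                                    catalog$gene[bad[1]], ")"))
  bad <- which(is.na(catalog$hgvs_c) | !nzchar(catalog$hgvs_c))
  if (length(bad)) fail(bad, "empty hgvs_c")
  dup <- which(duplicated(catalog$hgvs_c))
  if (length(dup)) fail(dup, paste0("duplicate hgvs_c (",
                                    catalog$hgvs_c[dup[1]], ")"))
  bad <- which(!catalog$consequence %in% CONSEQUENCES)
  if (length(bad)) fail(bad, "unknown consequence")
  bad <- which(!catalog$classification %in% CLINICAL_CLASSES)
  if (length(bad)) fail(bad, "unknown classification")
  dm <- catalog$spliceai_deltamax
  bad <- which(!is.na(dm) & (dm < 0 | dm > 1))
  if (length(bad)) fail(bad, "spliceai_deltamax outside [0, 1]")
  af <- catalog$gnomad_af
  bad <- which(!is.na(af) & (af < 0 | af > 1))
  if (length(bad)) fail(bad, "gnomad_af outside [0, 1]")
  invisible(catalog)
}

#' Read or write a variant catalog TSV
#'
#' The catalog is a UTF-8 tab-separated file with header columns \code{gene},
#' \code{hgvs_c}, \code{hgvs_p}, \code{consequence}, \code{classification},
#' \code{lof_score}, \code{spliceai_deltamax}, \code{gnomad_af}; extra
#' columns (e.g. \code{evidence_codes}, \code{uses_functional_evidence}) are
#' preserved. Empty string encodes a missing value. Validation errors name
#' the offending row. Writing then reading a catalog reproduces it exactly
#' (numeric columns are serialized at full double precision).
#'
#' @param path File path.
#' @return \code{read_variant_table} returns a data frame, one row per
#'   variant; \code{write_variant_table} returns \code{path} invisibly.
#' @export
read_variant_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE,
                           fileEncoding = "UTF-8")
  parse_num <- function(col, name) {
    col[!nzchar(col)] <- NA_character_
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(out))
    if (length(bad)) {
      stop("variant table '", path, "': malformed number in ", name,
           " at row ", bad[1], " (", col[bad[1]], ")")
    }
    out
  }
  for (col in intersect(c("lof_score", "spliceai_deltamax", "gnomad_af"),
                        names(raw))) {
    raw[[col]] <- parse_num(raw[[col]], col)
  }
  if ("uses_functional_evidence" %in% names(raw)) {
    raw$uses_functional_evidence <- as.logical(raw$uses_functional_evidence)
  }
  validate_catalog(raw, context = paste0("variant table '", path, "'"))
  raw
}

#' @rdname read_variant_table
#' @param catalog Data frame to write.
#' @export
write_variant_table <- function(catalog, path) {
  validate_catalog(catalog)
  out <- catalog
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- ""
      out[[col]] <- v
    } else {
      v <- as.character(out[[col]])
      v[is.na(v)] <- ""
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
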