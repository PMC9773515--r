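# Paired tumor-normal cohort container and TSV I/O.

MSI_LEVELS <- c("MSS", "MSI_low", "MSI_high", "not_assayed")

#' Construct a paired tumor-normal cohort
#'
#' A paired cohort couples each individual's germline findings with one
#' tumor test result. It is held as three data frames joined on
#' \code{individual_id}:
#' \describe{
#'   \item{cases}{one row per individual: \code{individual_id},
#'     \code{msi_status} (MSS / MSI_low / MSI_high / not_assayed),
#'     \code{mlh1_promoter_hypermethylated} (logical, \code{NA} = not
#'     assayed), \code{epcam_structural_variant} (logical).}
#'   \item{germline}{one row per germline finding: \code{individual_id},
#'     \code{gene}, \code{hgvs_c}, \code{consequence},
#'     \code{classification}, \code{lof_score}, \code{spliceai_deltamax}.}
#'   \item{somatic}{one row per somatic event: \code{individual_id},
#'     \code{gene}, \code{event_type} ("mutation" or "loh"),
#'     \code{hgvs_c}, \code{consequence}, \code{classification},
#'     \code{lof_score}, \code{spliceai_deltamax}. LOH rows carry no HGVS
#'     or scores.}
#' }
#'
#' @param cases,germline,somatic Data frames as above; \code{germline} and
#'   \code{somatic} may be empty but must have the columns.
#' @return Object of class \code{"paired_cohort"}.
#' @export
paired_cohort <- function(cases, germline, somatic) {
  stopifnot(is.data.frame(cases), is.data.frame(germline),
            is.data.frame(somatic))
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table missing column(s): ",
                           paste(miss, collapse = ", "))
  }
  req(cases, c("individual_id", "msi_status",
               "mlh1_promoter_hypermethylated", "epcam_structural_variant"),
      "cases")
  req(germline, c("individual_id", "gene", "hgvs_c", "consequence",
                  "classification", "lof_score", "spliceai_deltamax"),
      "germline")
  req(somatic, c("individual_id", "gene", "event_type", "hgvs_c",
                 "consequence", "classification", "lof_score",
                 "spliceai_deltamax"), "somatic")
  if (anyDuplicated(cases$individual_id)) {
    stop("one tumor result per case: duplicate individual_id in cases")
  }
  bad <- setdiff(unique(cases$msi_status), MSI_LEVELS)
  if (length(bad)) stop("unknown msi_status: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(c(germline$gene, somatic$gene)), CATALOG_GENES)
  if (length(bad)) stop("unknown gene in findings: ",
                        paste(bad, collapse = ", "))
  orphan <- setdiff(unique(c(germline$individual_id, somatic$individual_id)),
                    cases$individual_id)
  if (length(orphan)) {
    stop("findings reference individual_id absent from cases: ",
         paste(utils::head(orphan, 3), collapse = ", "))
  }
  structure(list(cases = cases, germline = germline, somatic = somatic),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("paired tumor-normal cohort: %d cases, %d germline findings, %d somatic events\n",
              nrow(x$cases), nrow(x$germline), nrow(x$somatic)))
  invisible(x)
}

subset_paired_cohort <- function(pc, ids) {
  paired_cohort(
    cases = pc$cases[pc$cases$individual_id %in% ids, , drop = FALSE],
    germline = pc$germline[pc$germline$individual_id %in% ids, , drop = FALSE],
    somatic = pc$somatic[pc$somatic$individual_id %in% ids, , drop = FALSE]
  )
}

#' Read or write a paired cohort as two TSV files
#'
#' \code{germline.tsv} holds the germline findings; \code{tumor.tsv} holds
#' one row per somatic event outer-joined with the case-level tumor
#' characteristics (cases without somatic events appear with an empty
#' \code{event_type}).
#'
#' @param pc A [paired_cohort()].
#' @param dir Directory for the two files.
#' @return \code{write_paired_cohort} returns the file paths invisibly;
#'   \code{read_paired_cohort} returns the reconstructed cohort.
#' @export
write_paired_cohort <- function(pc, dir) {
  stopifnot(inherits(pc, "paired_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g_path <- file.path(dir, "germline.tsv")
  t_path <- file.path(dir, "tumor.tsv")
  write_tsv <- function(df, path) {
    out <- df
    for (col in names(out)) {
      v <- if (is.numeric(out[[col]])) sprintf("%.17g", out[[col]])
           else as.character(out[[col]])
      v[is.na(out[[col]])] <- ""
      out[[col]] <- v
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tsv(pc$germline, g_path)
  som <- pc$somatic
  blank <- pc$cases$individual_id[!pc$cases$individual_id %in% som$individual_id]
  if (length(blank)) {
    pad <- som[rep(NA_integer_, length(blank)), , drop = FALSE]
    pad$individual_id <- blank
    pad$event_type <- NA_character_
    som <- rbind(som, pad)
  }
  tumor <- merge(som, pc$cases, by = "individual_id", all.x = TRUE,
                 sort = FALSE)
  tumor <- tumor[order(match(tumor$individual_id, pc$cases$individual_id)), ]
  write_tsv(tumor, t_path)
  invisible(c(germline = g_path, tumor = t_path))
}

#' @rdname write_paired_cohort
#' @export
read_paired_cohort <- function(dir) {
  read_tsv <- function(path) {
    utils::read.delim(path, colClasses = "character", na.strings = NULL,
                      check.names = FALSE, fileEncoding = "UTF-8")
  }
  num <- function(v) suppressWarnings(as.numeric(ifelse(nzchar(v), v, NA)))
  lgl <- function(v) as.logical(ifelse(nzchar(v), v, NA))
  g <- read_tsv(file.path(dir, "germline.tsv"))
  for (col in c("lof_score", "spliceai_deltamax")) g[[col]] <- num(g[[col]])
  t <- read_tsv(file.path(dir, "tumor.tsv"))
  for (col in c("lof_score", "spliceai_deltamax")) t[[col]] <- num(t[[col]])
  t$mlh1_promoter_hypermethylated <- lgl(t$mlh1_promoter_hypermethylated)
  t$epcam_structural_variant <- lgl(t$epcam_structural_variant)
  case_cols <- c("individual_id", "msi_status",
                 "mlh1_promoter_hypermethylated", "epcam_structural_variant")
  cases <- unique(t[, case_cols])
  som <- t[!is.na(t$event_type) & nzchar(t$event_type),
           c("individual_id", "gene", "event_type", "hgvs_c", "consequence",
             "classification", "lof_score", "spliceai_deltamax")]
  som$hgvs_c[!nzchar(som$hgvs_c)] <- NA_character_
  rownames(cases) <- rownames(som) <- NULL
  paired_cohort(cases, g, som)
}
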