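# Pipeline orchestration: stage ordering, manifests, report assembly.
# A thin command-line wrapper around run_pipeline() ships in
# inst/scripts/run-pipeline.R.

pipeline_stages <- c("simulate", "tier", "calibrate", "reclassify",
                     "associate", "paired")

hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

build_manifest <- function(command, config, inputs, seed) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    as.list(stats::setNames(unname(d), basename(inputs)))
  } else list()
  list(command = command,
       tool_version = as.character(utils::packageVersion("maveclass")),
       seed = seed,
       config_hash = hash_object(unclass(config)),
       input_digests = digests)
}

write_report <- function(x, path, manifest) {
  x$manifest <- manifest
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}

log_msg <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}

oddspath_report <- function(op) {
  fields <- c("n_path", "n_benign", "n_path_abnormal", "n_benign_abnormal",
              "n_path_normal", "n_benign_normal", "n_intermediate", "p1",
              "p2_abnormal", "p2_normal", "oddspath_abnormal",
              "oddspath_normal", "correction_applied_abnormal",
              "correction_applied_normal")
  out <- op[fields]
  out$strength_abnormal <- unclass(op$strength_abnormal)
  out$strength_normal <- unclass(op$strength_normal)
  out
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages in dependency order (tier feeds calibrate,
#' reclassify, associate and paired; reclassify additionally needs an
#' established calibration). With \code{stage = "all"} and no input paths
#' the synthetic generator supplies the data, so the full pipeline runs
#' end-to-end from a single seed. Every JSON report embeds a manifest
#' (command, package version, seed, configuration hash, input digests);
#' identical inputs give byte-identical reports, with timestamps confined
#' to the log stream.
#'
#' @param stage One of \code{"all"}, \code{"simulate"}, \code{"tier"},
#'   \code{"calibrate"}, \code{"reclassify"}, \code{"associate"},
#'   \code{"paired"}.
#' @param config A [simulation_config()]; also carries the seed.
#' @param out_dir Output directory, created if needed.
#' @param catalog_path,controls_path,germline_path,paired_dir Optional input
#'   paths; when absent the corresponding synthetic table is generated (and,
#'   for \code{stage = "simulate"} or \code{"all"}, written to
#'   \code{out_dir}).
#' @param cutoffs A [tier_cutoffs()] list.
#' @param ps3_strong_cutoff LoF score for PS3 at full strength.
#' @param verbose Log per-stage record counts to standard error.
#' @return Invisibly, a named list of report file paths.
#' @export
run_pipeline <- function(stage = "all",
                         config = simulation_config(),
                         out_dir = tempfile("maveclass_run_"),
                         catalog_path = NULL, controls_path = NULL,
                         germline_path = NULL, paired_dir = NULL,
                         cutoffs = tier_cutoffs(),
                         ps3_strong_cutoff = 1.7,
                         verbose = TRUE) {
  stage <- match.arg(stage, c("all", pipeline_stages))
  stages <- if (stage == "all") pipeline_stages else stage
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(catalog_path, controls_path, germline_path)
  manifest <- build_manifest(paste(stages, collapse = "+"), config,
                             inputs[!vapply(inputs, is.null, logical(1))],
                             config$seed)
  reports <- list()

  need <- function(s) s %in% stages || stage == "all"
  catalog <- NULL; controls <- NULL; germline <- NULL; paired <- NULL
  load_catalog <- function() {
    if (!is.null(catalog_path)) read_variant_table(catalog_path)
    else gen_catalog(config)
  }

  if (need("simulate")) {
    sim <- simulate_cohort(config)
    catalog <- sim$catalog; controls <- sim$controls
    germline <- sim$germline_cohort; paired <- sim$paired_cohort
    write_variant_table(catalog, file.path(out_dir, "catalog.tsv"))
    write_variant_table(controls, file.path(out_dir, "controls.tsv"))
    utils::write.table(germline, file.path(out_dir, "germline_cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_paired_cohort(paired, file.path(out_dir, "paired"))
    log_msg(verbose, "simulate: ", nrow(catalog), " variants, ",
            nrow(germline), " carriers, ", nrow(paired$cases),
            " paired cases")
    reports$simulate <- file.path(out_dir, "catalog.tsv")
  }

  if (is.null(catalog)) catalog <- load_catalog()
  catalog <- annotate_tiers(catalog, cutoffs)

  if (need("tier")) {
    counts <- count_by_mechanism(catalog, cutoffs)
    path <- file.path(out_dir, "tier_report.json")
    write_report(list(
      n_variants = nrow(catalog),
      n_unscored = sum(catalog$tier == "unscored"),
      tier_counts = as.list(stats::setNames(as.integer(rowSums(counts)),
                                            rownames(counts)))
    ), path, manifest)
    write_variant_table(catalog, file.path(out_dir, "catalog_tiered.tsv"))
    log_msg(verbose, "tier: ", nrow(catalog), " variants banded (",
            sum(catalog$tier == "unscored"), " unscored)")
    reports$tier <- path
  }

  calibration <- NULL
  calib_path <- file.path(out_dir, "calibration.json")
  if (need("calibrate")) {
    if (is.null(controls)) {
      controls <- if (!is.null(controls_path)) read_variant_table(controls_path)
                  else gen_control_set(config, catalog)
    }
    curated <- curate_controls(controls)
    calibration <- compute_oddspath(curated, cutoffs)
    write_report(oddspath_report(calibration), calib_path, manifest)
    log_msg(verbose, "calibrate: ", nrow(curated), " controls, OddsPath ",
            signif(calibration$oddspath_abnormal, 4), " / ",
            signif(calibration$oddspath_normal, 4))
    reports$calibrate <- calib_path
  }

  if (need("reclassify")) {
    if (is.null(calibration)) {
      stop("reclassify requires an established calibration: run the ",
           "calibrate stage first (stage = \"calibrate\" or \"all\")")
    }
    recl <- reclassify_catalog(catalog, calibration, cutoffs,
                               ps3_strong_cutoff)
    audit_path <- file.path(out_dir, "reclassification_audit.tsv")
    utils::write.table(recl$audit, audit_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path <- file.path(out_dir, "reclassification.json")
    write_report(recl[setdiff(names(recl), "audit")], path, manifest)
    log_msg(verbose, "reclassify: ", recl$n_vus, " VUS -> ",
            recl$newly_plp, " P/LP, ", recl$newly_blb, " B/LB, ",
            recl$remaining_vus, " remaining")
    reports$reclassify <- path
  }

  if (need("associate")) {
    if (is.null(germline)) {
      germline <- if (!is.null(germline_path)) {
        utils::read.delim(germline_path)
      } else gen_germline_cohort(config, catalog)
    }
    crc <- fit_cancer_association(germline, "CRC")
    uec <- fit_cancer_association(germline, "UEC")
    assoc <- rbind(cbind(outcome = "CRC", as.data.frame(crc)),
                   cbind(outcome = "UEC", as.data.frame(uec)))
    path <- file.path(out_dir, "association.tsv")
    utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_msg(verbose, "associate: ", nrow(germline), " carriers, ",
            nrow(assoc), " feature-outcome estimates")
    reports$associate <- path
  }

  if (need("paired")) {
    if (is.null(paired)) {
      paired <- if (!is.null(paired_dir)) read_paired_cohort(paired_dir)
                else gen_paired_cohort(config, catalog)
    }
    sole <- select_sole_msh2_missense_cases(paired)
    second <- second_hit_analysis(sole, cutoffs = cutoffs)
    msi <- tryCatch(msi_analysis(sole, cutoffs), error = function(e) NULL)
    coin <- somatic_coincidence_analysis(paired, cutoffs)
    path <- file.path(out_dir, "paired_analysis.json")
    as_tab <- function(t) if (is.null(t)) NULL else
      list(table = as.vector(t$table), p_value = t$p_value)
    write_report(list(
      n_paired = nrow(paired$cases),
      n_sole_msh2_missense = nrow(sole$cases),
      second_hit = as_tab(second),
      msi = as_tab(msi),
      somatic_coincidence = list(
        n_disruptive = coin$n_disruptive, n_neutral = coin$n_neutral,
        other_ls = as_tab(coin$other_ls),
        methylation = as_tab(coin$methylation),
        n_sporadic_candidates = length(coin$sporadic_candidates))
    ), path, manifest)
    log_msg(verbose, "paired: ", nrow(sole$cases),
            " sole-MSH2-missense cases; second-hit p = ",
            signif(second$p_value, 3))
    reports$paired <- path
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(reports)
}
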