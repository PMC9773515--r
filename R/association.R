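# Logistic cancer-association models over carrier features.

#' Default carrier feature columns for the association models
#'
#' Six mutually interpretable 0/1 carrier features: MSH2 missense with
#' deleterious function score, MSH2 missense with neutral function score,
#' MSH2 other (non-missense) P/LP, and any P/LP in MLH1, MSH6 or PMS2.
#'
#' @return Character vector of column names.
#' @export
association_features <- function() {
  c("msh2_mis_deleterious", "msh2_mis_neutral", "msh2_other_plp",
    "mlh1_plp", "msh6_plp", "pms2_plp")
}

#' Cancer association by carrier feature, via logistic regression
#'
#' Fits a maximum-likelihood logistic model with intercept: cancer diagnosis
#' as response and the binary carrier features as covariates. The
#' uterine/endometrial model is restricted to females. Exclusion rules are
#' applied first: individuals with a P/LP variant in a non-Lynch-syndrome
#' gene are dropped from the missense-VUS features' analysis, and an
#' individual carrying both an MSH2 missense VUS and a P/LP variant in
#' another Lynch gene counts as a carrier for that gene only (the missense
#' feature is zeroed). Wald 95\% intervals are reported on the odds-ratio
#' scale. Complete separation is flagged per term, never silently dropped;
#' empty (all-zero) feature columns are dropped with a warning.
#'
#' @param cohort Carrier table: one row per individual with columns
#'   \code{sex} ("female"/"male"), \code{crc_dx}, \code{uec_dx} (0/1), the
#'   feature columns, and optionally \code{non_ls_plp}.
#' @param outcome \code{"CRC"} (colorectal) or \code{"UEC"}
#'   (uterine/endometrial, females only).
#' @param features Feature columns to include.
#' @param include_sex Add sex as a covariate (CRC only; the generator and
#'   most clinical cohorts have strongly sex-dependent baseline rates, so
#'   the conditional odds ratio is the estimand). Ignored for UEC.
#' @return Data frame of class \code{"cancer_association"}: one row per
#'   feature with \code{odds_ratio}, \code{ci_low}, \code{ci_high},
#'   \code{p_value}, \code{n_carriers}, \code{separation} flag; attribute
#'   \code{n} is the analysed sample size.
#' @export
fit_cancer_association <- function(cohort,
                                   outcome = c("CRC", "UEC"),
                                   features = association_features(),
                                   include_sex = TRUE) {
  outcome <- match.arg(outcome)
  missing_cols <- setdiff(features, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dat <- cohort
  if (outcome == "UEC") {
    dat <- dat[dat$sex == "female", , drop = FALSE]
    include_sex <- FALSE
  }
  vus_features <- intersect(c("msh2_mis_deleterious", "msh2_mis_neutral"),
                            features)
  if (length(vus_features)) {
    vus_carrier <- rowSums(as.matrix(dat[, vus_features, drop = FALSE])) > 0
    if (!is.null(dat$non_ls_plp)) {
      drop <- vus_carrier & dat$non_ls_plp == 1
      dat <- dat[!drop, , drop = FALSE]
      vus_carrier <- vus_carrier[!drop]
    }
    other_ls <- intersect(c("mlh1_plp", "msh6_plp", "pms2_plp"), names(dat))
    if (length(other_ls)) {
      reassign <- rowSums(as.matrix(dat[, other_ls, drop = FALSE])) > 0
      for (f in vus_features) dat[[f]][reassign] <- 0
    }
  }
  empty <- vapply(features, function(f) sum(dat[[f]]) == 0, logical(1))
  if (any(empty)) {
    warning("dropping empty feature column(s): ",
            paste(features[empty], collapse = ", "))
    features <- features[!empty]
  }
  if (!length(features)) stop("no non-empty features to fit")

  y <- if (outcome == "CRC") dat$crc_dx else dat$uec_dx
  rhs <- features
  if (include_sex) rhs <- c(rhs, "sex")
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  dat$y <- as.integer(y)
  fit <- suppressWarnings(
    stats::glm(form, data = dat, family = stats::binomial())
  )
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  mu <- stats::fitted(fit)
  separated <- !fit$converged || any(abs(est[features]) > 15) ||
    any(mu > 1 - 1e-10) || any(mu < 1e-10)

  rows <- lapply(features, function(f) {
    b <- est[[f]]; s <- se[[f]]
    data.frame(term = f,
               odds_ratio = exp(b),
               ci_low = exp(b - z * s),
               ci_high = exp(b + z * s),
               p_value = 2 * stats::pnorm(-abs(b / s)),
               n_carriers = sum(dat[[f]] == 1),
               separation = separated && abs(b) > 15,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- nrow(dat)
  attr(out, "outcome") <- outcome
  attr(out, "converged") <- fit$converged
  class(out) <- c("cancer_association", class(out))
  out
}

#' @export
print.cancer_association <- function(x, ...) {
  cat(sprintf("Cancer association (%s, n = %d)\n",
              attr(x, "outcome"), attr(x, "n")))
  df <- as.data.frame(x)
  df$odds_ratio <- signif(df$odds_ratio, 3)
  df$ci_low <- signif(df$ci_low, 3)
  df$ci_high <- signif(df$ci_high, 3)
  df$p_value <- signif(df$p_value, 2)
  print.data.frame(df, row.names = FALSE)
  if (any(x$separation)) {
    cat("note: term(s) flagged for complete separation; estimates unstable\n")
  }
  invisible(x)
}
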