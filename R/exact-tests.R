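# Exact 2x2 and binomial tests. Point masses come from stats::dhyper/dbinom
# (computed in log space internally); the two-sided enumeration is defined
# here so its convention is explicit and auditable.

as_2x2 <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("expected a 2x2 table")
    x <- as.vector(t(x))
  }
  if (length(x) != 4L) stop("expected 4 counts (a, b, c, d)")
  if (any(is.na(x)) || any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integers")
  x
}

# Relative tolerance for "as or less probable than observed": a point mass
# within 1e-7 (relative) of the observed one counts toward the two-sided sum,
# matching the convention of mainstream exact-test implementations.
REL_TOL <- 1 + 1e-7

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration over all tables with the
#' observed margins, summing the probabilities of every table as or less
#' probable than the one observed (the "method of small p-values", with
#' relative tolerance 1e-7 on ties). A degenerate table with a zero margin
#' carries no information and returns p = 1.
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = outcome yes/no.
#'   Alternatively pass a 2x2 matrix as \code{a}.
#' @return The two-sided p-value in [0, 1].
#' @examples
#' fisher_two_sided(12, 1, 2, 10)
#' @export
fisher_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- if (is.null(b)) as_2x2(a) else as_2x2(c(a, b, c, d))
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- cc + d; m <- a + cc; n2 <- b + d
  if (r1 == 0 || r2 == 0 || m == 0 || n2 == 0) return(1)
  k <- max(0, m - r2):min(m, r1)
  pk <- stats::dhyper(k, r1, r2, m)
  pobs <- stats::dhyper(a, r1, r2, m)
  min(1, sum(pk[pk <= pobs * REL_TOL]))
}

#' Two-sided exact binomial test
#'
#' Tests \code{x} successes in \code{n} trials against success probability
#' \code{p0}. The default \code{"minlike"} method sums the probabilities of
#' all outcomes whose point probability does not exceed that of the observed
#' outcome (relative tolerance 1e-7), the convention of mainstream exact-test
#' implementations. \code{"central"} doubles the smaller tail and
#' \code{"midp"} doubles the mid-p tail (half-weighting the observed
#' outcome); both are capped at 1.
#'
#' @param x Observed successes.
#' @param n Number of trials.
#' @param p0 Null success probability, strictly inside (0, 1).
#' @param method Two-sidedness convention.
#' @return The two-sided p-value in [0, 1].
#' @examples
#' binomial_two_sided(34, 682, 351 / 5130)
#' @export
binomial_two_sided <- function(x, n, p0,
                               method = c("minlike", "central", "midp")) {
  method <- match.arg(method)
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      x < 0 || n < 1 || x > n || x != round(x) || n != round(n)) {
    stop("x must be an integer in [0, n]")
  }
  if (is.na(p0) || p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)")
  if (method == "minlike") {
    pk <- stats::dbinom(0:n, n, p0)
    return(min(1, sum(pk[pk <= pk[x + 1L] * REL_TOL])))
  }
  dx <- stats::dbinom(x, n, p0)
  lo <- stats::pbinom(x, n, p0)
  hi <- stats::pbinom(x - 1L, n, p0, lower.tail = FALSE)
  if (method == "midp") {
    lo <- lo - dx / 2
    hi <- hi - dx / 2
  }
  min(1, 2 * min(lo, hi))
}

#' Odds ratio for a 2x2 table with Woolf confidence interval
#'
#' Cross-product odds ratio \eqn{ad/bc} with a 95\% Wald interval on the log
#' scale, \eqn{\log OR \pm 1.96 \sqrt{1/a + 1/b + 1/c + 1/d}}. When any cell
#' is zero the Haldane-Anscombe 0.5 continuity correction is applied to every
#' cell and flagged. A companion sanity check for the logistic models, which
#' reproduce this quantity exactly for a single binary covariate.
#'
#' @inheritParams fisher_two_sided
#' @param term Label for the reported row.
#' @return One-row data frame: \code{term}, \code{odds_ratio}, \code{ci_low},
#'   \code{ci_high}, \code{p_value} (two-sided Fisher), and
#'   \code{continuity_corrected}.
#' @export
odds_ratio_2x2 <- function(a, b = NULL, c = NULL, d = NULL, term = "group") {
  x <- if (is.null(b)) as_2x2(a) else as_2x2(c(a, b, c, d))
  p <- fisher_two_sided(x)
  corrected <- any(x == 0)
  xc <- if (corrected) x + 0.5 else x
  or <- (xc[1] * xc[4]) / (xc[2] * xc[3])
  se <- sqrt(sum(1 / xc))
  z <- stats::qnorm(0.975)
  data.frame(term = term, odds_ratio = or,
             ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
             p_value = p, continuity_corrected = corrected,
             stringsAsFactors = FALSE)
}
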