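# Evidence-code algebra: the ACMG/AMP code registry, strength modifiers,
# point values, and point-based classification.

STRENGTH_LEVELS <- c("supporting", "moderate", "strong", "very_strong")
STRENGTH_SUFFIX <- c(P = "supporting", M = "moderate", S = "strong",
                     VS = "very_strong")

acmg_registry <- local({
  base <- c("PVS1",
            paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
            "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  intrinsic <- c("very_strong",
                 rep("strong", 4), rep("moderate", 6), rep("supporting", 5),
                 "very_strong", rep("strong", 4), rep("supporting", 7))
  direction <- ifelse(startsWith(base, "P"), "pathogenic", "benign")
  data.frame(base = base, intrinsic = intrinsic, direction = direction,
             stringsAsFactors = FALSE)
})

#' Construct an ACMG/AMP evidence code
#'
#' An evidence code is a base criterion (e.g. \code{PS3}, \code{PM2},
#' \code{BS3}) applied at a strength. The strength defaults to the base
#' code's intrinsic level (PVS very strong, PS strong, PM moderate, PP
#' supporting; mirrored for the benign codes, with the stand-alone BA1
#' treated as very strong) but may be overridden, e.g. \code{PM2} applied at
#' supporting. Direction (pathogenic/benign) follows the base prefix.
#'
#' @param base Base code name from the registry.
#' @param strength Applied strength; \code{NULL} uses the intrinsic level.
#' @return An object of class \code{"acmg_code"}.
#' @examples
#' acmg_code("PS3")
#' acmg_code("PM2", "supporting")
#' @export
acmg_code <- function(base, strength = NULL) {
  i <- match(base, acmg_registry$base)
  if (length(base) != 1L || is.na(i)) {
    stop("unknown evidence code base: ", paste(base, collapse = ", "))
  }
  if (is.null(strength)) strength <- acmg_registry$intrinsic[i]
  strength <- match.arg(strength, STRENGTH_LEVELS)
  structure(list(base = base, strength = strength,
                 direction = acmg_registry$direction[i]),
            class = "acmg_code")
}

#' Parse and format evidence-code tokens
#'
#' Tokens use the clinical shorthand \code{BASE} or \code{BASE_X} where
#' \code{X} is \code{P}, \code{M}, \code{S} or \code{VS}, overriding the
#' applied strength to supporting, moderate, strong or very strong. Thus
#' \code{"PM2_P"} is PM2 applied at supporting and \code{"PS4_M"} is PS4 at
#' moderate. \code{format_code} is the inverse: the suffix is emitted only
#' when the applied strength differs from the intrinsic one.
#'
#' @param text A single token such as \code{"PS3"} or \code{"PM2_P"}.
#' @return \code{parse_code} returns an [acmg_code()]; \code{parse_codes}
#'   parses a comma-separated string into a list of codes;
#'   \code{format_code} returns the token string.
#' @examples
#' parse_code("PM2_P")
#' format_code(acmg_code("PS4", "moderate"))
#' @export
parse_code <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("empty evidence-code token")
  }
  parts <- strsplit(trimws(text), "_", fixed = TRUE)[[1]]
  if (length(parts) > 2L || !parts[1] %in% acmg_registry$base) {
    stop("cannot parse evidence code token '", text, "'")
  }
  strength <- NULL
  if (length(parts) == 2L) {
    strength <- unname(STRENGTH_SUFFIX[parts[2]])
    if (is.na(strength)) {
      stop("cannot parse evidence code token '", text,
           "': unknown strength suffix '", parts[2], "'")
    }
  }
  acmg_code(parts[1], strength)
}

#' @rdname parse_code
#' @param codes Comma-separated tokens, e.g. \code{"PS3,PM2_P,PP3"}; empty
#'   string or \code{NA} gives an empty list.
#' @export
parse_codes <- function(codes) {
  if (length(codes) != 1L) stop("parse_codes expects a single string")
  if (is.na(codes) || !nzchar(trimws(codes))) return(list())
  lapply(strsplit(codes, ",", fixed = TRUE)[[1]], parse_code)
}

#' @rdname parse_code
#' @param code An [acmg_code()].
#' @export
format_code <- function(code) {
  stopifnot(inherits(code, "acmg_code"))
  intrinsic <- acmg_registry$intrinsic[match(code$base, acmg_registry$base)]
  if (code$strength == intrinsic) return(code$base)
  paste0(code$base, "_",
         names(STRENGTH_SUFFIX)[match(code$strength, STRENGTH_SUFFIX)])
}

#' @export
print.acmg_code <- function(x, ...) {
  cat(format_code(x), sprintf("(%s, %s)\n", x$direction, x$strength))
  invisible(x)
}

#' Point scale for evidence strengths
#'
#' Supporting 1, moderate 2, strong 4, very strong 8; benign-direction codes
#' contribute negative points. The scale is configuration, not a constant,
#' so alternative published scales can be swapped in.
#'
#' @return Named integer vector.
#' @export
acmg_point_scale <- function() {
  c(supporting = 1L, moderate = 2L, strong = 4L, very_strong = 8L)
}

#' Points contributed by one evidence code
#'
#' @param code An [acmg_code()].
#' @param scale Named vector from [acmg_point_scale()].
#' @return Signed integer points.
#' @examples
#' points_for(acmg_code("PS3"))   # +4
#' points_for(acmg_code("BS3"))   # -4
#' @export
points_for <- function(code, scale = acmg_point_scale()) {
  stopifnot(inherits(code, "acmg_code"))
  pts <- scale[[code$strength]]
  if (code$direction == "benign") -pts else pts
}

#' Category thresholds for point totals
#'
#' Point totals map to the five clinical tiers: at least 10 pathogenic, 6 to
#' 9 likely pathogenic, 0 to 5 uncertain, -6 to -1 likely benign, -7 or
#' below benign.
#'
#' @return Named list of boundary points.
#' @export
acmg_category_thresholds <- function() {
  list(pathogenic = 10L, likely_pathogenic = 6L, likely_benign = -1L,
       benign = -7L)
}

category_from_points <- function(points, thresholds = acmg_category_thresholds()) {
  ifelse(points >= thresholds$pathogenic, "P",
  ifelse(points >= thresholds$likely_pathogenic, "LP",
  ifelse(points > thresholds$likely_benign, "VUS",
  ifelse(points > thresholds$benign, "LB", "B"))))
}

#' Point-based classification from a set of evidence codes
#'
#' Sums the points of the applied codes and maps the total to a clinical
#' class. Each base code may be applied at most once; duplicates are a
#' validation error. The result is invariant to the order of the codes, and
#' adding a pathogenic code never lowers the category (nor a benign code
#' raises it).
#'
#' @param codes A list of [acmg_code()] objects, or a comma-separated token
#'   string accepted by [parse_codes()].
#' @param thresholds See [acmg_category_thresholds()].
#' @param scale See [acmg_point_scale()].
#' @return Object of class \code{"acmg_classification"}: \code{points},
#'   \code{category}, \code{codes_applied}.
#' @examples
#' classify_variant("PS3,PM2_P,PS4_M,PP3,PM1_P")  # 9 points -> LP
#' @export
classify_variant <- function(codes = list(),
                             thresholds = acmg_category_thresholds(),
                             scale = acmg_point_scale()) {
  if (is.character(codes)) codes <- parse_codes(codes)
  stopifnot(all(vapply(codes, inherits, logical(1), "acmg_code")))
  bases <- vapply(codes, `[[`, character(1), "base")
  if (anyDuplicated(bases)) {
    stop("evidence code applied more than once: ",
         bases[duplicated(bases)][1])
  }
  points <- if (length(codes)) {
    sum(vapply(codes, points_for, numeric(1), scale = scale))
  } else 0L
  structure(list(points = as.integer(points),
                 category = category_from_points(points, thresholds),
                 codes_applied = codes),
            class = "acmg_classification")
}

#' @export
print.acmg_classification <- function(x, ...) {
  toks <- vapply(x$codes_applied, format_code, character(1))
  cat(sprintf("ACMG point classification: %+d points -> %s  [%s]\n",
              x$points, x$category,
              if (length(toks)) paste(toks, collapse = ", ") else "no codes"))
  invisible(x)
}
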