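#' @importFrom jsonlite read_json write_json
NULL

# Variant definitions: which factors of the master point table each cohort
# variant retains. Age and gender are one sex-stratified factor internally but
# are counted as two factors, following the convention of the index itself.
.anu_variants <- list(
  anu_adri_full   = c("age", "education", "diabetes", "tbi", "depression",
                      "cognitive_activity", "social_network", "smoking",
                      "alcohol", "physical_activity", "fish_intake"),
  anu_adri_map    = c("age", "education", "diabetes", "tbi",
                      "cognitive_activity", "social_network", "smoking",
                      "alcohol", "physical_activity"),
  anu_adri_kp     = c("age", "education", "diabetes", "tbi", "social_network",
                      "smoking", "alcohol"),
  anu_adri_cvhs   = c("age", "education", "diabetes", "depression", "smoking",
                      "alcohol", "physical_activity", "fish_intake"),
  anu_adri_common = c("age", "education", "diabetes", "smoking", "alcohol")
)

.caide_variants <- list(
  caide                = c("age", "sex", "low_education", "hypercholesterolaemia",
                           "high_systolic_bp", "physical_inactivity", "obesity"),
  caide_no_bmi         = c("age", "sex", "low_education", "hypercholesterolaemia",
                           "high_systolic_bp", "physical_inactivity"),
  caide_no_bmi_no_chol = c("age", "sex", "low_education", "high_systolic_bp",
                           "physical_inactivity")
)

#' All known scorecard variant identifiers
#'
#' @return Character vector of identifiers accepted by [build_scorecard()].
#' @export
scorecard_variants <- function() {
  c(names(.anu_variants), names(.caide_variants))
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "anuadri")
  if (!nzchar(path)) stop("bundled file not found: ", file, call. = FALSE)
  path
}

new_scorecard <- function(name, factors, metadata = list()) {
  card <- structure(
    list(name = name, factors = factors, metadata = metadata),
    class = "scorecard"
  )
  validate_scorecard(card)
  card
}

factor_categories <- function(f) {
  if (isTRUE(f$stratified_by_sex)) c(f$strata$male, f$strata$female) else f$categories
}

validate_scorecard <- function(card) {
  stopifnot(is.character(card$name), length(card$name) == 1L)
  if (length(card$factors) == 0L) stop("scorecard has no factors", call. = FALSE)
  nms <- vapply(card$factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate factor names in scorecard", call. = FALSE)
  for (f in card$factors) {
    cats <- factor_categories(f)
    if (length(cats) < 2L) stop("factor '", f$name, "' needs >= 2 categories", call. = FALSE)
    pts <- vapply(cats, `[[`, numeric(1), "points")
    if (any(!is.finite(pts)) || any(pts != round(pts)))
      stop("factor '", f$name, "' has non-integer points", call. = FALSE)
    if (isTRUE(f$stratified_by_sex)) {
      for (s in c("male", "female")) {
        labs <- vapply(f$strata[[s]], `[[`, character(1), "label")
        if (anyDuplicated(labs))
          stop("duplicate category labels in factor '", f$name, "' (", s, ")", call. = FALSE)
      }
    } else {
      labs <- vapply(f$categories, `[[`, character(1), "label")
      if (anyDuplicated(labs))
        stop("duplicate category labels in factor '", f$name, "'", call. = FALSE)
      if (!any(pts == 0))
        stop("factor '", f$name, "' lacks a zero-point reference category", call. = FALSE)
    }
  }
  invisible(card)
}

#' Read a scorecard from its JSON serialisation
#'
#' The on-disk format is `{name, metadata, factors:[...]}` where each factor
#' carries `name`, `source` (`"column"`, `"age"` or `"sex"`),
#' `stratified_by_sex`, and either a flat `categories` list of
#' `{label, points}` objects (age-based categories additionally carry
#' `age_min`/`age_max` integer bounds) or per-sex `strata` lists.
#'
#' @param path Path to a scorecard JSON file.
#' @return A `scorecard` object.
#' @seealso [write_scorecard()], [build_scorecard()]
#' @export
read_scorecard <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  new_scorecard(raw$name, raw$factors, raw$metadata)
}

#' Write a scorecard to JSON
#'
#' @param card A `scorecard` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scorecard <- function(card, path) {
  stopifnot(inherits(card, "scorecard"))
  jsonlite::write_json(unclass(card), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Build a named scorecard variant
#'
#' Constructs one of the bundled point systems: the full additive dementia
#' risk index, its cohort-specific restrictions (each validation cohort
#' measured only a subset of factors), the common-variable subset (age, sex,
#' education, diabetes, smoking, alcohol), or the CAIDE comparator index and
#' its reduced forms.
#'
#' The cohort restrictions follow the factor availability of the three
#' published validation cohorts: the memory-and-aging-study variant
#' (`anu_adri_map`) has 10 counted factors (no depressive symptoms or fish
#' intake), the Kungsholmen variant (`anu_adri_kp`) has 8 (additionally no
#' cognitive or physical activity; its smoking item distinguished only never
#' and current smokers, so the `former` category is dropped), and the
#' cardiovascular-health variant (`anu_adri_cvhs`) has 9 (no TBI, cognitive
#' activity, or social network). Age and gender are one sex-stratified factor
#' internally but count as two, matching the convention of the index.
#'
#' @param variant One of [scorecard_variants()].
#' @param overrides Optional named list of point overrides, e.g.
#'   `list(alcohol = c(heavy = 2))` sets the `heavy` category of the alcohol
#'   factor to 2 points. For the sex-stratified age factor use
#'   `list(age = list(male = c("<65" = 1)))`.
#' @return A `scorecard` object.
#' @examples
#' card <- build_scorecard("anu_adri_map")
#' theoretical_range(card)
#' @export
build_scorecard <- function(variant, overrides = NULL) {
  variant <- as.character(variant)[1]
  if (variant %in% names(.anu_variants)) {
    master <- read_scorecard(.extdata("anu_adri.json"))
    keep <- .anu_variants[[variant]]
  } else if (variant %in% names(.caide_variants)) {
    master <- read_scorecard(.extdata("caide.json"))
    keep <- .caide_variants[[variant]]
  } else {
    stop("unknown scorecard variant '", variant, "'; see scorecard_variants()",
         call. = FALSE)
  }
  nms <- vapply(master$factors, `[[`, character(1), "name")
  factors <- master$factors[match(keep, nms)]
  if (variant == "anu_adri_kp") {
    # Kungsholmen smoking was asked only as current vs never
    i <- which(keep == "smoking")
    factors[[i]]$categories <- Filter(
      function(cat) cat$label %in% c("never", "current"),
      factors[[i]]$categories
    )
  }
  card <- new_scorecard(variant, factors, master$metadata)
  if (!is.null(overrides)) card <- apply_overrides(card, overrides)
  card
}

apply_overrides <- function(card, overrides) {
  stopifnot(is.list(overrides))
  nms <- vapply(card$factors, `[[`, character(1), "name")
  for (fname in names(overrides)) {
    i <- match(fname, nms)
    if (is.na(i)) stop("override refers to unknown factor '", fname, "'", call. = FALSE)
    ov <- overrides[[fname]]
    set_points <- function(cats, ov_vec) {
      labs <- vapply(cats, `[[`, character(1), "label")
      for (lab in names(ov_vec)) {
        j <- match(lab, labs)
        if (is.na(j)) stop("override refers to unknown category '", lab,
                           "' of factor '", fname, "'", call. = FALSE)
        cats[[j]]$points <- as.integer(ov_vec[[lab]])
      }
      cats
    }
    if (isTRUE(card$factors[[i]]$stratified_by_sex)) {
      stopifnot(is.list(ov))
      for (s in names(ov)) {
        if (!s %in% c("male", "female"))
          stop("stratified override must name 'male'/'female' strata", call. = FALSE)
        card$factors[[i]]$strata[[s]] <- set_points(card$factors[[i]]$strata[[s]], ov[[s]])
      }
    } else {
      card$factors[[i]]$categories <- set_points(card$factors[[i]]$categories, ov)
    }
  }
  validate_scorecard(card)
  card
}

#' Names of the factors in a scorecard
#'
#' @param card A `scorecard`.
#' @param counted If `TRUE`, count a sex-stratified age factor as two factors
#'   (age and gender), the convention used when the index is described as
#'   having "10 factors" etc.
#' @return Character vector of factor names (`counted = FALSE`) or an integer
#'   count (`counted = TRUE` returns the names too, with the count as the
#'   `n_counted` attribute).
#' @export
scorecard_factors <- function(card, counted = FALSE) {
  stopifnot(inherits(card, "scorecard"))
  nms <- vapply(card$factors, `[[`, character(1), "name")
  if (counted) {
    n <- length(nms) + sum(vapply(card$factors, function(f)
      isTRUE(f$stratified_by_sex), logical(1)))
    attr(nms, "n_counted") <- n
  }
  nms
}

#' Theoretical score range of a scorecard
#'
#' The minimum (maximum) achievable total score: the sum over factors of the
#' smallest (largest) category points, taking the extremum over both sex
#' strata for sex-stratified factors.
#'
#' @param card A `scorecard`.
#' @return Named integer vector `c(min = ..., max = ...)`.
#' @examples
#' theoretical_range(build_scorecard("anu_adri_map"))   # -13, 64
#' theoretical_range(build_scorecard("anu_adri_cvhs"))  # -11, 56
#' @export
theoretical_range <- function(card) {
  stopifnot(inherits(card, "scorecard"))
  per_factor <- vapply(card$factors, function(f) {
    pts <- vapply(factor_categories(f), `[[`, numeric(1), "points")
    c(min(pts), max(pts))
  }, numeric(2))
  out <- as.integer(rowSums(per_factor))
  c(min = out[1], max = out[2])
}

#' Convert a pooled risk ratio to integer index points
#'
#' Point weights for an additive risk index are derived from pooled relative
#' risk estimates: the log risk ratio (the beta-weight of the factor) is
#' multiplied by a scaling constant and rounded to the nearest integer, half
#' away from zero. Protective factors (risk ratio < 1) yield negative points.
#' The bundled point tables, not this function, are the source of truth for
#' the index weights; this exposes the derivation rule for extending the
#' index with new factors.
#'
#' @param risk_ratio Pooled risk/odds ratio, > 0.
#' @param scale Positive multiplicative constant applied to the log ratio.
#' @return Integer points.
#' @examples
#' derive_points(1.0, 10)   # 0
#' derive_points(0.5, 10)   # -7
#' @export
derive_points <- function(risk_ratio, scale) {
  if (!is.numeric(risk_ratio) || any(!is.finite(risk_ratio)) || any(risk_ratio <= 0))
    stop("risk_ratio must be positive and finite", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a positive number", call. = FALSE)
  x <- scale * log(risk_ratio)
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' @export
print.scorecard <- function(x, ...) {
  nms <- scorecard_factors(x, counted = TRUE)
  cat("<scorecard> ", x$name, "\n", sep = "")
  cat("  factors (", attr(nms, "n_counted"), " counted): ",
      paste(nms, collapse = ", "), "\n", sep = "")
  r <- theoretical_range(x)
  cat("  theoretical range: ", r["min"], " to ", r["max"], "\n", sep = "")
  invisible(x)
}

#' @export
format.scorecard <- function(x, ...) {
  lines <- character(0)
  for (f in x$factors) {
    lines <- c(lines, paste0(f$name, ":"))
    show <- function(cats, prefix = "  ") {
      vapply(cats, function(cat)
        sprintf("%s%-16s %3d", prefix, cat$label, as.integer(cat$points)),
        character(1))
    }
    if (isTRUE(f$stratified_by_sex)) {
      lines <- c(lines, "  [male]", show(f$strata$male, "    "),
                 "  [female]", show(f$strata$female, "    "))
    } else {
      lines <- c(lines, show(f$categories))
    }
  }
  lines
}
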