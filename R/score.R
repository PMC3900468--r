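# Per-factor point lookup. Returns a numeric vector of points (NA = missing)
# for all rows of `data` under factor `f`; errors on unknown category labels.
factor_points <- function(f, data) {
  n <- nrow(data)
  lookup <- function(labels, cats) {
    labs <- vapply(cats, `[[`, character(1), "label")
    pts <- vapply(cats, `[[`, numeric(1), "points")
    bad <- !is.na(labels) & is.na(match(labels, labs))
    if (any(bad))
      stop("unknown category label(s) for factor '", f$name, "': ",
           paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
    pts[match(labels, labs)]
  }
  age_points <- function(age, cats) {
    out <- rep(NA_real_, length(age))
    a <- floor(age)
    for (cat in cats) {
      lo <- if (is.null(cat$age_min)) -Inf else cat$age_min
      hi <- if (is.null(cat$age_max)) Inf else cat$age_max
      sel <- !is.na(a) & a >= lo & a <= hi
      out[sel] <- cat$points
    }
    out
  }
  src <- f$source %||% "column"
  if (src == "age") {
    if (is.null(data$age)) stop("data lacks an 'age' column", call. = FALSE)
    if (isTRUE(f$stratified_by_sex)) {
      if (is.null(data$sex)) stop("data lacks a 'sex' column", call. = FALSE)
      out <- rep(NA_real_, n)
      for (s in c("male", "female")) {
        sel <- !is.na(data$sex) & data$sex == s
        out[sel] <- age_points(data$age[sel], f$strata[[s]])
      }
      out
    } else {
      age_points(data$age, f$categories)
    }
  } else if (src == "sex") {
    if (is.null(data$sex)) stop("data lacks a 'sex' column", call. = FALSE)
    lookup(as.character(data$sex), f$categories)
  } else {
    col <- data[[f$name]]
    if (is.null(col)) return(rep(NA_real_, n))
    col <- as.character(col)
    col[!is.na(col) & col == ""] <- NA_character_
    lookup(col, f$categories)
  }
}

#' Score a cohort table against a scorecard
#'
#' Computes the additive index score for every row of a participant table:
#' the sum over the scorecard's factors of the points of the category each
#' participant falls in, with age points taken from the sex-matched stratum.
#'
#' @param data Data frame with one row per participant. Must contain `age`
#'   and `sex` (values `"male"`/`"female"`) plus one column per
#'   column-sourced factor of the card holding category labels; empty
#'   strings and `NA` are treated as missing. If a `baseline_dementia`
#'   column is present, prevalent cases (value 1) are refused — exclude them
#'   first (see [filter_analysis_set()]).
#' @param card A `scorecard` from [build_scorecard()] or [read_scorecard()].
#' @param missing_policy `"strict"` (default) errors if any required factor
#'   value is missing, matching a complete-case analysis; `"skip"` lets
#'   missing factors contribute 0 points and records them.
#' @return Data frame with columns `id` (taken from `data$id`, or row number),
#'   `score` (integer), `n_factors_used`, and `missing_factors`
#'   (comma-separated names, `""` if none).
#' @examples
#' card <- build_scorecard("anu_adri_common")
#' d <- data.frame(id = "p1", sex = "female", age = 72, education = ">11",
#'                 diabetes = "no", smoking = "never", alcohol = "light_moderate")
#' score_cohort(d, card)
#' @export
score_cohort <- function(data, card, missing_policy = c("strict", "skip")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(card, "scorecard"), is.data.frame(data))
  if (nrow(data) == 0L) stop("empty participant table", call. = FALSE)
  if (!is.null(data$baseline_dementia) && any(data$baseline_dementia == 1, na.rm = TRUE))
    stop("participant table contains baseline dementia cases; ",
         "exclude them before scoring (filter_analysis_set)", call. = FALSE)

  pts <- vapply(card$factors, factor_points, numeric(nrow(data)), data = data)
  pts <- matrix(pts, nrow = nrow(data))  # guard n = 1
  colnames(pts) <- scorecard_factors(card)
  miss <- is.na(pts)
  if (missing_policy == "strict" && any(miss)) {
    bad <- colnames(pts)[colSums(miss) > 0]
    stop("missing factor value(s) under strict policy: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  contrib <- pts
  contrib[miss] <- 0
  ids <- if (!is.null(data$id)) as.character(data$id) else as.character(seq_len(nrow(data)))
  missing_factors <- apply(miss, 1L, function(m)
    paste(colnames(pts)[m], collapse = ","))
  data.frame(
    id = ids,
    score = as.integer(rowSums(contrib)),
    n_factors_used = as.integer(rowSums(!miss)),
    missing_factors = missing_factors,
    stringsAsFactors = FALSE
  )
}

#' Score a single participant
#'
#' Convenience wrapper around [score_cohort()] for one record.
#'
#' @param p Named list or one-row data frame with the fields described in
#'   [score_cohort()].
#' @inheritParams score_cohort
#' @return A list with `id`, `score`, `n_factors_used` and `missing_factors`
#'   (character vector, possibly empty).
#' @export
score_participant <- function(p, card, missing_policy = c("strict", "skip")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.data.frame(p)) {
    p <- lapply(p, function(x) if (is.null(x)) NA else x)
    p <- as.data.frame(p, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(p) == 1L)
  res <- score_cohort(p, card, missing_policy)
  mf <- res$missing_factors[1]
  list(
    id = res$id[1],
    score = res$score[1],
    n_factors_used = res$n_factors_used[1],
    missing_factors = if (nzchar(mf)) strsplit(mf, ",", fixed = TRUE)[[1]] else character(0)
  )
}
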