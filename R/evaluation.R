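#' @importFrom survival coxph Surv
#' @importFrom stats quantile qnorm var median chisq.test
NULL

outcome_column <- function(outcome) {
  switch(outcome,
         ad = "event_ad",
         any_dementia = "event_dementia",
         stop("unknown outcome '", outcome, "'", call. = FALSE))
}

# per-row missingness indicator matrix for the card's factors
missing_matrix <- function(data, card) {
  m <- vapply(card$factors, function(f) is.na(factor_points(f, data)),
              logical(nrow(data)))
  m <- matrix(m, nrow = nrow(data))
  colnames(m) <- scorecard_factors(card)
  m
}

#' Build the complete-case analysis set
#'
#' Applies the exclusions of a complete-case validation analysis, in order:
#' prevalent (baseline) dementia cases, records with a missing outcome or
#' missing/negative follow-up time, and — under the strict policy — records
#' missing any factor required by the scorecard. Counts per exclusion reason
#' are recorded (each record is counted once, under the first applicable
#' reason).
#'
#' @param data Participant data frame (see [score_cohort()] for the layout).
#' @param card Scorecard defining the required factors.
#' @param outcome `"ad"` or `"any_dementia"`.
#' @param missing_policy `"strict"` (complete cases, default) or `"skip"`.
#' @return An `analysis_set`: list with `data` (retained rows), `exclusions`
#'   (named counts), `n_input` and `n_retained`.
#' @export
filter_analysis_set <- function(data, card,
                                outcome = c("ad", "any_dementia"),
                                missing_policy = c("strict", "skip")) {
  outcome <- match.arg(outcome)
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("empty cohort", call. = FALSE)
  ev <- outcome_column(outcome)
  if (is.null(data[[ev]])) stop("cohort lacks outcome column '", ev, "'", call. = FALSE)

  base <- !is.na(data$baseline_dementia %||% rep(0L, nrow(data))) &
    (data$baseline_dementia %||% rep(0L, nrow(data))) == 1L
  miss_out <- !base & is.na(data[[ev]])
  bad_fu <- !base & !miss_out &
    (is.na(data$followup_years) | data$followup_years < 0)
  keep <- !(base | miss_out | bad_fu)
  incomplete <- rep(FALSE, nrow(data))
  if (missing_policy == "strict" && any(keep)) {
    mm <- missing_matrix(data[keep, , drop = FALSE], card)
    incomplete[keep] <- rowSums(mm) > 0
    keep <- keep & !incomplete
  }
  if (!any(keep)) stop("no participants remain after exclusions", call. = FALSE)
  structure(list(
    data = data[keep, , drop = FALSE],
    exclusions = c(baseline_dementia = sum(base),
                   missing_outcome = sum(miss_out),
                   missing_followup = sum(bad_fu),
                   incomplete_factors = sum(incomplete)),
    outcome = outcome,
    n_input = nrow(data),
    n_retained = sum(keep)
  ), class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat("<analysis_set> ", x$n_retained, "/", x$n_input, " retained (outcome: ",
      x$outcome, ")\n", sep = "")
  ex <- x$exclusions[x$exclusions > 0]
  if (length(ex))
    cat("  excluded:", paste(names(ex), ex, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

new_auc_result <- function(auc, ci_low, ci_high, n_cases, n_controls,
                           outcome = NA_character_, subgroup = NA_character_) {
  structure(list(auc = auc, ci_low = ci_low, ci_high = ci_high,
                 n_cases = n_cases, n_controls = n_controls,
                 outcome = outcome, subgroup = subgroup),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f", x$auc))
  if (!is.na(x$ci_low)) cat(sprintf(" (%.3f-%.3f)", x$ci_low, x$ci_high))
  cat(sprintf("  [%d cases / %d controls]\n", x$n_cases, x$n_controls))
  invisible(x)
}

check_binary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both cases and controls are required", call. = FALSE)
  list(scores = scores, labels = labels)
}

#' Concordance statistic (AUC) of a score for a binary outcome
#'
#' The probability that a randomly chosen case scores higher than a randomly
#' chosen control, ties counted half — the Mann-Whitney form of the area
#' under the ROC curve, computed from midranks.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = incident case, 0 = control).
#' @return An `auc_result` (point estimate only; CI fields are `NA`).
#' @examples
#' c_statistic(c(3, 1, 2, 0), c(1, 1, 0, 0))  # 0.75
#' @export
c_statistic <- function(scores, labels) {
  z <- check_binary(scores, labels)
  n1 <- sum(z$labels == 1L); n0 <- sum(z$labels == 0L)
  r <- rank(z$scores)
  auc <- (sum(r[z$labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  new_auc_result(auc, NA_real_, NA_real_, n1, n0)
}

# DeLong placement variance via midranks
delong_se <- function(scores, labels) {
  x <- scores[labels == 1L]; y <- scores[labels == 0L]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  sqrt(var(v10) / m + var(v01) / n)
}

#' Confidence interval for the c-statistic
#'
#' DeLong's placement-based variance estimate (default) with a normal-theory
#' interval truncated to \[0, 1\]; degenerate inputs with zero estimated
#' variance return a zero-width interval at the point estimate. A seeded
#' percentile bootstrap is available for cross-checking.
#'
#' @inheritParams c_statistic
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @return An `auc_result` with `ci_low`/`ci_high` filled.
#' @export
auc_confidence_interval <- function(scores, labels, level = 0.95,
                                    method = c("delong", "bootstrap"),
                                    n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  z <- check_binary(scores, labels)
  if (sum(z$labels == 1L) < 2L || sum(z$labels == 0L) < 2L)
    stop("need at least 2 cases and 2 controls for a confidence interval",
         call. = FALSE)
  res <- c_statistic(z$scores, z$labels)
  if (method == "delong") {
    se <- delong_se(z$scores, z$labels)
    zq <- qnorm((1 + level) / 2)
    res$ci_low <- max(0, res$auc - zq * se)
    res$ci_high <- min(1, res$auc + zq * se)
  } else {
    set.seed(seed)
    n <- length(z$scores)
    boots <- replicate(n_boot, {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(z$labels[i])) < 2L) return(NA_real_)
      c_statistic(z$scores[i], z$labels[i])$auc
    })
    ci <- quantile(boots, c((1 - level) / 2, (1 + level) / 2), na.rm = TRUE,
                   names = FALSE)
    res$ci_low <- ci[1]; res$ci_high <- ci[2]
  }
  res
}

#' Assign within-sample score quartiles
#'
#' Cut points are the 25th/50th/75th sample percentiles under the
#' linear-interpolation quantile definition; intervals are half-open on the
#' left — `(-Inf, q25], (q25, q50], (q50, q75], (q75, Inf)` — so a score
#' tied with a boundary falls in the lower quartile, matching the
#' "x.1 – y" style of printed quartile ranges. With heavily tied scores,
#' coincident cut points are collapsed (with a warning) and the affected
#' quartiles are merged downward.
#'
#' @param scores Numeric scores.
#' @return List with `labels` (integer quartile 1–4 per score) and
#'   `boundaries` (the three cut points).
#' @export
assign_quartiles <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no scores to split", call. = FALSE)
  q <- quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  breaks <- unique(q)
  if (length(breaks) < 3L)
    warning("degenerate score distribution: quartile boundaries coincide",
            call. = FALSE)
  labels <- as.integer(cut(scores, breaks = c(-Inf, breaks, Inf), right = TRUE,
                           labels = FALSE))
  list(labels = labels, boundaries = stats::setNames(q, c("q25", "q50", "q75")))
}

#' Incidence per 1000 person-years by quartile
#'
#' @param followup_years Follow-up time per participant.
#' @param events Binary event indicator.
#' @param quartiles Integer quartile labels (from [assign_quartiles()]).
#' @return Data frame with per-quartile `n`, `events`, `person_years`,
#'   `incidence_per_1000py`, and `zero_events` (flagging quartiles whose
#'   rate is 0 and hence has a very wide implicit interval).
#' @export
incidence_rates <- function(followup_years, events, quartiles) {
  stopifnot(length(followup_years) == length(events),
            length(events) == length(quartiles))
  qs <- sort(unique(quartiles))
  out <- do.call(rbind, lapply(qs, function(q) {
    sel <- quartiles == q
    py <- sum(followup_years[sel])
    ev <- sum(events[sel])
    if (py <= 0) stop("zero person-years in quartile ", q, call. = FALSE)
    data.frame(quartile = q, n = sum(sel), events = ev, person_years = py,
               incidence_per_1000py = 1000 * ev / py,
               zero_events = ev == 0L)
  }))
  rownames(out) <- NULL
  out
}

#' Cox quartile hazard ratios with a linear trend test
#'
#' Fits a proportional-hazards model with indicator covariates for quartiles
#' 2–4 against quartile 1 (Breslow tie handling by default) and reports
#' hazard ratios with Wald confidence intervals, plus a separate model with
#' the quartile entered as an ordinal 1–4 covariate whose Wald p-value is the
#' linear trend test. Quartiles whose likelihood is monotone (no events, or
#' complete separation) are flagged and their interval marked unbounded
#' rather than silently reported.
#'
#' @param followup_years Follow-up time per participant.
#' @param events Binary event indicator.
#' @param quartiles Integer quartile labels.
#' @param scores Optional numeric scores used to report the per-quartile
#'   median and range.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param level Confidence level for the Wald intervals.
#' @return A `quartile_analysis`: list with `table` (per-quartile summary:
#'   `n`, `events`, `person_years`, `incidence_per_1000py`, score summaries,
#'   `hazard_ratio`, `hr_ci_low`, `hr_ci_high`, `unbounded`), `trend_p`,
#'   `ties` and `notes`.
#' @export
cox_quartile_hr <- function(followup_years, events, quartiles, scores = NULL,
                            ties = c("breslow", "efron"), level = 0.95) {
  ties <- match.arg(ties)
  inc <- incidence_rates(followup_years, events, quartiles)
  notes <- character(0)
  qs <- inc$quartile
  if (inc$events[1] == 0L)
    stop("no events in the reference quartile", call. = FALSE)

  tab <- inc
  if (!is.null(scores)) {
    tab$median_score <- vapply(qs, function(q) median(scores[quartiles == q]), numeric(1))
    tab$score_min <- vapply(qs, function(q) min(scores[quartiles == q]), numeric(1))
    tab$score_max <- vapply(qs, function(q) max(scores[quartiles == q]), numeric(1))
  }
  tab$hazard_ratio <- 1
  tab$hr_ci_low <- NA_real_
  tab$hr_ci_high <- NA_real_
  tab$unbounded <- FALSE

  if (length(qs) < 2L) {
    notes <- c(notes, "single quartile level: no contrast to estimate")
    trend_p <- 1
  } else {
    qf <- factor(quartiles, levels = qs)
    d <- data.frame(time = followup_years, ev = events, qf = qf,
                    qord = as.numeric(as.character(quartiles)))
    warn <- character(0)
    fit <- withCallingHandlers(
      coxph(Surv(time, ev) ~ qf, data = d, ties = ties),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    zq <- qnorm((1 + level) / 2)
    for (k in seq_len(nrow(sm))) {
      i <- k + 1L  # row in tab (reference is first)
      b <- sm[k, "coef"]; se <- sm[k, "se(coef)"]
      unb <- !is.finite(b) || !is.finite(se) || se > 50 || abs(b) > 15
      tab$hazard_ratio[i] <- exp(b)
      tab$hr_ci_low[i] <- if (unb) 0 else exp(b - zq * se)
      tab$hr_ci_high[i] <- if (unb) Inf else exp(b + zq * se)
      tab$unbounded[i] <- unb
    }
    if (any(tab$unbounded))
      notes <- c(notes, "monotone likelihood in at least one quartile; its CI is unbounded")
    if (length(warn)) notes <- c(notes, paste("coxph:", warn))
    tfit <- withCallingHandlers(
      coxph(Surv(time, ev) ~ qord, data = d, ties = ties),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    trend_p <- summary(tfit)$coefficients[1, "Pr(>|z|)"]
  }
  structure(list(table = tab, trend_p = trend_p, ties = ties, notes = notes),
            class = "quartile_analysis")
}

#' @export
print.quartile_analysis <- function(x, ...) {
  cat("<quartile_analysis> (ties: ", x$ties, ")\n", sep = "")
  print(x$table, digits = 4)
  cat(sprintf("P for linear trend: %.4g\n", x$trend_p))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Full quartile dose-response analysis of an index score
#'
#' Convenience wrapper: assigns within-sample quartiles, computes incidence
#' per 1000 person-years, and fits the quartile Cox model with trend test.
#'
#' @param set An `analysis_set` from [filter_analysis_set()].
#' @param scores Scores aligned with `set$data` (e.g. from [score_cohort()]).
#' @param outcome `"ad"` or `"any_dementia"`.
#' @inheritParams cox_quartile_hr
#' @return A `quartile_analysis` with quartile `boundaries` attached.
#' @export
quartile_analysis <- function(set, scores, outcome = c("ad", "any_dementia"),
                              ties = c("breslow", "efron"), level = 0.95) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(set, "analysis_set"), length(scores) == nrow(set$data))
  qa <- assign_quartiles(scores)
  res <- cox_quartile_hr(set$data$followup_years,
                         set$data[[outcome_column(outcome)]],
                         qa$labels, scores = scores, ties = ties, level = level)
  res$boundaries <- qa$boundaries
  res$outcome <- outcome
  res
}

#' Discrimination report for an index over outcomes and subgroups
#'
#' Reproduces the standard external-validation discrimination table: the
#' c-statistic with confidence interval for each outcome (AD, any dementia)
#' overall and by sex, plus a rerun on the common-variable scorecard (age,
#' sex, education, diabetes, smoking, alcohol) scored on the *same*
#' participants as the full card — no re-filtering — with the difference
#' against the full-card overall AUC recorded. The c-statistic is computed
#' on incident-case status over follow-up, not on a time-dependent risk set.
#'
#' @param data Participant data frame.
#' @param card Scorecard used for the primary score.
#' @param outcomes Outcomes to evaluate.
#' @param subgroups Any of `"overall"`, `"male"`, `"female"`.
#' @param common_card Scorecard for the common-variable rerun, or `NULL` to
#'   skip it.
#' @param missing_policy Passed to [filter_analysis_set()].
#' @param level Confidence level.
#' @return Data frame (class `auc_report`) with one row per card x outcome x
#'   subgroup: `n`, `n_cases`, `n_controls`, `auc`, `ci_low`, `ci_high`, and
#'   `diff_vs_full` (common-card rows only).
#' @export
evaluate_index <- function(data, card,
                           outcomes = c("ad", "any_dementia"),
                           subgroups = c("overall", "male", "female"),
                           common_card = build_scorecard("anu_adri_common"),
                           missing_policy = c("strict", "skip"),
                           level = 0.95) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(all(subgroups %in% c("overall", "male", "female")))
  rows <- list()
  for (outcome in outcomes) {
    set <- filter_analysis_set(data, card, outcome, missing_policy)
    d <- set$data
    scores <- score_cohort(d, card, missing_policy)$score
    labels <- d[[outcome_column(outcome)]]
    full_overall <- NA_real_
    for (sg in subgroups) {
      idx <- if (sg == "overall") rep(TRUE, nrow(d)) else (!is.na(d$sex) & d$sex == sg)
      if (!any(idx)) stop("empty subgroup '", sg, "'", call. = FALSE)
      if (length(unique(labels[idx])) < 2L)
        stop("subgroup '", sg, "' has a single outcome class", call. = FALSE)
      r <- auc_confidence_interval(scores[idx], labels[idx], level = level)
      if (sg == "overall") full_overall <- r$auc
      rows[[length(rows) + 1L]] <- data.frame(
        card = card$name, outcome = outcome, subgroup = sg,
        n = sum(idx), n_cases = r$n_cases, n_controls = r$n_controls,
        auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
        diff_vs_full = NA_real_, stringsAsFactors = FALSE)
    }
    if (!is.null(common_card)) {
      cs <- score_cohort(d, common_card, missing_policy)$score
      r <- auc_confidence_interval(cs, labels, level = level)
      rows[[length(rows) + 1L]] <- data.frame(
        card = common_card$name, outcome = outcome, subgroup = "common_variables",
        n = nrow(d), n_cases = r$n_cases, n_controls = r$n_controls,
        auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
        diff_vs_full = r$auc - full_overall, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("auc_report", class(out))
  out
}

#' Compare dementia case proportions by quartile across an age split
#'
#' Splits the filtered sample at `split_age` (quartiles are computed on the
#' *full* sample first), then for each quartile tests the 2x2 association of
#' age group with incident case status using Pearson's chi-square without
#' continuity correction (1 df). Quartiles with an empty age group are
#' reported with an undefined (NA) statistic.
#'
#' @param data Participant data frame.
#' @param card Scorecard to score with.
#' @param split_age Age cut (default 70: young-old below, old-old at or above).
#' @param outcome Outcome defining a case (default `"any_dementia"`).
#' @param missing_policy Passed to [filter_analysis_set()].
#' @return Data frame (class `age_split`) with per-quartile young/old counts,
#'   case counts, percentages, `chi_square` and `p_value`; quartile score
#'   ranges and the split age are attached as attributes.
#' @export
age_split_comparison <- function(data, card, split_age = 70,
                                 outcome = "any_dementia",
                                 missing_policy = c("strict", "skip")) {
  missing_policy <- match.arg(missing_policy)
  set <- filter_analysis_set(data, card, outcome, missing_policy)
  d <- set$data
  scores <- score_cohort(d, card, missing_policy)$score
  young <- d$age < split_age
  if (!any(young) || all(young))
    stop("both age groups must be non-empty at split_age = ", split_age,
         call. = FALSE)
  qa <- assign_quartiles(scores)
  cases <- d[[outcome_column(outcome)]] == 1L
  rows <- lapply(sort(unique(qa$labels)), function(q) {
    sel <- qa$labels == q
    ny <- sum(sel & young); no <- sum(sel & !young)
    cy <- sum(sel & young & cases); co <- sum(sel & !young & cases)
    chi <- p <- NA_real_
    if (ny > 0 && no > 0) {
      tab <- rbind(c(cy, ny - cy), c(co, no - co))
      if (all(colSums(tab) > 0)) {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        chi <- unname(ct$statistic); p <- unname(ct$p.value)
      }
    }
    data.frame(quartile = q,
               score_min = min(scores[sel]), score_max = max(scores[sel]),
               n_young = ny, cases_young = cy,
               pct_young = if (ny > 0) 100 * cy / ny else NA_real_,
               n_old = no, cases_old = co,
               pct_old = if (no > 0) 100 * co / no else NA_real_,
               chi_square = chi, p_value = p)
  })
  out <- do.call(rbind, rows)
  attr(out, "split_age") <- split_age
  attr(out, "boundaries") <- qa$boundaries
  attr(out, "outcome") <- outcome
  class(out) <- c("age_split", class(out))
  out
}
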