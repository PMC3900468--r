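# Independent oracles used to cross-check the implementation.

# Exhaustive pairwise concordance count: P(case > control) + 0.5 P(tie).
brute_force_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

# Cox partial log-likelihood for a single covariate, Breslow tie handling.
breslow_loglik <- function(b, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(event == 1 & time == t)
    risk <- which(time >= t)
    ll <- ll + b * sum(x[d]) - length(d) * log(sum(exp(b * x[risk])))
  }
  ll
}

# Numeric maximization of the Breslow partial likelihood.
grid_max_cox <- function(time, event, x, interval = c(-10, 10)) {
  stats::optimize(breslow_loglik, interval = interval, maximum = TRUE,
                  time = time, event = event, x = x, tol = 1e-10)$maximum
}

# Points of a category looked up directly from the scorecard object: an
# independent per-factor re-computation used to check additivity.
card_points <- function(card, factor_name, label, sex = NULL) {
  f <- card$factors[[match(factor_name, scorecard_factors(card))]]
  cats <- if (isTRUE(f$stratified_by_sex)) f$strata[[sex]] else f$categories
  labs <- vapply(cats, `[[`, character(1), "label")
  cats[[match(label, labs)]]$points
}

# Small hand-built cohort table for IO and filter tests.
tiny_cohort <- function() {
  data.frame(
    id = c("a", "b", "c"),
    sex = c("female", "male", "female"),
    age = c(72, 66, 81),
    education = c(">11", "8-11", "<8"),
    diabetes = c("no", "yes", "no"),
    depression = c("no", "no", "yes"),
    smoking = c("never", "current", "former"),
    alcohol = c("light_moderate", "abstainer", "abstainer"),
    physical_activity = c("high", "low", "medium"),
    fish_intake = c("0.26-2.0", "0-0.25", "2.1-4.0"),
    followup_years = c(5.2, 3.1, 6.4),
    event_ad = c(0L, 1L, 0L),
    event_dementia = c(0L, 1L, 1L),
    baseline_dementia = c(0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}
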