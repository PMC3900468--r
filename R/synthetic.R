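# Cohort presets: marginal category frequencies of the three published
# validation cohorts (observed counts, normalized at config build time),
# per-sex age-band counts, and follow-up length. The joint distribution is
# NOT published, so factors are sampled independently — a documented
# simplification. CAIDE-specific binary prevalences are invented plumbing so
# the comparator index can be exercised end to end.
.age_bands <- data.frame(
  label = c("<65", "65-69", "70-74", "75-79", "80-84", "85-89", ">=90"),
  lo = c(-Inf, 65, 70, 75, 80, 85, 90),
  hi = c(64, 69, 74, 79, 84, 89, 99),
  stringsAsFactors = FALSE
)

.cohort_presets <- list(
  map_like = list(
    scorecard_variant = "anu_adri_map",
    male_prob = 300 / 1164,
    age_floor = 54,
    age_counts = list(
      male   = c(6, 12, 39, 69, 104, 53, 17),
      female = c(40, 73, 98, 199, 247, 149, 57)
    ),
    category_counts = list(
      education          = c("<8" = 42, "8-11" = 60, ">11" = 1061),
      diabetes           = c(no = 1016, yes = 147),
      tbi                = c(no = 1098, yes = 65),
      cognitive_activity = c(low = 408, moderate = 600, high = 155),
      social_network     = c(high = 97, medium_high = 328, medium_low = 422, low = 125),
      smoking            = c(never = 685, former = 432, current = 44),
      alcohol            = c(abstainer = 193, light_moderate = 887, heavy = 80),
      physical_activity  = c(low = 465, medium = 495, high = 203)
    ),
    caide_prevalence = c(low_education = 0.06, hypercholesterolaemia = 0.25,
                         high_systolic_bp = 0.40, physical_inactivity = 0.38,
                         obesity = 0.20),
    censor_time_mean = 3.5
  ),
  kp_like = list(
    scorecard_variant = "anu_adri_kp",
    male_prob = 325 / 1301,
    age_floor = 74,
    age_counts = list(
      male   = c(0, 0, 6, 141, 106, 50, 22),
      female = c(0, 0, 15, 376, 306, 194, 85)
    ),
    category_counts = list(
      education      = c("<8" = 654, "8-11" = 253, ">11" = 389),
      diabetes       = c(no = 1187, yes = 114),
      tbi            = c(no = 877, yes = 86),
      social_network = c(high = 13, medium_high = 226, medium_low = 880, low = 84),
      smoking        = c(never = 867, current = 104),
      alcohol        = c(abstainer = 391, light_moderate = 577, heavy = 0)
    ),
    caide_prevalence = c(low_education = 0.60, hypercholesterolaemia = 0.25,
                         high_systolic_bp = 0.45, physical_inactivity = 0.50,
                         obesity = 0.12),
    censor_time_mean = 6.0
  ),
  cvhs_like = list(
    scorecard_variant = "anu_adri_cvhs",
    male_prob = 1381 / 3375,
    age_floor = 62,
    age_counts = list(
      male   = c(30, 356, 607, 263, 86, 24, 3),
      female = c(62, 626, 787, 355, 123, 18, 1)
    ),
    category_counts = list(
      education         = c("<8" = 367, "8-11" = 439, ">11" = 2537),
      diabetes          = c(no = 2805, yes = 537),
      depression        = c(no = 2811, yes = 180),
      smoking           = c(never = 1558, former = 1426, current = 364),
      alcohol           = c(abstainer = 1585, light_moderate = 1634, heavy = 129),
      physical_activity = c(low = 993, medium = 1677, high = 671),
      fish_intake       = c("0-0.25" = 388, "0.26-2.0" = 1168,
                            "2.1-4.0" = 1263, ">=4.1" = 119)
    ),
    caide_prevalence = c(low_education = 0.18, hypercholesterolaemia = 0.25,
                         high_systolic_bp = 0.40, physical_inactivity = 0.30,
                         obesity = 0.20),
    censor_time_mean = 6.0
  )
)

#' Configuration for a synthetic validation cohort
#'
#' Builds a validated configuration object for the seeded cohort generator.
#' Defaults reproduce the marginal risk-factor frequencies, sex ratio,
#' age-band distribution and mean follow-up of the named published cohort;
#' the time-to-dementia process is a proportional-hazards model in the index
#' score with exponential event and censoring times.
#'
#' @param cohort `"map_like"`, `"kp_like"` or `"cvhs_like"` — which published
#'   cohort's marginals and factor availability to emulate.
#' @param n Number of participants.
#' @param beta_per_point Log-hazard increment per index point (default 0.05).
#' @param baseline_hazard Yearly dementia hazard of an average-scoring
#'   participant (default 0.02).
#' @param ad_fraction Probability an incident dementia is Alzheimer's disease
#'   (default 0.75, the commonly cited share of AD among dementias).
#' @param censor_time_mean Mean of the exponential censoring time in years;
#'   defaults to the cohort's published mean/median follow-up (3.5 years for
#'   `map_like`, 6 for the others).
#' @param missing_rate Per-cell probability that a factor value is missing
#'   after generation (default 0, i.e. complete data).
#' @param baseline_dementia_rate Probability a participant is a prevalent
#'   case at baseline (default 0).
#' @param category_probs Optional named list overriding category probability
#'   vectors for specific factors (names must match the scorecard's labels).
#' @param seed Integer seed; every generator draw is a deterministic function
#'   of the configuration and this seed.
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config("cvhs_like", n = 500, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' head(cohort$participants)
#' @export
synthetic_config <- function(cohort = c("cvhs_like", "map_like", "kp_like"),
                             n,
                             beta_per_point = 0.05,
                             baseline_hazard = 0.02,
                             ad_fraction = 0.75,
                             censor_time_mean = NULL,
                             missing_rate = 0,
                             baseline_dementia_rate = 0,
                             category_probs = NULL,
                             seed = 1L) {
  cohort <- match.arg(cohort)
  preset <- .cohort_presets[[cohort]]
  n <- as.integer(n)
  stopifnot(n >= 1L, baseline_hazard > 0, ad_fraction >= 0, ad_fraction <= 1,
            missing_rate >= 0, missing_rate < 1,
            baseline_dementia_rate >= 0, baseline_dementia_rate < 1)
  seed <- as.integer(seed)
  stopifnot(is.finite(seed))

  card <- build_scorecard(preset$scorecard_variant)
  probs <- lapply(preset$category_counts, normalize_probs)
  if (!is.null(category_probs)) {
    stopifnot(is.list(category_probs))
    for (fn in names(category_probs)) {
      if (!fn %in% names(probs))
        stop("category_probs refers to factor '", fn, "' not in the ",
             cohort, " scorecard", call. = FALSE)
      p <- normalize_probs(category_probs[[fn]])
      if (!setequal(names(p), names(probs[[fn]])))
        stop("category_probs for '", fn, "' must name categories ",
             paste(names(probs[[fn]]), collapse = ", "), call. = FALSE)
      probs[[fn]] <- p[names(probs[[fn]])]
    }
  }
  # sanity: probability names match the card's category labels
  for (f in card$factors) {
    if ((f$source %||% "column") != "column") next
    labs <- vapply(f$categories, `[[`, character(1), "label")
    if (!setequal(labs, names(probs[[f$name]])))
      stop("preset categories for '", f$name, "' do not match the scorecard",
           call. = FALSE)
  }

  structure(list(
    cohort = cohort,
    n = n,
    scorecard_variant = preset$scorecard_variant,
    male_prob = preset$male_prob,
    age_floor = preset$age_floor,
    age_probs = lapply(preset$age_counts, normalize_probs),
    category_probs = probs,
    caide_prevalence = preset$caide_prevalence,
    beta_per_point = beta_per_point,
    baseline_hazard = baseline_hazard,
    ad_fraction = ad_fraction,
    censor_time_mean = censor_time_mean %||% preset$censor_time_mean,
    missing_rate = missing_rate,
    baseline_dementia_rate = baseline_dementia_rate,
    seed = seed
  ), class = "synthetic_config")
}

#' Draw baseline risk-factor profiles
#'
#' Samples participant records without outcomes: sex first, then an age band
#' conditional on sex, then a uniform integer age within the band (the
#' open-ended top band uses ages 90–99; the bottom band is floored at the
#' cohort's minimum age), then each categorical factor independently from its
#' marginal distribution, plus the binary CAIDE comparator variables.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed for this draw; defaults to `config$seed`.
#' @return Data frame of baseline records with outcome columns unset (`NA`).
#' @export
sample_factors <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(config$male_prob, 1 - config$male_prob))
  age <- integer(n)
  for (s in c("male", "female")) {
    idx <- which(sex == s)
    if (!length(idx)) next
    band <- sample.int(nrow(.age_bands), length(idx), replace = TRUE,
                       prob = config$age_probs[[s]])
    lo <- pmax(.age_bands$lo[band], config$age_floor)
    hi <- .age_bands$hi[band]
    age[idx] <- as.integer(lo + floor(stats::runif(length(idx)) * (hi - lo + 1)))
  }
  out <- data.frame(id = sprintf("p%06d", seq_len(n)), sex = sex, age = age,
                    stringsAsFactors = FALSE)
  for (fn in names(config$category_probs)) {
    p <- config$category_probs[[fn]]
    out[[fn]] <- names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  }
  for (fn in names(config$caide_prevalence)) {
    out[[fn]] <- c("no", "yes")[1L + stats::rbinom(n, 1L, config$caide_prevalence[[fn]])]
  }
  out$followup_years <- NA_real_
  out$event_dementia <- NA_integer_
  out$event_ad <- NA_integer_
  out$baseline_dementia <- NA_integer_
  out
}

#' Attach a proportional-hazards dementia outcome
#'
#' Scores the sampled records with the configured scorecard variant and draws
#' an exponential event time with rate
#' `baseline_hazard * exp(beta_per_point * (score - mean(score)))` — centring
#' keeps `baseline_hazard` interpretable as the hazard of an average-scoring
#' participant — and an independent exponential censoring time with mean
#' `censor_time_mean`. Follow-up is the minimum of the two; an observed event
#' is Alzheimer's disease with probability `ad_fraction`.
#'
#' @param participants Output of [sample_factors()] (complete factor data).
#' @param config The same [synthetic_config()].
#' @param seed Seed for the outcome draw; defaults to `config$seed + 1` so
#'   the outcome stream is independent of the factor-sampling stream.
#' @return A `synthetic_cohort`: list with `participants` (outcome columns
#'   filled), `config`, and `true_scores` (named integer vector).
#' @export
simulate_outcome <- function(participants, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"), is.data.frame(participants))
  if (config$censor_time_mean <= 0)
    stop("censor_time_mean must be > 0", call. = FALSE)
  card <- build_scorecard(config$scorecard_variant)
  sc <- score_cohort(participants[setdiff(names(participants), "baseline_dementia")],
                     card, missing_policy = "strict")
  set.seed(seed)
  n <- nrow(participants)
  score <- sc$score
  rate <- config$baseline_hazard * exp(config$beta_per_point * (score - mean(score)))
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::rexp(n, 1 / config$censor_time_mean)
  event <- as.integer(t_event <= t_cens)
  participants$followup_years <- pmin(t_event, t_cens)
  participants$event_dementia <- event
  participants$event_ad <- as.integer(event == 1L &
                                        stats::runif(n) < config$ad_fraction)
  participants$baseline_dementia <-
    stats::rbinom(n, 1L, config$baseline_dementia_rate)
  structure(list(
    participants = participants,
    config = config,
    true_scores = stats::setNames(score, sc$id)
  ), class = "synthetic_cohort")
}

# knock out factor cells completely at random at the configured rate
inject_missing <- function(data, columns, rate, seed) {
  if (rate <= 0) return(data)
  set.seed(seed)
  for (col in columns) {
    hit <- stats::runif(nrow(data)) < rate
    data[[col]][hit] <- NA_character_
  }
  data
}

#' Generate a complete synthetic cohort
#'
#' Runs [sample_factors()] and [simulate_outcome()], then (if
#' `missing_rate > 0`) knocks out factor values completely at random.
#' `true_scores` always reflects the complete pre-missingness data.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort` (see [simulate_outcome()]).
#' @export
simulate_cohort <- function(config) {
  cohort <- simulate_outcome(sample_factors(config), config)
  factor_cols <- c(names(config$category_probs), names(config$caide_prevalence))
  cohort$participants <- inject_missing(cohort$participants, factor_cols,
                                        config$missing_rate, config$seed + 2L)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$config$cohort, ", n = ", nrow(x$participants),
      ", seed = ", x$config$seed, "\n", sep = "")
  cat("  events: ", sum(x$participants$event_dementia, na.rm = TRUE),
      " dementia (", sum(x$participants$event_ad, na.rm = TRUE), " AD)\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort fixture to CSV
#'
#' Writes a participant CSV in the package's data-dictionary layout (columns
#' `id, sex, age`, one column per available factor, then
#' `followup_years, event_ad, event_dementia, baseline_dementia`) with the
#' named cohort's factor availability — factors the emulated cohort did not
#' measure are absent as columns — plus an adjacent `<name>_meta.json`
#' recording the full configuration and seed. Byte-identical for a fixed
#' seed.
#'
#' @param name `"map_like"`, `"kp_like"` or `"cvhs_like"`.
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param dir Output directory (default current directory).
#' @param ... Further arguments to [synthetic_config()].
#' @return Path of the CSV, invisibly.
#' @export
make_fixture <- function(name, n, seed, dir = ".", ...) {
  config <- synthetic_config(cohort = name, n = n, seed = seed, ...)
  cohort <- simulate_cohort(config)
  csv <- file.path(dir, paste0(name, ".csv"))
  meta <- file.path(dir, paste0(name, "_meta.json"))
  cols <- c("id", "sex", "age", names(config$category_probs),
            names(config$caide_prevalence),
            "followup_years", "event_ad", "event_dementia", "baseline_dementia")
  utils::write.csv(cohort$participants[, cols], csv, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(config[setdiff(names(unclass(config)), NULL)], meta,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(csv)
}
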