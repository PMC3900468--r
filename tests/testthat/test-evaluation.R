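test_that("the c-statistic equals exhaustive pairwise concordance", {
  r <- c_statistic(c(3, 1, 2, 0), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(c_statistic(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(c_statistic(rep(2, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(c_statistic(1:4, c(1, 1, 1, 1)), "cases and controls")

  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    scores <- sample(-5:15, n, replace = TRUE)  # integer scores force ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    auc <- c_statistic(scores, labels)$auc
    expect_equal(auc, brute_force_auc(scores, labels))
    # label-flip antisymmetry
    expect_equal(auc + c_statistic(scores, 1 - labels)$auc, 1)
  }
})

test_that("DeLong intervals behave and agree with an independent implementation", {
  perfect <- auc_confidence_interval(c(4, 5, 1, 2), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$ci_low, 1)
  expect_equal(perfect$ci_high, 1)

  set.seed(7)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    scores <- rnorm(n) + 0.8 * (labels <- rbinom(n, 1, 0.4))
    if (sum(labels) < 2 || sum(1 - labels) < 2) next
    got <- auc_confidence_interval(scores, labels)
    expect_true(got$ci_low <= got$auc && got$auc <= got$ci_high)
    ref <- pROC::ci.auc(pROC::roc(labels, scores, levels = c(0, 1),
                                  direction = "<", quiet = TRUE),
                        method = "delong")
    expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(got$ci_low, max(0, as.numeric(ref[1])), tolerance = 1e-10)
    expect_equal(got$ci_high, min(1, as.numeric(ref[3])), tolerance = 1e-10)
  }

  boot <- auc_confidence_interval(rnorm(60) + seq(0, 1, length.out = 60),
                                  rep(0:1, 30), method = "bootstrap",
                                  n_boot = 500, seed = 1)
  expect_true(boot$ci_low <= boot$auc && boot$auc <= boot$ci_high)
})

test_that("quartile assignment uses interpolated cut points with ties going down", {
  q <- assign_quartiles(1:8)
  expect_equal(as.vector(table(q$labels)), c(2, 2, 2, 2))
  expect_equal(unname(q$boundaries), c(2.75, 4.5, 6.25))
  # a score equal to a boundary lands in the lower quartile
  q2 <- assign_quartiles(c(0, 1, 1, 2))  # q50 is exactly 1
  expect_equal(q2$labels[2:3], c(2L, 2L))
  expect_warning(qd <- assign_quartiles(rep(5, 10)), "degenerate")
  expect_true(all(qd$labels == 1L))
  expect_error(assign_quartiles(numeric(0)), "no scores")
})

test_that("incidence rates are events per 1000 person-years and sum correctly", {
  inc <- incidence_rates(c(60, 40, 10, 20), c(1, 1, 0, 0), c(1, 1, 2, 2))
  expect_equal(inc$incidence_per_1000py, c(20, 0))
  expect_true(inc$zero_events[2])

  cfg <- synthetic_config("cvhs_like", n = 1500, seed = 21)
  co <- simulate_cohort(cfg)$participants
  q <- assign_quartiles(unname(simulate_cohort(cfg)$true_scores))
  inc <- incidence_rates(co$followup_years, co$event_ad, q$labels)
  expect_equal(sum(inc$events), sum(co$event_ad))
  expect_equal(sum(inc$person_years), sum(co$followup_years))
  expect_equal(inc$incidence_per_1000py,
               1000 * inc$events / inc$person_years)
})

test_that("Cox quartile fits match analytic and grid partial-likelihood maxima", {
  # three subjects, one binary contrast: the partial likelihood
  # e^b/(2e^b+1) * 1/(1+e^b) peaks at b = -log(2)/2
  res <- cox_quartile_hr(c(1, 2, 3), c(1, 1, 0), c(2, 1, 2))
  expect_equal(log(res$table$hazard_ratio[2]), -0.5 * log(2), tolerance = 1e-6)

  set.seed(13)
  done <- 0
  while (done < 50) {
    n <- sample(4:6, 1)
    time <- sample(1:4, n, replace = TRUE) + 0.5 * rbinom(n, 1, 0.5)
    event <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.5)
    grp <- x + 1L
    if (length(unique(grp)) < 2 || sum(event[grp == 1]) == 0) next
    fit <- tryCatch(cox_quartile_hr(time, event, grp), error = function(e) NULL)
    if (is.null(fit) || fit$table$unbounded[2]) next
    b <- log(fit$table$hazard_ratio[2])
    if (abs(b) > 8) next
    expect_equal(b, grid_max_cox(time, event, x), tolerance = 1e-6)
    done <- done + 1
  }

  # no contrast across subjects: unit hazard ratios, flat trend
  flat <- cox_quartile_hr(c(1, 2, 3, 4), c(1, 0, 1, 0), c(1, 1, 1, 1))
  expect_true(all(flat$table$hazard_ratio == 1))
  expect_equal(flat$trend_p, 1)

  expect_error(cox_quartile_hr(c(1, 2), c(0, 1), c(1, 2)),
               "reference quartile")
})

test_that("age-split chi-square is the uncorrected Pearson statistic", {
  # young (age 65) and old (age 75) rows engineered to the same total score,
  # so everyone shares one quartile and the 2x2 is fully under our control:
  # the 16-point female age gap (5 vs 21) is offset by education +6,
  # smoking +4, diabetes +3 for the young and fish intake -3 for the old
  flat_cohort <- function(n_young, n_old, cases_young, cases_old) {
    young <- data.frame(
      sex = "female", age = 65, education = ">11", diabetes = "yes",
      depression = "no", smoking = "current", alcohol = "abstainer",
      physical_activity = "low", fish_intake = "0-0.25",
      stringsAsFactors = FALSE)[rep(1, n_young), ]
    old <- data.frame(
      sex = "female", age = 75, education = "<8", diabetes = "no",
      depression = "no", smoking = "never", alcohol = "abstainer",
      physical_activity = "low", fish_intake = "0.26-2.0",
      stringsAsFactors = FALSE)[rep(1, n_old), ]
    d <- rbind(young, old)
    d$id <- as.character(seq_len(nrow(d)))
    d$followup_years <- 5
    d$event_ad <- 0L
    d$event_dementia <- c(rep(1L, cases_young), rep(0L, n_young - cases_young),
                          rep(1L, cases_old), rep(0L, n_old - cases_old))
    d$baseline_dementia <- 0L
    d
  }
  # balanced 2x2 -> independence
  d0 <- flat_cohort(20, 20, 10, 10)
  suppressWarnings(
    res0 <- age_split_comparison(d0, build_scorecard("anu_adri_cvhs")))
  expect_equal(res0$chi_square[1], 0)
  expect_equal(res0$p_value[1], 1)

  # [[20,80],[40,60]] -> chi-square 9.5238, p = 0.0020
  d1 <- flat_cohort(100, 100, 20, 40)
  suppressWarnings(
    res1 <- age_split_comparison(d1, build_scorecard("anu_adri_cvhs")))
  expect_equal(res1$chi_square[1], 200 * (20 * 60 - 80 * 40)^2 / (100 * 100 * 60 * 140),
               tolerance = 1e-12)
  expect_equal(res1$p_value[1], 0.00203, tolerance = 1e-2)
  expect_equal(res1$pct_young[1], 20)
  expect_equal(res1$pct_old[1], 40)

  expect_error(age_split_comparison(d1, build_scorecard("anu_adri_cvhs"),
                                    split_age = 50), "non-empty")
})

test_that("discrimination reporting covers subgroups and the common-card rerun", {
  cfg <- synthetic_config("cvhs_like", n = 4000, seed = 31, beta_per_point = 0)
  co <- simulate_cohort(cfg)
  rep_null <- evaluate_index(co$participants, build_scorecard("anu_adri_cvhs"))
  expect_true(all(rep_null$auc > 0.45 & rep_null$auc < 0.55))  # chance only
  # common-card rows are computed on the same analysis set as the full card
  full_n <- rep_null$n[rep_null$subgroup == "overall"]
  common_n <- rep_null$n[rep_null$subgroup == "common_variables"]
  expect_equal(common_n, full_n)
  common <- rep_null[rep_null$subgroup == "common_variables", ]
  overall <- rep_null[rep_null$subgroup == "overall", ]
  expect_equal(common$diff_vs_full, common$auc - overall$auc)
  expect_equal(rep_null$n_cases + rep_null$n_controls, rep_null$n)
})

test_that("complete-case filtering removes and logs each exclusion reason", {
  card <- build_scorecard("anu_adri_cvhs")
  d <- tiny_cohort()
  d <- rbind(d, d, d, d)  # 12 rows
  d$id <- as.character(seq_len(nrow(d)))
  d$baseline_dementia[1] <- 1L
  d$event_ad[2] <- NA
  d$followup_years[3] <- NA
  d$diabetes[4] <- NA
  set <- filter_analysis_set(d, card, "ad", "strict")
  expect_equal(set$n_retained, 8L)
  expect_equal(unname(set$exclusions),  c(1L, 1L, 1L, 1L))
  # no-op on clean data
  clean <- tiny_cohort()
  expect_identical(filter_analysis_set(clean, card, "ad")$data, clean)
  # under skip, incomplete factor data is retained
  expect_equal(filter_analysis_set(d, card, "ad", "skip")$n_retained, 9L)
})

test_that("injected missingness reproduces the complete-case retention fraction", {
  # complete-case fraction 903/1164 over the 8 column-based factors of the
  # 10-factor variant -> per-cell missingness 1 - (903/1164)^(1/8)
  target <- 903 / 1164
  rate <- 1 - target^(1 / 8)
  n <- 4000
  cfg <- synthetic_config("map_like", n = n, seed = 17, missing_rate = rate)
  co <- simulate_cohort(cfg)
  set <- filter_analysis_set(co$participants, build_scorecard("anu_adri_map"),
                             "ad", "strict")
  frac <- set$n_retained / n
  expect_lt(abs(frac - target), 3 * sqrt(target * (1 - target) / n))
})
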