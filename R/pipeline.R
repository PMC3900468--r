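.mandatory_cols <- c("id", "sex", "age", "followup_years",
                     "event_ad", "event_dementia", "baseline_dementia")

#' Read and validate a participant CSV
#'
#' Parses a cohort table in the package's data dictionary: mandatory columns
#' `id, sex, age, followup_years, event_ad, event_dementia,
#' baseline_dementia` plus one column per measured factor holding category
#' labels (empty cells are missing). Structural problems (absent mandatory
#' columns, non-numeric numerics) are hard errors; content problems —
#' unknown category labels, negative follow-up, an AD event without a
#' dementia event (AD is a dementia subtype), unexpected sex values — are
#' collected into a validation report instead. Factor columns a given
#' scorecard does not use are simply ignored, so a cohort that never
#' measured a factor can omit its column.
#'
#' @param path CSV file path.
#' @param card Optional scorecard; if supplied, factor labels are checked
#'   against it.
#' @return List with `data` (the parsed data frame) and `report` (data frame
#'   of `row`, `field`, `issue`; zero rows if clean).
#' @export
read_cohort_csv <- function(path, card = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), colClasses = "character")
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  to_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(x)
    if (any(bad))
      stop("unparseable numeric value(s) in column '", col, "' (row ",
           which(bad)[1], ")", call. = FALSE)
    x
  }
  data <- raw
  data$age <- to_num("age")
  data$followup_years <- to_num("followup_years")
  for (col in c("event_ad", "event_dementia", "baseline_dementia"))
    data[[col]] <- as.integer(to_num(col))

  issues <- list()
  note <- function(rows, field, issue) {
    if (length(rows))
      issues[[length(issues) + 1L]] <<- data.frame(row = rows, field = field,
                                                   issue = issue)
  }
  note(which(!is.na(data$sex) & !data$sex %in% c("male", "female")),
       "sex", "unexpected value")
  note(which(!is.na(data$followup_years) & data$followup_years < 0),
       "followup_years", "negative follow-up")
  note(which(!is.na(data$event_ad) & !is.na(data$event_dementia) &
               data$event_ad > data$event_dementia),
       "event_ad", "AD event without dementia event")
  for (col in c("event_ad", "event_dementia", "baseline_dementia"))
    note(which(!is.na(data[[col]]) & !data[[col]] %in% c(0L, 1L)),
         col, "not 0/1")
  if (!is.null(card)) {
    for (f in card$factors) {
      if ((f$source %||% "column") != "column") next
      col <- data[[f$name]]
      if (is.null(col)) next  # factor not measured in this cohort
      labs <- vapply(f$categories, `[[`, character(1), "label")
      note(which(!is.na(col) & !col %in% labs), f$name,
           "unknown category label")
    }
  }
  report <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(0), field = character(0), issue = character(0))
  list(data = data, report = report)
}

pipeline_defaults <- function() {
  list(
    input_csv = NULL,
    synthetic = NULL,            # list(cohort =, n =, ...) for simulate_cohort
    scorecard_variant = NULL,    # default: inferred from synthetic cohort
    outcomes = c("ad", "any_dementia"),
    subgroups = c("overall", "male", "female"),
    missing_policy = "strict",
    ties = "breslow",
    level = 0.95,
    split_age = 70,
    caide = TRUE,
    out_dir = NULL,
    seed = 1L
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$input_csv) == is.null(cfg$synthetic))
    stop("config must provide exactly one of input_csv or synthetic",
         call. = FALSE)
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

qa_to_list <- function(qa) {
  if (is.null(qa)) return(NULL)
  list(table = qa$table, trend_p = qa$trend_p, ties = qa$ties,
       boundaries = as.list(qa$boundaries), notes = qa$notes)
}

#' Run the full validation pipeline
#'
#' Orchestrates the standard sequence for validating an additive risk index
#' on a cohort: load (CSV or synthetic generation), complete-case filter,
#' score, discrimination (c-statistics with CIs by outcome/sex plus the
#' common-variable subset), quartile dose-response (incidence per 1000
#' person-years, Cox hazard ratios, linear trend) per outcome, an optional
#' age-split quartile comparison, and the CAIDE comparator index. Each stage
#' logs participant flow; errors carry a stage label. Results are written as
#' JSON alongside a run manifest and a Markdown report; a fixed config and
#' seed give byte-identical results.
#'
#' @param config Named list, or path to a YAML/JSON file, with fields
#'   `input_csv` *or* `synthetic` (arguments for [synthetic_config()]),
#'   `scorecard_variant`, `outcomes`, `subgroups`, `missing_policy`, `ties`,
#'   `level`, `split_age` (`NULL` to skip), `caide` (logical), `out_dir`
#'   (`NULL` to skip writing), `seed`.
#' @param quiet Suppress progress messages.
#' @return The results list, invisibly; written to `<out_dir>/results.json`
#'   (with `manifest.json` and `report.md`) when `out_dir` is set.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- read_run_config(config)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)

  data <- stage("load", {
    if (!is.null(cfg$synthetic)) {
      syn_args <- cfg$synthetic
      syn_args$seed <- syn_args$seed %||% cfg$seed
      syn <- do.call(synthetic_config, syn_args)
      if (is.null(cfg$scorecard_variant))
        cfg$scorecard_variant <- syn$scorecard_variant
      say("simulating ", syn$cohort, " cohort, n = ", syn$n,
          ", seed = ", syn$seed)
      simulate_cohort(syn)$participants
    } else {
      say("reading ", cfg$input_csv)
      loaded <- read_cohort_csv(cfg$input_csv)
      if (nrow(loaded$report))
        say(nrow(loaded$report), " validation issue(s) in input")
      loaded$data
    }
  })
  if (is.null(cfg$scorecard_variant)) cfg$scorecard_variant <- "anu_adri_full"
  card <- stage("scorecard", build_scorecard(cfg$scorecard_variant))
  say("scorecard ", card$name, ", n = ", nrow(data), " read in")

  sets <- list(); scores <- list()
  for (outcome in cfg$outcomes) {
    sets[[outcome]] <- stage("filter",
      filter_analysis_set(data, card, outcome, cfg$missing_policy))
    scores[[outcome]] <- stage("score",
      score_cohort(sets[[outcome]]$data, card, cfg$missing_policy)$score)
    say("outcome ", outcome, ": ", sets[[outcome]]$n_retained, "/",
        sets[[outcome]]$n_input, " retained")
  }

  first <- cfg$outcomes[1]
  s1 <- scores[[first]]
  qsum <- assign_quartiles(s1)
  score_summary <- list(
    n = length(s1), mean = mean(s1), sd = stats::sd(s1),
    boundaries = as.list(qsum$boundaries),
    quartiles = data.frame(
      quartile = sort(unique(qsum$labels)),
      median = vapply(sort(unique(qsum$labels)), function(q)
        median(s1[qsum$labels == q]), numeric(1)),
      min = vapply(sort(unique(qsum$labels)), function(q)
        min(s1[qsum$labels == q]), numeric(1)),
      max = vapply(sort(unique(qsum$labels)), function(q)
        max(s1[qsum$labels == q]), numeric(1))))

  discrimination <- stage("auc", evaluate_index(
    data, card, outcomes = cfg$outcomes, subgroups = cfg$subgroups,
    missing_policy = cfg$missing_policy, level = cfg$level))
  say("discrimination: ", nrow(discrimination), " AUC estimates")

  quartiles <- list()
  for (outcome in cfg$outcomes) {
    quartiles[[outcome]] <- stage("quartiles", quartile_analysis(
      sets[[outcome]], scores[[outcome]], outcome,
      ties = cfg$ties, level = cfg$level))
    say("quartile trend p (", outcome, "): ",
        format(quartiles[[outcome]]$trend_p, digits = 3))
  }

  age_split <- NULL
  if (!is.null(cfg$split_age)) {
    age_split <- stage("age_split", tryCatch(
      age_split_comparison(data, card, split_age = cfg$split_age,
                           missing_policy = cfg$missing_policy),
      error = function(e) { say("age split skipped: ", conditionMessage(e)); NULL }))
  }

  caide <- NULL
  if (isTRUE(cfg$caide)) {
    caide <- stage("caide", {
      ccard <- build_scorecard("caide")
      need <- vapply(Filter(function(f) (f$source %||% "column") == "column",
                            ccard$factors), `[[`, character(1), "name")
      absent <- setdiff(need, names(data))
      if (length(absent))
        stop("required column(s) missing for the CAIDE comparator: ",
             paste(absent, collapse = ", "))
      do.call(rbind, lapply(c("caide", "caide_no_bmi", "caide_no_bmi_no_chol"),
        function(v) evaluate_index(data, build_scorecard(v),
                                   outcomes = cfg$outcomes,
                                   subgroups = "overall", common_card = NULL,
                                   missing_policy = cfg$missing_policy,
                                   level = cfg$level)))
    })
    say("caide comparator: ", nrow(caide), " AUC estimates")
  }

  results <- list(
    meta = list(
      scorecard_variant = cfg$scorecard_variant,
      seed = cfg$seed,
      n_input = nrow(data),
      theoretical_range = as.list(theoretical_range(card)),
      exclusions = lapply(sets, function(s) as.list(s$exclusions)),
      n_retained = lapply(sets, function(s) s$n_retained)
    ),
    score_summary = score_summary,
    discrimination = as.data.frame(discrimination),
    quartiles = lapply(quartiles, qa_to_list),
    age_split = if (!is.null(age_split)) list(
      split_age = attr(age_split, "split_age"),
      boundaries = as.list(attr(age_split, "boundaries")),
      table = as.data.frame(age_split)),
    caide = if (!is.null(caide)) as.data.frame(caide)
  )

  if (!is.null(cfg$out_dir)) {
    stage("write", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(results, file.path(cfg$out_dir, "results.json"),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
      manifest <- list(package = "anuadri",
                       version = as.character(utils::packageVersion("anuadri")),
                       config = cfg[!vapply(cfg, is.null, logical(1))])
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
      writeLines(render_report(results), file.path(cfg$out_dir, "report.md"))
      say("wrote ", cfg$out_dir, "/{results.json, manifest.json, report.md}")
    })
  }
  invisible(results)
}

md_table <- function(df, digits = 3) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", format(round(x, digits), trim = TRUE))
    else ifelse(is.na(x), "", as.character(x))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

render_report <- function(results) {
  out <- c("# Risk index validation report", "",
           paste0("Scorecard: `", results$meta$scorecard_variant,
                  "` (theoretical range ",
                  results$meta$theoretical_range$min, " to ",
                  results$meta$theoretical_range$max, "), seed ",
                  results$meta$seed, ", n = ", results$meta$n_input, "."), "",
           "## Score distribution", "",
           sprintf("Mean %.2f (SD %.2f), n = %d analysed.",
                   results$score_summary$mean, results$score_summary$sd,
                   results$score_summary$n), "",
           md_table(results$score_summary$quartiles), "",
           "## Discrimination (c-statistics)", "",
           md_table(results$discrimination), "")
  for (outcome in names(results$quartiles)) {
    q <- results$quartiles[[outcome]]
    out <- c(out, paste0("## Quartile dose-response: ", outcome), "",
             md_table(q$table),
             sprintf("\nP for linear trend: %.3g (ties: %s)", q$trend_p, q$ties), "")
  }
  if (!is.null(results$age_split))
    out <- c(out, paste0("## Age split at ", results$age_split$split_age,
                         " years (dementia cases per quartile)"), "",
             md_table(results$age_split$table), "")
  if (!is.null(results$caide))
    out <- c(out, "## CAIDE comparator", "", md_table(results$caide), "")
  out
}
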