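#' Run the full analysis pipeline
#'
#' One-shot reproducible run: read lexicon and corpus, apply the activity
#' filter, tokenize and score per user-hour, derive baselines, relative
#' probabilities and diurnal curves, assemble the regression table, and run
#' the screened permutation regressions of every affect outcome on the
#' behaviour/health exposures and covariates. All stage outputs are written
#' as tidy CSV files plus a `manifest.json` (config hash, package version,
#' per-stage row counts, seeds) so any output is re-derivable; a failing
#' stage aborts with the stage name after writing the partial manifest.
#'
#' @param config A named list or the path of a YAML file with entries:
#' * `lexicon`, `lexicon_dialect` (`"tsv"`/`"json"`/`"liwc_dic"`),
#'   `postings`, `profiles` — input paths;
#' * `output_dir` — where outputs are written (`NULL` skips writing);
#' * `timezone` (default `"Asia/Shanghai"`), `min_postings` (25),
#'   `tokenize_mode`, `match_mode`, `baseline_mode`;
#' * `outcomes`, `exposures`, `covariates` — term sets for the regression
#'   stage (defaults: the 7 affect dimensions + 2 composite scores; the
#'   `sexual` and `health` baselines; the coded demographic/network
#'   covariates);
#' * `B`, `seed`, `screen_alpha`, `final_alpha` — permutation settings
#'   (`seed` is mandatory when the regression stage runs).
#' @return Invisibly, a list with every stage output (`postings`,
#'   `active_users`, `counts`, `pa`, `baselines`, `rpa`, `curves`,
#'   `user_summary`, `regression`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    lexicon_dialect = "tsv", timezone = "Asia/Shanghai", min_postings = 25,
    tokenize_mode = "whitespace", match_mode = "token",
    baseline_mode = "active_hours",
    outcomes = c(SENTIMENT_DIMS, EMOTION_DIMS, COMPOSITE_DIMS),
    exposures = EXPOSURE_DIMS,
    covariates = c("age_group", "education", "geolocation", "hometown",
                   "bmi_class", "sex_role", "log_followers", "log_followees",
                   "log_chat_groups"),
    B = 4999, screen_alpha = 0.20, final_alpha = 0.05,
    output_dir = NULL, seed = NULL, run_regression = TRUE
  )
  config <- utils::modifyList(defaults, config)
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("affectrhythm")),
    seed = config$seed,
    stages = list()
  )
  flush_manifest <- function() {
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      flush_manifest()
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    n <- if (is.data.frame(res)) nrow(res) else if (is.atomic(res)) length(res) else NA
    manifest$stages[[name]] <<- list(status = "ok", rows = n)
    res
  }
  write_stage <- function(df, file) {
    if (!is.null(out_dir)) {
      readr::write_csv(df, file.path(out_dir, file))
    }
  }

  lex <- stage("lexicon", read_lexicon(config$lexicon, config$lexicon_dialect))
  postings <- stage("read_postings",
                    read_postings(config$postings, timezone = config$timezone))
  profiles <- stage("read_profiles", read_profiles(config$profiles))
  active <- stage("filter_active_users",
                  filter_active_users(postings, config$min_postings))
  postings_kept <- dplyr::filter(postings, .data$user_id %in% active)
  counts <- stage("score", count_user_hours(
    postings_kept, lex,
    tokenize_mode = config$tokenize_mode, match_mode = config$match_mode))
  pa <- stage("probabilities", hour_probabilities(counts))
  baselines <- stage("baselines", affect_baselines(pa, mode = config$baseline_mode))
  rpa <- stage("relative_probabilities",
               relative_probabilities(pa, baselines = baselines))
  curves <- stage("diurnal_curve", diurnal_curve(rpa))
  covariates <- stage("covariates", derive_covariates(profiles))
  summary_tbl <- stage("user_summary", build_user_summary(baselines, covariates))

  regression <- NULL
  if (isTRUE(config$run_regression)) {
    if (is.null(config$seed)) {
      abort("Pipeline stage 'regression' failed: `seed` is required in the config.")
    }
    outcomes <- intersect(config$outcomes, names(summary_tbl))
    candidates <- intersect(c(config$exposures, config$covariates),
                            names(summary_tbl))
    ## Constant factors (e.g. a covariate with a single observed level)
    ## cannot enter a regression; drop them up front.
    usable <- vapply(candidates, function(t) {
      v <- summary_tbl[[t]]
      length(unique(v[!is.na(v)])) > 1
    }, logical(1))
    candidates <- candidates[usable]
    regression <- stage("regression", purrr::imap(
      setNames(outcomes, outcomes),
      function(oc, i) screen_then_fit(
        summary_tbl, oc, candidates,
        screen_alpha = config$screen_alpha, final_alpha = config$final_alpha,
        B = config$B, seed = derive_seed(config$seed, match(oc, outcomes)))
    ) |> dplyr::bind_rows())
  }

  write_stage(counts, "user_hour_counts.csv")
  write_stage(baselines, "baselines.csv")
  write_stage(curves, "diurnal_curves.csv")
  write_stage(summary_tbl, "user_summary.csv")
  if (!is.null(regression)) write_stage(regression, "regression_results.csv")
  flush_manifest()

  invisible(list(
    postings = postings, active_users = active, counts = counts, pa = pa,
    baselines = baselines, rpa = rpa, curves = curves,
    covariates = covariates, user_summary = summary_tbl,
    regression = regression, manifest = manifest
  ))
}
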