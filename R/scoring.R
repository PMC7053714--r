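#' Accumulate token and match counts per user and clock hour
#'
#' Tokenizes every posting and tallies, for each user and each clock hour
#' pooled across calendar days, the total token count and the number of
#' tokens matching each lexicon dimension. When the lexicon contains both
#' sentiment dimensions (`positive_affect`, `negative_affect`) the signed
#' composite count `positive_sentiment_score` = positive - negative is
#' added; when it contains all five basic emotions the composite
#' `positive_emotion_score` = joy - (sadness + anger + fear + disgust) is
#' added.
#'
#' @param postings Tibble with columns `user_id`, `hour` (0-23) and `text`
#'   (see [read_postings()]).
#' @param lex An [lexicon()].
#' @param tokenize_mode,segmenter Passed to [tokenize()].
#' @param match_mode Passed to [count_matches()]. Token-mode counts are
#'   bounded by the token total; substring counts on unsegmented text are
#'   not.
#' @return A tibble with one row per observed (user, hour): `user_id`,
#'   `hour`, `n_postings`, `token_total`, and one integer count column per
#'   dimension and composite.
#' @export
count_user_hours <- function(postings, lex,
                             tokenize_mode = c("whitespace", "segmenter"),
                             match_mode = c("token", "substring"),
                             segmenter = NULL) {
  assert_columns(postings, c("user_id", "hour", "text"), "postings")
  tokenize_mode <- match.arg(tokenize_mode)
  match_mode <- match.arg(match_mode)
  if (!inherits(lex, "affect_lexicon")) {
    abort("`lex` must be an affect_lexicon (see `lexicon()`).")
  }
  if (any(is.na(postings$hour)) || any(postings$hour < 0 | postings$hour > 23)) {
    abort("`postings$hour` must be integers in 0-23.")
  }

  toks <- tokenize(postings$text, mode = tokenize_mode, segmenter = segmenter)
  n_tok <- lengths(toks)
  n_post <- nrow(postings)
  dims <- names(lex)

  per_posting <- matrix(0L, nrow = n_post, ncol = length(dims),
                        dimnames = list(NULL, dims))
  if (match_mode == "token") {
    pid <- rep.int(seq_len(n_post), n_tok)
    flat <- fold_text(unlist(toks, use.names = FALSE))
    for (d in dims) {
      hit <- token_match_flags(flat, lex[[d]])
      if (any(hit)) {
        per_posting[, d] <- tabulate(pid[hit], nbins = n_post)
      }
    }
  } else {
    folded <- fold_text(postings$text)
    for (d in dims) {
      per_posting[, d] <- vapply(folded, count_substring_matches,
                                 integer(1), entries = lex[[d]],
                                 USE.NAMES = FALSE)
    }
  }

  out <- tibble::tibble(
    user_id = as.character(postings$user_id),
    hour = as.integer(postings$hour),
    n_postings = 1L,
    token_total = as.integer(n_tok)
  )
  for (d in dims) out[[d]] <- per_posting[, d]
  out <- out |>
    dplyr::group_by(.data$user_id, .data$hour) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop") |>
    dplyr::arrange(.data$user_id, .data$hour)

  if (all(SENTIMENT_DIMS %in% dims)) {
    out$positive_sentiment_score <- out$positive_affect - out$negative_affect
  }
  if (all(EMOTION_DIMS %in% dims)) {
    out$positive_emotion_score <-
      out$joy - (out$sadness + out$anger + out$fear + out$disgust)
  }
  attr(out, "dimensions") <- setdiff(names(out),
                                     c("user_id", "hour", "n_postings", "token_total"))
  out
}

#' Per-user-hour affect probabilities
#'
#' For each user, hour and dimension, the probability that a token posted
#' by that user in that hour belongs to the dimension's word list:
#' count / token total. Composite (signed) counts yield scores in
#' \[-1, 1\]; unipolar dimensions yield probabilities in \[0, 1\]. A
#' user-hour with zero tokens has an undefined probability (`NA`), not
#' zero, and is excluded from baselines, grand means and curves.
#'
#' @param counts Output of [count_user_hours()].
#' @param dimensions Dimensions to score; defaults to every count column.
#' @return A long tibble: `user_id`, `hour`, `dimension`, `count`,
#'   `token_total`, `pa`.
#' @export
hour_probabilities <- function(counts, dimensions = NULL) {
  assert_columns(counts, c("user_id", "hour", "token_total"), "counts")
  dims <- dimensions %||% attr(counts, "dimensions") %||%
    setdiff(names(counts), c("user_id", "hour", "n_postings", "token_total"))
  missing <- setdiff(dims, names(counts))
  if (length(missing) > 0) {
    abort(sprintf("Unknown dimension column(s): %s", paste(missing, collapse = ", ")))
  }
  long <- counts |>
    dplyr::select(dplyr::all_of(c("user_id", "hour", "token_total", dims))) |>
    tidyr::pivot_longer(dplyr::all_of(dims), names_to = "dimension",
                        values_to = "count") |>
    dplyr::mutate(
      dimension = factor(.data$dimension, levels = dims),
      pa = dplyr::if_else(.data$token_total > 0,
                          .data$count / .data$token_total, NA_real_)
    ) |>
    dplyr::select("user_id", "hour", "dimension", "count", "token_total", "pa") |>
    dplyr::arrange(.data$dimension, .data$user_id, .data$hour)
  long
}

#' Per-user baseline affect
#'
#' The user's average affective state for each dimension, used as the
#' regression outcome. Two denominator conventions are provided:
#' `active_hours` (default) averages the defined hourly probabilities over
#' the hours the user actually posted in; `all_hours` divides their sum by
#' the full 24-hour cycle, so hours without postings implicitly contribute
#' zero affect and sparse users are pulled toward 0.
#'
#' @param pa Long probability table from [hour_probabilities()].
#' @param mode `"active_hours"` or `"all_hours"`.
#' @param n_hours Cycle length for `all_hours` (24 for clock hours).
#' @return A tibble: `user_id`, `dimension`, `baseline`, `n_active_hours`.
#' @export
affect_baselines <- function(pa, mode = c("active_hours", "all_hours"),
                             n_hours = 24) {
  mode <- match.arg(mode)
  assert_columns(pa, c("user_id", "dimension", "pa"), "pa")
  defined_hours <- pa |>
    dplyr::filter(!is.na(.data$pa)) |>
    dplyr::distinct(.data$user_id)
  none <- setdiff(unique(pa$user_id), defined_hours$user_id)
  if (length(none) > 0) {
    abort(sprintf("User(s) with no defined hours (all postings empty): %s",
                  paste(head(none, 5), collapse = ", ")))
  }
  pa |>
    dplyr::filter(!is.na(.data$pa)) |>
    dplyr::group_by(.data$user_id, .data$dimension) |>
    dplyr::summarise(
      baseline = if (mode == "active_hours") mean(.data$pa) else sum(.data$pa) / n_hours,
      n_active_hours = dplyr::n(),
      .groups = "drop"
    )
}

#' Relative affect probabilities
#'
#' Recentres each user-hour probability by the user's own baseline and adds
#' back the grand mean over all defined user-hours:
#' `rpa = pa - baseline + grand_mean`. The relative probability represents
#' the user's deviation from his own baseline, putting users with different
#' overall affect levels on a common diurnal scale. The mean of `rpa` over
#' all defined user-hours equals the grand mean exactly.
#'
#' @param pa Long probability table from [hour_probabilities()].
#' @param baselines Optional output of [affect_baselines()]; computed with
#'   `mode` if not supplied.
#' @param mode Baseline convention, see [affect_baselines()].
#' @return `pa` with columns `baseline`, `grand_mean` and `rpa` added.
#' @export
relative_probabilities <- function(pa, baselines = NULL,
                                   mode = c("active_hours", "all_hours")) {
  mode <- match.arg(mode)
  baselines <- baselines %||% affect_baselines(pa, mode = mode)
  grand <- pa |>
    dplyr::filter(!is.na(.data$pa)) |>
    dplyr::group_by(.data$dimension) |>
    dplyr::summarise(grand_mean = mean(.data$pa), .groups = "drop")
  pa |>
    dplyr::left_join(baselines[c("user_id", "dimension", "baseline")],
                     by = c("user_id", "dimension")) |>
    dplyr::left_join(grand, by = "dimension") |>
    dplyr::mutate(rpa = .data$pa - .data$baseline + .data$grand_mean)
}

#' Population diurnal curve
#'
#' Averages the relative probabilities over the set of users active
#' (posting at least one token) in each clock hour, yielding a 24-point
#' population rhythm per dimension. Hours in which no user was active are
#' reported with `NA` and a zero user count.
#'
#' @param rpa Output of [relative_probabilities()].
#' @return A tibble of class `diurnal_curve`: `dimension`, `hour`,
#'   `rpa_mean`, `n_users`.
#' @export
diurnal_curve <- function(rpa) {
  assert_columns(rpa, c("dimension", "hour", "rpa"), "rpa")
  observed <- rpa |>
    dplyr::filter(!is.na(.data$rpa)) |>
    dplyr::group_by(.data$dimension, .data$hour) |>
    dplyr::summarise(rpa_mean = mean(.data$rpa), n_users = dplyr::n(),
                     .groups = "drop")
  grid <- tidyr::expand_grid(
    dimension = unique(rpa$dimension),
    hour = 0:23
  )
  out <- grid |>
    dplyr::left_join(observed, by = c("dimension", "hour")) |>
    dplyr::mutate(n_users = dplyr::coalesce(.data$n_users, 0L)) |>
    dplyr::arrange(.data$dimension, .data$hour)
  class(out) <- c("diurnal_curve", class(out))
  out
}

#' Peak window of a diurnal curve
#'
#' Finds, per dimension, the contiguous circular window of `width` clock
#' hours maximizing the mean curve value; ties are broken by the earliest
#' start hour. Windows containing undefined hours are not eligible.
#'
#' @param curve A [diurnal_curve()] tibble, any tibble with `hour` and
#'   `rpa_mean` (optionally `dimension`), or a bare numeric vector of 24
#'   hourly values.
#' @param width Window width in hours, 1-24.
#' @return A tibble: `dimension` (if present), `start_hour`, `end_hour`,
#'   `peak_hour` (window centre, rounded down), `mean_value`.
#' @export
peak_window <- function(curve, width = 3) {
  if (!is.numeric(width) || width < 1 || width > 24) {
    abort("`width` must be between 1 and 24 hours.")
  }
  width <- as.integer(width)
  if (is.numeric(curve)) {
    if (length(curve) != 24) abort("A numeric `curve` must have 24 hourly values.")
    return(peak_window_one(curve, width))
  }
  assert_columns(curve, c("hour", "rpa_mean"), "curve")
  if (!"dimension" %in% names(curve)) {
    curve <- dplyr::mutate(curve, dimension = "curve")
  }
  curve |>
    dplyr::group_by(.data$dimension) |>
    dplyr::group_modify(function(df, key) {
      vals <- rep(NA_real_, 24)
      vals[df$hour + 1] <- df$rpa_mean
      peak_window_one(vals, width)
    }) |>
    dplyr::ungroup()
}

peak_window_one <- function(vals, width) {
  ext <- c(vals, vals) # circular windows
  means <- vapply(0:23, function(s) mean(ext[(s + 1):(s + width)]), numeric(1))
  if (all(is.na(means))) {
    abort(sprintf("Fewer than %d contiguous defined hours in the curve.", width))
  }
  best <- which(means == max(means, na.rm = TRUE))[1] - 1L # earliest start wins ties
  tibble::tibble(
    start_hour = best,
    end_hour = (best + width - 1L) %% 24L,
    peak_hour = (best + (width - 1L) %/% 2L) %% 24L,
    mean_value = means[best + 1]
  )
}

#' Assemble the per-user regression table
#'
#' One row per active user: baseline outcomes (the affect dimensions and
#' composite scores), baseline exposures (`sexual`, `health`) and the coded
#' covariates.
#'
#' @param baselines Output of [affect_baselines()].
#' @param covariates Output of [derive_covariates()]; users without a
#'   profile row get `unknown`/`NA` covariates.
#' @return A tibble with one column per dimension baseline plus the
#'   covariate columns.
#' @export
build_user_summary <- function(baselines, covariates = NULL) {
  assert_columns(baselines, c("user_id", "dimension", "baseline"), "baselines")
  wide <- baselines |>
    dplyr::select("user_id", "dimension", "baseline") |>
    tidyr::pivot_wider(names_from = "dimension", values_from = "baseline")
  if (!is.null(covariates)) {
    wide <- dplyr::left_join(wide, covariates, by = "user_id")
  }
  wide
}
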