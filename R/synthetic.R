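#' Configuration for the synthetic corpus generator
#'
#' Builds and validates the generator settings. The defaults describe a
#' desk-scale corpus with the statistical structure the analysis assumes:
#' per-dimension baseline token emission rates anchored to the magnitudes
#' reported for this kind of social-media corpus (positive affect 0.014,
#' negative affect 0.016, joy 0.015, ..., sexual 0.009, health 0.008),
#' morning peaks (hour 8) for the positive dimensions and late-night peaks
#' (hour 3) for the negative and health dimensions, posting activity spread
#' over all 24 clock hours, and a negative-binomial posting volume with a
#' mean of 80 postings per user.
#'
#' Diurnal modulation is applied on the logit of the emission probability,
#' `logit p(u,h,d) = logit(base_d) + b(u,d) + A_d cos(2 pi (h - peak_d)/24)
#' + effects`, which keeps probabilities in (0,1) at any amplitude; the
#' default amplitude 0.8 gives roughly a 5-fold peak-to-trough rate ratio.
#' `b(u,d)` is a per-user normal random effect (SD `user_sd`).
#'
#' `covariate_effects` couples user-level traits to emission rates, e.g.
#' `list(positive_affect = c(sexual = 1))` adds `1 * b(u, sexual)` to the
#' positive-affect logit of every user, so users with a high latent
#' sexual-word rate also emit more positive-affect words — the ground truth
#' recovered by the regression stage. Effect names may be dimension names
#' (coupling to that dimension's random effect) or `age_gt25`,
#' `log_followers`, `log_followees`, `log_chat_groups`.
#'
#' @param n_users Number of users.
#' @param postings_per_user,tokens_per_posting Named vectors
#'   `c(mean=, dispersion=)` of negative-binomial parameters (dispersion is
#'   the NB `size`); draws are clamped to at least 1.
#' @param base_rates Named vector of baseline emission probabilities per
#'   dimension; the remainder at every hour goes to a neutral filler
#'   vocabulary.
#' @param peak_hours Named vector of peak clock hours for the dimensions
#'   with a diurnal signal; dimensions absent here are flat.
#' @param amplitude Logit-scale amplitude for the dimensions in
#'   `peak_hours` (a single number or a named vector).
#' @param user_sd SD of the per-user random effect on the logit scale.
#' @param covariate_effects Named list: outcome dimension -> named numeric
#'   vector of logit-scale slopes (see above).
#' @param activity Length-24 vector of posting-time probabilities over
#'   clock hours (normalized internally).
#' @param words_per_dim Vocabulary size per dimension (disjoint word lists).
#' @param n_filler Size of the neutral filler vocabulary.
#' @param overlap_frac Fraction of each dimension's vocabulary shared with
#'   the next dimension, to exercise multi-dimension matching.
#' @param seed Mandatory integer seed; generation is fully reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_users = 200,
                       postings_per_user = c(mean = 80, dispersion = 2),
                       tokens_per_posting = c(mean = 20, dispersion = 4),
                       base_rates = c(positive_affect = 0.014,
                                      negative_affect = 0.016,
                                      joy = 0.015, sadness = 0.005,
                                      anger = 0.0005, fear = 0.0006,
                                      disgust = 0.004,
                                      sexual = 0.009, health = 0.008),
                       peak_hours = c(positive_affect = 8, joy = 8,
                                      negative_affect = 3, sadness = 3,
                                      disgust = 3, health = 3, sexual = 23),
                       amplitude = 0.8,
                       user_sd = 0.4,
                       covariate_effects = list(),
                       activity = rep(1, 24),
                       words_per_dim = 20,
                       n_filler = 200,
                       overlap_frac = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  dims <- names(base_rates)
  if (is.null(dims) || any(!nzchar(dims))) abort("`base_rates` must be named.")
  if (any(base_rates <= 0 | base_rates >= 1)) {
    abort("`base_rates` must lie strictly in (0, 1).")
  }
  if (length(activity) != 24 || any(activity < 0) || sum(activity) == 0) {
    abort("`activity` must be 24 non-negative hourly weights.")
  }
  bad_peaks <- setdiff(names(peak_hours), dims)
  if (length(bad_peaks) > 0) {
    abort(sprintf("`peak_hours` names unknown dimension(s): %s",
                  paste(bad_peaks, collapse = ", ")))
  }
  amp <- rep(0, length(dims))
  names(amp) <- dims
  if (length(names(peak_hours)) > 0) {
    if (length(amplitude) == 1 && is.null(names(amplitude))) {
      amp[names(peak_hours)] <- amplitude
    } else {
      amp[names(amplitude)] <- amplitude
    }
  }
  for (d in names(covariate_effects)) {
    if (!d %in% dims) abort(sprintf("`covariate_effects` targets unknown dimension '%s'.", d))
    nm <- names(covariate_effects[[d]])
    ok <- nm %in% c(dims, "age_gt25", "log_followers", "log_followees", "log_chat_groups")
    if (is.null(nm) || !all(ok)) {
      abort("`covariate_effects` entries must be named by a dimension or a profile covariate.")
    }
  }
  ## Deterministic part of the hourly emission probabilities must leave
  ## room for the filler vocabulary at every hour.
  worst <- vapply(0:23, function(h) {
    sum(plogis(qlogis(base_rates) + amp * cos(2 * pi * (h - ifelse(dims %in% names(peak_hours), peak_hours[dims], 0)) / 24)))
  }, numeric(1))
  if (any(worst >= 1)) {
    abort("Configured emission probabilities exceed 1 at some hour; lower `base_rates` or `amplitude`.")
  }
  structure(list(
    n_users = as.integer(n_users),
    postings_per_user = postings_per_user,
    tokens_per_posting = tokens_per_posting,
    base_rates = base_rates, dims = dims,
    peak_hours = peak_hours, amplitude = amp,
    user_sd = user_sd, covariate_effects = covariate_effects,
    activity = activity / sum(activity),
    words_per_dim = as.integer(words_per_dim),
    n_filler = as.integer(n_filler),
    overlap_frac = overlap_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## Dimension vocabularies: disjoint synthetic word lists, optionally with a
## shared block between consecutive dimensions.
sim_vocabulary <- function(config) {
  dims <- config$dims
  W <- config$words_per_dim
  vocab <- lapply(seq_along(dims), function(i) {
    sprintf("%s_w%02d", dims[i], seq_len(W))
  })
  names(vocab) <- dims
  k <- round(config$overlap_frac * W)
  if (k > 0 && length(dims) > 1) {
    for (i in seq_len(length(dims) - 1)) {
      shared <- sprintf("shared_%s_%s_w%02d", dims[i], dims[i + 1], seq_len(k))
      vocab[[i]][seq_len(k)] <- shared
      vocab[[i + 1]] <- unique(c(vocab[[i + 1]], shared))
    }
  }
  filler <- sprintf("filler_w%03d", seq_len(config$n_filler))
  list(dims = vocab, filler = filler)
}

#' Generate a synthetic posting corpus with known ground truth
#'
#' Draws user profiles from demographic marginals typical of the study
#' population, posting times from the configured hourly activity profile,
#' and each token i.i.d. from the hour's categorical distribution over the
#' dimension vocabularies and a neutral filler vocabulary. Emission rates
#' carry a sinusoidal diurnal signal on the logit scale, per-user random
#' effects, and any configured covariate couplings. Fully reproducible for
#' a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_corpus`:
#' * `postings` — tibble `user_id`, `timestamp`, `hour`, `text`;
#' * `profiles` — tibble in the [read_profiles()] layout;
#' * `lexicon` — the [lexicon()] of the generating vocabularies;
#' * `truth` — generator ground truth: per-user random effects, expected
#'   per-user emission rates, peak hours, amplitudes and covariate slopes.
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config().")
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n <- config$n_users
  dims <- config$dims
  D <- length(dims)
  user_id <- sprintf("u%05d", seq_len(n))
  vocab <- sim_vocabulary(config)

  profiles <- sim_profiles(user_id)

  ## Per-user random effects and covariate couplings on the logit scale.
  b <- matrix(rnorm(n * D, 0, config$user_sd), nrow = n,
              dimnames = list(user_id, dims))
  cov_shift <- matrix(0, nrow = n, ncol = D, dimnames = list(user_id, dims))
  for (d in names(config$covariate_effects)) {
    eff <- config$covariate_effects[[d]]
    for (k in names(eff)) {
      x <- if (k %in% dims) {
        b[, k]
      } else if (k == "age_gt25") {
        as.numeric(profiles$age > 25)
      } else {
        v <- log10(profiles[[sub("^log_", "", k)]] + 1)
        (v - mean(v)) / max(sd(v), 1e-12)
      }
      cov_shift[, d] <- cov_shift[, d] + eff[[k]] * x
    }
  }

  ## Hourly emission probabilities p[[d]]: n_users x 24.
  hours <- 0:23
  p <- vector("list", D)
  names(p) <- dims
  for (d in dims) {
    peak <- if (d %in% names(config$peak_hours)) config$peak_hours[[d]] else 0
    diel <- config$amplitude[[d]] * cos(2 * pi * (hours - peak) / 24)
    eta <- outer(b[, d] + cov_shift[, d], rep(1, 24)) +
      matrix(qlogis(config$base_rates[[d]]) + diel, nrow = n, ncol = 24,
             byrow = TRUE)
    p[[d]] <- plogis(eta)
  }
  psum <- Reduce(`+`, p)
  if (any(psum >= 1)) {
    abort("Realized emission probabilities exceed 1 at some user-hour; lower `base_rates`, `amplitude` or `user_sd`.")
  }

  ## Posting skeleton.
  n_post <- pmax(1L, rnbinom(n, size = config$postings_per_user[["dispersion"]],
                             mu = config$postings_per_user[["mean"]]))
  post_user <- rep.int(seq_len(n), n_post)
  total_posts <- length(post_user)
  post_hour <- sample(hours, total_posts, replace = TRUE, prob = config$activity)
  post_ntok <- pmax(1L, rnbinom(total_posts,
                                size = config$tokens_per_posting[["dispersion"]],
                                mu = config$tokens_per_posting[["mean"]]))

  ## Token emission, grouped by user-hour for one categorical draw each.
  texts <- character(total_posts)
  W <- lengths(vocab$dims)
  for (u in seq_len(n)) {
    idx <- which(post_user == u)
    for (h in unique(post_hour[idx])) {
      ih <- idx[post_hour[idx] == h]
      ntok <- post_ntok[ih]
      total <- sum(ntok)
      probs <- c(vapply(p, function(m) m[u, h + 1], numeric(1)),
                 1 - psum[u, h + 1])
      labels <- sample.int(D + 1, total, replace = TRUE, prob = probs)
      words <- character(total)
      for (d in seq_len(D)) {
        k <- which(labels == d)
        if (length(k) > 0) {
          words[k] <- vocab$dims[[d]][sample.int(W[d], length(k), replace = TRUE)]
        }
      }
      k <- which(labels == D + 1)
      if (length(k) > 0) {
        words[k] <- vocab$filler[sample.int(config$n_filler, length(k), replace = TRUE)]
      }
      texts[ih] <- vapply(split(words, rep.int(seq_along(ih), ntok)),
                          paste, character(1), collapse = " ")
    }
  }

  timestamp <- lubridate::make_datetime(
    year = 2015,
    month = sample(1:12, total_posts, replace = TRUE),
    day = sample(1:28, total_posts, replace = TRUE),
    hour = post_hour,
    min = sample(0:59, total_posts, replace = TRUE),
    sec = sample(0:59, total_posts, replace = TRUE),
    tz = "Asia/Shanghai"
  )
  postings <- tibble::tibble(
    user_id = user_id[post_user],
    timestamp = timestamp,
    hour = as.integer(post_hour),
    text = texts
  )

  ## Expected per-user rate: activity-weighted mean over hours of p(u,h,d),
  ## the target of the active-hours baseline for a user active in all hours.
  expected <- purrr::imap(p, function(m, d) {
    tibble::tibble(user_id = user_id, dimension = d,
                   rate = drop(m %*% config$activity))
  }) |> dplyr::bind_rows()

  truth <- list(
    config = config,
    user_effects = tibble::tibble(
      user_id = rep(user_id, D),
      dimension = rep(dims, each = n),
      effect = as.vector(b)
    ),
    expected_rates = expected,
    peak_hours = config$peak_hours,
    amplitude = config$amplitude,
    covariate_effects = config$covariate_effects
  )
  structure(list(postings = postings, profiles = profiles,
                 lexicon = lexicon(vocab$dims), truth = truth),
            class = "sim_corpus")
}

## Demographic marginals mirroring the published sample composition of the
## study population (proportions of N = 5871).
sim_profiles <- function(user_id) {
  n <- length(user_id)
  draw <- function(levels, probs) sample(levels, n, replace = TRUE, prob = probs)
  age_band <- draw(c("le25", "gt25"), c(0.5401, 0.4599))
  age <- ifelse(age_band == "le25", sample(18:25, n, TRUE), sample(26:45, n, TRUE))
  education <- draw(c("high_school_or_below", "above_high_school", NA),
                    c(0.1310, 0.3533, 0.5157))
  geolocation <- draw(c("Guangzhou", "Shenzhen", "Dongguan", "Foshan"),
                      c(0.3405, 0.3170, 0.0869, 0.2556))
  hometown <- draw(c("Guangdong", "Hunan", NA), c(0.4839, 0.3648, 0.1513))
  bmi_band <- draw(c("underweight", "normal", "overweight", "obese"),
                   c(0.1639, 0.7576, 0.0664, 0.0121))
  bmi <- stats::runif(n,
                      c(underweight = 16, normal = 18.5, overweight = 25, obese = 30)[bmi_band],
                      c(underweight = 18.4, normal = 24.9, overweight = 29.9, obese = 35)[bmi_band])
  height <- rnorm(n, 1.72, 0.05)
  sex_role <- draw(c("receptive", "insertive", "versatile", NA),
                   c(0.2035, 0.2892, 0.2255, 0.2818))
  count_draw <- function(mu, sd) pmax(0, round(10^rnorm(n, mu, sd)) - 1)
  tibble::tibble(
    user_id = user_id,
    age = age,
    education = education,
    geolocation = geolocation,
    hometown = hometown,
    height = round(height, 2),
    weight = round(bmi * height^2, 1),
    sex_role = sex_role,
    followers = count_draw(2.341, 0.430),
    followees = count_draw(1.786, 0.889),
    chat_groups = count_draw(0.277, 0.331)
  )
}

#' Write a synthetic corpus in the formats the readers consume
#'
#' Writes `postings.jsonl`, `profiles.csv`, `lexicon.tsv` and `truth.json`
#' into `dir`, byte-identical for a fixed generator seed.
#'
#' @param sim A `sim_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_corpus <- function(sim, dir) {
  if (!inherits(sim, "sim_corpus")) abort("`sim` must come from generate_corpus().")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    postings = file.path(dir, "postings.jsonl"),
    profiles = file.path(dir, "profiles.csv"),
    lexicon = file.path(dir, "lexicon.tsv"),
    truth = file.path(dir, "truth.json")
  )
  post <- sim$postings
  lines <- sprintf(
    '{"user_id":%s,"ts":%s,"text":%s}',
    vapply(post$user_id, jsonlite::toJSON, character(1), auto_unbox = TRUE),
    vapply(format(post$timestamp, "%Y-%m-%dT%H:%M:%S%z"), jsonlite::toJSON,
           character(1), auto_unbox = TRUE),
    vapply(post$text, jsonlite::toJSON, character(1), auto_unbox = TRUE)
  )
  readr::write_lines(lines, paths[["postings"]])
  readr::write_csv(sim$profiles, paths[["profiles"]])
  lex_tbl <- as_tibble(sim$lexicon)
  readr::write_lines(sprintf("%s\t%s", lex_tbl$dimension, lex_tbl$entry),
                     paths[["lexicon"]])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Score recovery of the generator's ground truth
#'
#' Compares pipeline outputs on a synthetic corpus with the generating
#' parameters: bias and RMSE of per-user baselines against the expected
#' emission rates, circular peak-hour error of the diurnal curves for every
#' dimension with a generated diurnal signal, and sign/screening agreement
#' of recovered covariate slopes.
#'
#' @param sim A `sim_corpus` from [generate_corpus()].
#' @param baselines Output of [affect_baselines()] on the scored corpus.
#' @param curve Optional [diurnal_curve()] output.
#' @param regression Optional [screen_then_fit()] output (multivariate
#'   stage rows are used).
#' @param peak_width Window width handed to [peak_window()].
#' @return A list of tibbles: `baseline` (per-dimension bias/RMSE),
#'   `peaks` (recovered vs generating peak hour), `slopes` (sign and
#'   screening agreement per configured effect).
#' @export
recovery_report <- function(sim, baselines, curve = NULL, regression = NULL,
                            peak_width = 3) {
  if (!inherits(sim, "sim_corpus")) abort("`sim` must come from generate_corpus().")
  truth <- sim$truth
  base_tbl <- baselines |>
    dplyr::mutate(dimension = as.character(.data$dimension)) |>
    dplyr::inner_join(truth$expected_rates,
                      by = c("user_id", "dimension")) |>
    dplyr::group_by(.data$dimension) |>
    dplyr::summarise(
      n_users = dplyr::n(),
      bias = mean(.data$baseline - .data$rate),
      rmse = sqrt(mean((.data$baseline - .data$rate)^2)),
      .groups = "drop"
    )

  peaks <- NULL
  if (!is.null(curve)) {
    signal_dims <- names(truth$peak_hours)
    pw <- peak_window(dplyr::filter(
      dplyr::mutate(curve, dimension = as.character(.data$dimension)),
      .data$dimension %in% signal_dims), width = peak_width)
    peaks <- pw |>
      dplyr::mutate(
        true_peak = unname(truth$peak_hours[.data$dimension]),
        error_hours = circular_hour_distance(.data$peak_hour, .data$true_peak),
        contains_true = circular_window_contains(.data$start_hour, .data$end_hour,
                                                 .data$true_peak)
      )
  }

  slopes <- NULL
  if (!is.null(regression) && length(truth$covariate_effects) > 0) {
    rows <- list()
    for (d in names(truth$covariate_effects)) {
      eff <- truth$covariate_effects[[d]]
      for (k in names(eff)) {
        hit <- regression |>
          dplyr::filter(.data$stage == "multivariate", .data$outcome == d,
                        .data$term == k)
        rows[[length(rows) + 1]] <- tibble::tibble(
          outcome = d, term = k, true_slope = eff[[k]],
          estimate = if (nrow(hit) > 0) hit$estimate[1] else NA_real_,
          p_value = if (nrow(hit) > 0) hit$p_value[1] else NA_real_,
          screened_in = nrow(hit) > 0,
          sign_match = nrow(hit) > 0 && sign(hit$estimate[1]) == sign(eff[[k]]),
          significant = nrow(hit) > 0 && isTRUE(hit$significant[1])
        )
      }
    }
    slopes <- dplyr::bind_rows(rows)
  }

  list(baseline = base_tbl, peaks = peaks, slopes = slopes)
}

circular_hour_distance <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

circular_window_contains <- function(start, end, h) {
  ifelse(start <= end, h >= start & h <= end, h >= start | h <= end)
}
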