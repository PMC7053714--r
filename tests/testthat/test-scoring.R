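test_that("user-hour accumulation pools counts and derives composite scores", {
  lx <- lexicon(list(joy = "love", sadness = "tear", anger = "roar",
                     fear = "panic", disgust = "wordy",
                     positive_affect = "sweet", negative_affect = "hurt"))
  p <- make_postings("u1", 10, "love tear love")
  ct <- count_user_hours(p, lx)
  expect_equal(ct$token_total, 3L)
  expect_equal(ct$joy, 2L)
  expect_equal(ct$sadness, 1L)
  expect_equal(ct$positive_emotion_score, 1L) # joy - (sad + anger + fear + disgust)

  p2 <- make_postings("u1", 10, "sweet hurt hurt hurt hurt hurt sweet x y z")
  ct2 <- count_user_hours(p2, lx)
  expect_equal(ct2$positive_affect, 2L)
  expect_equal(ct2$negative_affect, 5L)
  expect_equal(ct2$positive_sentiment_score, -3L)
})

test_that("postings of one user in one clock hour merge additively", {
  lx <- tiny_lexicon()
  texts <- c("love tear sweet", "kiss love", "infection panic roar")
  pooled <- count_user_hours(make_postings("u", 7, texts), lx)
  singles <- lapply(texts, function(tx) count_user_hours(make_postings("u", 7, tx), lx))
  for (d in c(dimension_names(lx), "token_total")) {
    expect_equal(pooled[[d]], sum(vapply(singles, function(s) s[[d]], integer(1))),
                 info = d)
  }
  # distinct hours and users stay distinct
  spread <- count_user_hours(make_postings(c("u", "u", "v"), c(7, 8, 7), texts), lx)
  expect_equal(nrow(spread), 3)
})

test_that("hourly probabilities are count / token_total, missing when no tokens", {
  lx <- lexicon(list(joy = "love", sadness = "tear", anger = "roar",
                     fear = "panic", disgust = "wordy"))
  p <- make_postings(c("u", "u"), c(1, 2),
                     c("love love a b c d e f g h", ",,,"))
  pa <- hour_probabilities(count_user_hours(p, lx))
  joy1 <- dplyr::filter(pa, dimension == "joy", hour == 1)
  expect_equal(joy1$pa, 0.2) # 2 joy words in 10 tokens
  empty <- dplyr::filter(pa, hour == 2)
  expect_true(all(empty$token_total == 0))
  expect_true(all(is.na(empty$pa)))
  # signed composite score
  p3 <- make_postings("u", 3, "hurt hurt hurt sweet w1 w2 w3 w4 w5 w6")
  lx2 <- lexicon(list(positive_affect = "sweet", negative_affect = "hurt"))
  pa3 <- hour_probabilities(count_user_hours(p3, lx2))
  expect_equal(dplyr::filter(pa3, dimension == "positive_sentiment_score")$pa, -0.2)
})

test_that("baseline conventions: active-hours mean vs sum over the 24-hour cycle", {
  pa <- tibble::tibble(
    user_id = "u", hour = 0L, dimension = factor("joy"),
    count = 24L, token_total = 100L, pa = 0.24
  )
  expect_equal(affect_baselines(pa, "all_hours")$baseline, 0.01)
  expect_equal(affect_baselines(pa, "active_hours")$baseline, 0.24)

  const <- tibble::tibble(
    user_id = "u", hour = 0:23, dimension = factor("joy"),
    count = 3L, token_total = 10L, pa = 0.3
  )
  expect_equal(affect_baselines(const, "all_hours")$baseline, 0.3)
  expect_equal(affect_baselines(const, "active_hours")$baseline, 0.3)

  gone <- tibble::tibble(user_id = "v", hour = 1L, dimension = factor("joy"),
                         count = 0L, token_total = 0L, pa = NA_real_)
  expect_error(affect_baselines(gone), "no defined hours")
})

test_that("sparse baselines equal a brute-force re-summation oracle", {
  fx <- scored_fixture(seed = 303, n_users = 15)
  bl <- affect_baselines(fx$pa, "active_hours")
  bl_all <- affect_baselines(fx$pa, "all_hours")
  manual <- fx$pa[!is.na(fx$pa$pa), ]
  for (i in sample.int(nrow(bl), 25)) {
    rows <- manual[manual$user_id == bl$user_id[i] &
                     manual$dimension == bl$dimension[i], ]
    expect_equal(bl$baseline[i], sum(rows$pa) / nrow(rows))
  }
  for (i in sample.int(nrow(bl_all), 10)) {
    rows <- manual[manual$user_id == bl_all$user_id[i] &
                     manual$dimension == bl_all$dimension[i], ]
    expect_equal(bl_all$baseline[i], sum(rows$pa) / 24)
  }
})

test_that("relative probabilities recentre by user baseline plus grand mean", {
  pa <- tibble::tibble(
    user_id = rep(c("u1", "u2"), each = 2),
    hour = rep(0:1, 2),
    dimension = factor("joy"),
    count = 1L, token_total = 10L,
    pa = c(0.1, 0.3, 0.2, 0.2)
  )
  rpa <- relative_probabilities(pa)
  expect_equal(rpa$baseline, c(0.2, 0.2, 0.2, 0.2))
  expect_equal(rpa$grand_mean, rep(0.2, 4))
  expect_equal(rpa$rpa, c(0.1, 0.3, 0.2, 0.2))
  cv <- diurnal_curve(rpa)
  expect_equal(dplyr::filter(cv, hour == 0)$rpa_mean, 0.15)
  expect_equal(dplyr::filter(cv, hour == 1)$rpa_mean, 0.25)
  expect_equal(dplyr::filter(cv, hour == 2)$n_users, 0L)
  expect_true(is.na(dplyr::filter(cv, hour == 2)$rpa_mean))

  # constant user: deviations vanish, rpa is the constant
  pac <- tibble::tibble(user_id = "u", hour = 0:23, dimension = factor("joy"),
                        count = 1L, token_total = 10L, pa = 0.07)
  expect_equal(relative_probabilities(pac)$rpa, rep(0.07, 24))
})

test_that("centering identities hold to machine precision on a simulated corpus", {
  fx <- scored_fixture(seed = 404, n_users = 25)
  rpa <- relative_probabilities(fx$pa)
  defined <- dplyr::filter(rpa, !is.na(rpa))
  check <- defined |>
    dplyr::group_by(dimension) |>
    dplyr::summarise(
      gap = abs(mean(rpa) - grand_mean[1]),
      .groups = "drop")
  expect_lt(max(check$gap), 1e-12)
  per_user <- defined |>
    dplyr::group_by(user_id, dimension) |>
    dplyr::summarise(dev = abs(sum(pa - baseline)), .groups = "drop")
  expect_lt(max(per_user$dev), 1e-12)
})

test_that("composite scores stay within [-1, 1] and unipolar within [0, 1]", {
  fx <- scored_fixture(seed = 505, n_users = 10)
  defined <- dplyr::filter(fx$pa, !is.na(pa))
  comp <- dplyr::filter(defined, grepl("score", dimension))
  uni <- dplyr::filter(defined, !grepl("score", dimension))
  expect_true(all(comp$pa >= -1 & comp$pa <= 1))
  expect_true(all(uni$pa >= 0 & uni$pa <= 1))
})

test_that("peak windows maximize the circular window mean with earliest-start ties", {
  vals <- rep(0, 24); vals[9] <- 1 # unique max at hour 8
  expect_equal(peak_window(vals, 1)$start_hour, 8L)
  expect_equal(peak_window(vals, 1)$end_hour, 8L)

  sinus <- cos(2 * pi * ((0:23) - 3) / 24)
  pw <- peak_window(sinus, 3)
  expect_true(pw$start_hour <= 3 && pw$end_hour >= 3)
  # exhaustive-scan oracle over all 24 circular windows
  ext <- c(sinus, sinus)
  means <- vapply(0:23, function(s) mean(ext[(s + 1):(s + 3)]), numeric(1))
  expect_equal(pw$mean_value, max(means))
  expect_equal(pw$start_hour, which.max(means) - 1L)

  expect_equal(peak_window(rep(0.5, 24), 4)$start_hour, 0L)
  expect_equal(peak_window(rep(0.5, 24), 4)$end_hour, 3L)

  # a window wraps around midnight
  wrap <- rep(0, 24); wrap[c(24, 1)] <- 1 # hours 23 and 0
  expect_equal(peak_window(wrap, 2)$start_hour, 23L)

  lone <- rep(NA_real_, 24); lone[5] <- 1
  expect_error(peak_window(lone, 3), "defined hours")
  expect_error(peak_window(1:10, 3), "24 hourly")
})

test_that("neutral filler dilution rescales probabilities but not the peak hour", {
  lx <- lexicon(list(joy = "love", sadness = "tear", anger = "roar",
                     fear = "panic", disgust = "wordy"))
  base <- make_postings(rep("u", 4), c(1, 1, 2, 3),
                        c("love x", "love love x x", "love x x x", "tear x"))
  diluted <- base
  # one filler token per original token: every probability halves
  diluted$text <- vapply(base$text, function(tx) {
    n <- length(tokenize(tx)[[1]])
    paste(tx, paste(rep("pad", n), collapse = " "))
  }, character(1))
  pa1 <- hour_probabilities(count_user_hours(base, lx))
  pa2 <- hour_probabilities(count_user_hours(diluted, lx))
  j1 <- dplyr::filter(pa1, dimension == "joy")
  j2 <- dplyr::filter(pa2, dimension == "joy")
  expect_equal(j2$pa, j1$pa / 2)
  expect_equal(which.max(j1$pa), which.max(j2$pa))
})
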