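test_that("OLS fits exactly and matches the normal-equations oracle", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), y = 2 * c(1, 2, 3, 4))
  fit <- fit_ols(d, "y", "x", intercept = FALSE)
  expect_equal(fit$estimate, 2)

  d2 <- tibble::tibble(x = rnorm(20), z = rnorm(20), y = 5)
  fit2 <- fit_ols(d2, "y", c("x", "z"))
  expect_equal(fit2$estimate[fit2$term != "(Intercept)"], c(0, 0))

  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(8:20, 1)
      d3 <- tibble::tibble(a = rnorm(n), b = rnorm(n), y = rnorm(n))
      fit3 <- fit_ols(d3, "y", c("a", "b"))
      X <- cbind(1, d3$a, d3$b)
      expect_equal(fit3$estimate, unname(oracle_ols(X, d3$y)), tolerance = 1e-10)
    }
  })
})

test_that("collinear designs error naming the offending columns", {
  d <- tibble::tibble(x = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(fit_ols(d, "y", c("x", "x2")), "x2")
  expect_error(perm_lm(d, "y", c("x", "x2"), B = 99, seed = 1), "rank deficient")
})

test_that("factor terms use treatment coding against the declared reference level", {
  d <- tibble::tibble(
    g = factor(rep(c("ref", "alt"), each = 10), levels = c("ref", "alt")),
    y = rep(c(1, 3), each = 10)
  )
  fit <- fit_ols(d, "y", "g")
  expect_equal(fit$term, c("(Intercept)", "galt"))
  expect_equal(fit$estimate, c(1, 2))
})

test_that("permutation p-values are deterministic for a fixed seed and scheme", {
  withr::with_seed(42, {
    d <- tibble::tibble(x = rnorm(30), z = rnorm(30), y = rnorm(30))
  })
  for (sch in c("response", "freedman_lane")) {
    f1 <- perm_lm(d, "y", c("x", "z"), scheme = sch, B = 199, seed = 99)
    f2 <- perm_lm(d, "y", c("x", "z"), scheme = sch, B = 199, seed = 99)
    f3 <- perm_lm(d, "y", c("x", "z"), scheme = sch, B = 199, seed = 100)
    expect_identical(tidy(f1), tidy(f2))
    expect_false(identical(tidy(f1)$p_value, tidy(f3)$p_value))
  }
  expect_error(perm_lm(d, "y", "x", B = 50, seed = 1), "at least 99")
  expect_error(perm_lm(d, "y", "x", B = 199), "seed")
})

test_that("a perfect linear relation attains the minimum attainable p-value", {
  d <- tibble::tibble(x = seq_len(40), y = seq_len(40))
  fit <- perm_lm(d, "y", "x", scheme = "response", B = 999, seed = 3)
  expect_equal(tidy(fit)$p_value[tidy(fit)$term == "x"], 1 / 1000)
})

test_that("permutation and classical t-test p-values agree for Gaussian errors", {
  withr::with_seed(77, {
    n <- 150
    d <- tibble::tibble(x = rnorm(n), z = rnorm(n))
    d$y <- 0.25 * d$x + rnorm(n)
  })
  fit <- perm_lm(d, "y", c("x", "z"), scheme = "freedman_lane", B = 1999, seed = 8)
  classical <- summary(lm(y ~ x + z, data = d))$coefficients
  p_perm <- tidy(fit)$p_value[tidy(fit)$term == "x"]
  p_t <- classical["x", "Pr(>|t|)"]
  expect_equal(p_perm, p_t, tolerance = 0.35) # simulation-error agreement
})

test_that("tidy and glance expose the fit in broom style", {
  d <- tibble::tibble(x = rnorm(25), y = rnorm(25))
  fit <- perm_lm(d, "y", "x", B = 99, seed = 5)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "statistic", "p_value"))
  gl <- glance(fit)
  expect_equal(gl$n, 25)
  expect_equal(gl$B, 99L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the univariate screen gates entry to the multivariate model", {
  withr::with_seed(12, {
    n <- 120
    d <- tibble::tibble(strong = rnorm(n), null1 = rnorm(n), null2 = rnorm(n))
    d$y <- 1.2 * d$strong + rnorm(n)
  })
  res <- screen_then_fit(d, "y", c("strong", "null1", "null2"),
                         B = 499, seed = 21)
  uni <- dplyr::filter(res, stage == "univariate")
  expect_equal(nrow(uni), 3)
  strong_multi <- dplyr::filter(res, stage == "multivariate", term == "strong")
  expect_equal(nrow(strong_multi), 1)
  expect_true(strong_multi$significant)
  expect_gt(strong_multi$estimate, 0)
  # screened-out terms do not appear in the multivariate stage
  out_terms <- dplyr::filter(uni, !screened_in)$term
  expect_false(any(out_terms %in% dplyr::filter(res, stage == "multivariate")$term))

  # screen_alpha = 1 admits everything
  res_all <- screen_then_fit(d, "y", c("strong", "null1"),
                             screen_alpha = 1, B = 199, seed = 22)
  expect_setequal(dplyr::filter(res_all, stage == "multivariate")$term,
                  c("strong", "null1"))

  # nothing passes: multivariate stage skipped with a warning
  d0 <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  d0$x <- d0$y * 0 + rnorm(50) # pure noise
  expect_warning(
    res0 <- screen_then_fit(d0, "y", "x", screen_alpha = 1e-4,
                            B = 199, seed = 23),
    "skipped")
  expect_true(all(res0$stage == "univariate"))
})

test_that("Cohen's kappa matches hand-computed agreement statistics", {
  # perfect agreement with mixed margins
  r <- rep(c("a", "b", "c"), c(10, 5, 3))
  expect_equal(cohen_kappa(r, r)$kappa, 1)
  expect_equal(cohen_kappa(r, r)$agreement, 100)

  # constructed 2x2 table: a=40, b=5, c=10, d=45
  r1 <- rep(c("pos", "pos", "neg", "neg"), c(40, 5, 10, 45))
  r2 <- rep(c("pos", "neg", "pos", "neg"), c(40, 5, 10, 45))
  k <- cohen_kappa(r1, r2)
  # p_o = 0.85, p_e = (50*45 + 50*55)/100^2 = 0.5, kappa = 0.35/0.5
  expect_equal(k$kappa, 0.7)
  expect_equal(k$agreement, 85)

  # independent raters matching margins exactly: kappa 0
  r3 <- rep(c("x", "x", "y", "y"), c(9, 3, 3, 1))
  r4 <- rep(c("x", "y", "x", "y"), c(9, 3, 3, 1))
  expect_equal(cohen_kappa(r3, r4)$kappa, 0)

  # degenerate: both raters constant and identical
  k0 <- cohen_kappa(rep("a", 10), rep("a", 10))
  expect_true(is.na(k0$kappa))
  expect_equal(k0$agreement, 100)
})

test_that("reported proportions use half-away-from-zero rounding", {
  expect_equal(proportion_summary(97, 387)$percent, 25.1)
  expect_equal(proportion_summary(0, 50)$percent, 0)
  expect_equal(proportion_summary(4448, 5871, digits = 2)$percent, 75.76)
  # a tie that banker's rounding would send the other way
  expect_equal(proportion_summary(1, 40)$percent, 2.5)
  expect_equal(proportion_summary(35, 1000, digits = 0)$percent, 4)
  expect_equal(round_half_up(-2.5), -3)
  expect_error(proportion_summary(1, 0), "positive")
})
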