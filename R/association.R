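#' Ordinary least squares fit for affect outcomes
#'
#' Fits the linear model `outcome ~ terms` by least squares with treatment
#' coding for factors (the first factor level is the reference; see
#' [derive_covariates()] for the analysis reference levels). A
#' rank-deficient design is an error naming the collinear columns rather
#' than a silent `NA` coefficient.
#'
#' @param data Tibble with one row per user (see [build_user_summary()]).
#' @param outcome Name of the outcome column.
#' @param terms Character vector of predictor column names; `character(0)`
#'   fits the intercept-only model.
#' @param intercept Include an intercept (default `TRUE`).
#' @return A tibble with `term` and `estimate` for every design column.
#' @export
fit_ols <- function(data, outcome, terms, intercept = TRUE) {
  dm <- build_design(data, outcome, terms, intercept = intercept)
  fit <- stats::lm.fit(dm$X, dm$y)
  if (fit$rank < ncol(dm$X)) {
    dropped <- colnames(dm$X)[is.na(fit$coefficients)]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s.",
                  paste(dropped, collapse = ", ")))
  }
  tibble::tibble(term = colnames(dm$X), estimate = unname(fit$coefficients))
}

## Shared design-matrix builder: complete cases, treatment contrasts.
build_design <- function(data, outcome, terms, intercept = TRUE) {
  assert_columns(data, c(outcome, terms), "data")
  cols <- data[c(outcome, terms)]
  keep <- complete.cases(cols)
  if (!all(keep)) {
    inform(sprintf("Dropping %d row(s) with missing outcome or predictors.",
                   sum(!keep)))
  }
  cols <- droplevels(cols[keep, , drop = FALSE]) # unused factor levels would give all-zero columns
  y <- as.numeric(cols[[outcome]])
  rhs <- if (length(terms) == 0) "1" else paste(
    c(if (intercept) NULL else "0",
      vapply(terms, function(t) sprintf("`%s`", t), character(1))),
    collapse = " + ")
  f <- stats::as.formula(paste("~", rhs))
  X <- model.matrix(f, data = cols)
  colnames(X) <- sub("^`|`$", "", colnames(X))
  if (nrow(X) <= ncol(X)) {
    abort(sprintf("Too few complete rows (%d) for %d parameters.",
                  nrow(X), ncol(X)))
  }
  list(X = X, y = y, n = nrow(X))
}

## Columns of the design matrix belonging to one model term (a factor term
## expands to several indicator columns).
term_columns <- function(X, data, term) {
  v <- data[[term]]
  if (is.factor(v) || is.character(v)) {
    lv <- levels(as.factor(v))
    cand <- paste0(term, lv)
    intersect(colnames(X), cand)
  } else {
    intersect(colnames(X), term)
  }
}

## t statistics for every coefficient of an OLS fit, vectorized over many
## response vectors at once. Y is an n x B matrix; returns k x B.
## A zero residual variance yields an infinite t (perfect fit).
ols_t_matrix <- function(X, Y, XtX_inv, pinv) {
  B <- ncol(Y)
  n <- nrow(X)
  k <- ncol(X)
  beta <- pinv %*% Y                    # k x B
  resid <- Y - X %*% beta               # n x B
  rss <- colSums(resid^2)
  sigma2 <- rss / (n - k)
  d <- diag(XtX_inv)
  se <- sqrt(outer(d, sigma2))          # k x B
  t <- beta / se
  perfect <- se == 0
  if (any(perfect)) {
    t[perfect] <- sign(beta[perfect]) * Inf
    t[perfect & beta == 0] <- 0
  }
  t
}

#' Permutation-test linear regression
#'
#' Fits `outcome ~ terms` by OLS and attaches permutation p-values that do
#' not assume normally distributed errors — the appropriate inference for
#' skewed affect scores. Two schemes:
#'
#' * `response` — permute the outcome vector, refit, compare `|t|`;
#'   exact under the null of total exchangeability (the univariate default);
#' * `freedman_lane` — for each tested term, permute the residuals of the
#'   reduced model (all other terms), add them back to the reduced fit,
#'   refit the full model, compare the term's `|t|`; the standard choice
#'   when testing one term adjusted for others (the multivariate default).
#'
#' Two-sided p-values are `(b + 1) / (B + 1)` where `b` counts permuted
#' `|t|` at least as large as observed, so p is never zero and lies in
#' (0, 1].
#'
#' @param data Tibble of one row per user.
#' @param outcome Outcome column name.
#' @param terms Character vector of predictor column names.
#' @param test_terms Terms whose coefficients get permutation p-values;
#'   defaults to all of `terms`.
#' @param scheme `"freedman_lane"` or `"response"`.
#' @param B Number of permutations (>= 99; default 4999).
#' @param seed Integer seed; the fit is reproducible for a fixed seed.
#' @return An object of class `perm_lm` with [tidy()] and [glance()]
#'   methods; `tidy()` gives `term`, `estimate`, `statistic`, `p_value`.
#' @export
perm_lm <- function(data, outcome, terms, test_terms = NULL,
                    scheme = c("freedman_lane", "response"),
                    B = 4999, seed) {
  scheme <- match.arg(scheme)
  if (!is.numeric(B) || B < 99) {
    abort("`B` must be at least 99 permutations for a stable p-value.")
  }
  B <- as.integer(B)
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  test_terms <- test_terms %||% terms

  dm <- build_design(data, outcome, terms)
  X <- dm$X
  y <- dm$y
  n <- dm$n
  XtX <- crossprod(X)
  XtX_inv <- tryCatch(solve(XtX), error = function(e) {
    abort("Design matrix is rank deficient; drop collinear terms.")
  })
  pinv <- XtX_inv %*% t(X)
  t_obs <- drop(ols_t_matrix(X, matrix(y, ncol = 1), XtX_inv, pinv))
  beta_obs <- drop(pinv %*% y)

  perms <- withr::with_seed(seed, {
    matrix(replicate(B, sample.int(n)), nrow = n)
  })

  coef_rows <- list()
  if (scheme == "response") {
    Ystar <- matrix(y[perms], nrow = n)
    t_star <- ols_t_matrix(X, Ystar, XtX_inv, pinv)
    for (term in test_terms) {
      for (cn in term_columns(X, data, term)) {
        j <- match(cn, colnames(X))
        b <- sum(abs(t_star[j, ]) >= abs(t_obs[j]))
        coef_rows[[length(coef_rows) + 1]] <- tibble::tibble(
          term = cn, estimate = beta_obs[j], statistic = t_obs[j],
          p_value = (b + 1) / (B + 1))
      }
    }
  } else {
    for (term in test_terms) {
      cols <- term_columns(X, data, term)
      j_all <- match(cols, colnames(X))
      Xr <- X[, -j_all, drop = FALSE]
      XtXr_inv <- solve(crossprod(Xr))
      pinv_r <- XtXr_inv %*% t(Xr)
      fit_r <- Xr %*% (pinv_r %*% y)
      e_r <- y - fit_r
      Ystar <- matrix(fit_r, nrow = n, ncol = B) + matrix(e_r[perms], nrow = n)
      t_star <- ols_t_matrix(X, Ystar, XtX_inv, pinv)
      for (cn in cols) {
        j <- match(cn, colnames(X))
        b <- sum(abs(t_star[j, ]) >= abs(t_obs[j]))
        coef_rows[[length(coef_rows) + 1]] <- tibble::tibble(
          term = cn, estimate = beta_obs[j], statistic = t_obs[j],
          p_value = (b + 1) / (B + 1))
      }
    }
  }

  rss <- sum((y - X %*% beta_obs)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = dplyr::bind_rows(coef_rows),
    all_estimates = tibble::tibble(term = colnames(X), estimate = beta_obs),
    outcome = outcome, terms = terms, scheme = scheme,
    B = B, seed = seed, n = n,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    sigma = sqrt(rss / (n - ncol(X)))
  ), class = "perm_lm")
}

#' @export
print.perm_lm <- function(x, ...) {
  cat(sprintf("Permutation-test linear regression (%s scheme, B = %d, seed = %s)\n",
              x$scheme, x$B, format(x$seed)))
  cat(sprintf("Outcome: %s   n = %d   R^2 = %.4f\n", x$outcome, x$n, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' @rdname perm_lm
#' @param x A `perm_lm` object.
#' @param ... Unused.
#' @method tidy perm_lm
#' @export
tidy.perm_lm <- function(x, ...) x$coefficients

#' @rdname perm_lm
#' @method glance perm_lm
#' @export
glance.perm_lm <- function(x, ...) {
  tibble::tibble(n = x$n, B = x$B, scheme = x$scheme,
                 r.squared = x$r_squared, sigma = x$sigma,
                 outcome = x$outcome)
}

#' Univariate screen followed by multivariate permutation regression
#'
#' The two-stage analysis: each candidate term is first tested alone
#' (univariate permutation regression, `response` scheme); candidates with
#' any coefficient p-value below `screen_alpha` (0.20) enter a single
#' multivariate model in which every retained term is tested with the
#' `freedman_lane` scheme, flagged as significant below `final_alpha`
#' (0.05).
#'
#' @inheritParams perm_lm
#' @param candidate_terms Character vector of candidate predictors.
#' @param screen_alpha Univariate inclusion threshold (default 0.20).
#' @param final_alpha Multivariate significance threshold (default 0.05).
#' @return A tibble with one row per coefficient and stage: `stage`
#'   (`"univariate"`/`"multivariate"`), `outcome`, `term`, `coefficient`,
#'   `estimate`, `p_value`, `B`, `seed`, `screened_in`, `significant`.
#'   If no candidate passes the screen the multivariate stage is skipped
#'   with a warning.
#' @export
screen_then_fit <- function(data, outcome, candidate_terms,
                            screen_alpha = 0.20, final_alpha = 0.05,
                            B = 4999, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  uni <- purrr::imap(
    setNames(candidate_terms, candidate_terms),
    function(term, idx) {
      fit <- perm_lm(data, outcome, terms = term,
                     scheme = "response", B = B,
                     seed = derive_seed(seed, match(term, candidate_terms)))
      tidy(fit) |>
        dplyr::mutate(stage = "univariate", term_group = term)
    }
  ) |> dplyr::bind_rows()

  screened <- uni |>
    dplyr::group_by(.data$term_group) |>
    dplyr::summarise(min_p = min(.data$p_value), .groups = "drop") |>
    dplyr::filter(.data$min_p < screen_alpha)
  keep <- candidate_terms[candidate_terms %in% screened$term_group]

  uni_out <- uni |>
    dplyr::transmute(
      stage = .data$stage, outcome = outcome,
      term = .data$term_group, coefficient = .data$term,
      estimate = .data$estimate, p_value = .data$p_value,
      B = B, seed = seed,
      screened_in = .data$term_group %in% keep,
      significant = NA
    )

  if (length(keep) == 0) {
    warn(sprintf("No candidate passed the univariate screen at alpha = %g; multivariate stage skipped.",
                 screen_alpha))
    return(uni_out)
  }

  multi <- perm_lm(data, outcome, terms = keep,
                   scheme = "freedman_lane", B = B,
                   seed = derive_seed(seed, 0L))
  dm <- build_design(data, outcome, keep)
  coef_term <- character(0)
  for (t in keep) {
    for (cn in term_columns(dm$X, data, t)) coef_term[[cn]] <- t
  }
  term_of <- function(coefs) {
    vapply(coefs, function(cn) coef_term[[cn]] %||% cn, character(1))
  }
  multi_out <- tidy(multi) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::transmute(
      stage = "multivariate", outcome = outcome,
      term = term_of(.data$term), coefficient = .data$term,
      estimate = .data$estimate, p_value = .data$p_value,
      B = B, seed = seed, screened_in = TRUE,
      significant = .data$p_value < final_alpha
    )
  dplyr::bind_rows(uni_out, multi_out)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement for theme coding: kappa =
#' (p_o - p_e) / (1 - p_e), where p_o is the observed agreement and p_e
#' the expected agreement under independent raters with the observed
#' margins. When both raters assign a single identical category (p_e = 1)
#' kappa is undefined and reported as `NA` with 100% agreement.
#'
#' @param rater1,rater2 Vectors of labels, one element per rated item.
#' @return A tibble: `kappa`, `agreement` (percent), `n`.
#' @examples
#' cohen_kappa(rep(c("a", "b"), c(45, 55)), rep(c("a", "b", "a", "b"), c(40, 5, 10, 45)))
#' @export
cohen_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) {
    abort("`rater1` and `rater2` must have the same length.")
  }
  keep <- !is.na(rater1) & !is.na(rater2)
  r1 <- as.character(rater1[keep])
  r2 <- as.character(rater2[keep])
  n <- length(r1)
  if (n == 0) abort("No complete rater pairs.")
  lv <- sort(unique(c(r1, r2)))
  tab <- table(factor(r1, lv), factor(r2, lv))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps^0.5) NA_real_ else (p_o - p_e) / (1 - p_e)
  tibble::tibble(kappa = kappa, agreement = 100 * p_o, n = n)
}

#' Reported proportion with table rounding
#'
#' `100 * numerator / denominator`, rounded half away from zero to the
#' stated number of decimals — the convention of published frequency
#' tables. Returns both the rounded percentage and the exact fraction.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @param digits Decimals in the reported percentage (default 1).
#' @return A tibble: `numerator`, `denominator`, `fraction`, `percent`.
#' @examples
#' proportion_summary(97, 387) # 25.1%
#' @export
proportion_summary <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) abort("`denominator` must be positive.")
  if (any(numerator < 0)) abort("`numerator` must be non-negative.")
  frac <- numerator / denominator
  tibble::tibble(
    numerator = numerator, denominator = denominator,
    fraction = frac,
    percent = round_half_up(100 * frac, digits)
  )
}
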