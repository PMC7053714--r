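#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used when reporting percentages in epidemiological tables
#' (base R's `round()` rounds ties to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(2.5, 0) # 3, where round(2.5) gives 2
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Case-fold + unicode NFC normalization applied to both lexicon entries and
## tokens so matching is case-insensitive and composition-insensitive.
fold_text <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfc(x))
}

## Deterministic child seeds below 2^31 for staged stochastic steps.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
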