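# affectrhythm

Lexicon-based measurement of affective states — sentiment, basic emotions,
and sexual/health word use — in time-stamped social-media postings, with
diurnal rhythm curves and permutation-test regression. The package targets
digital-epidemiology analyses of the kind run on postings from MSM (men
who have sex with men) dating/community apps: score each posting against
LIWC-style word lists, aggregate by user and clock hour, describe the
population's diurnal mood rhythm, and test how users' baseline affect
relates to their sexual-behaviour and health word use and demographic
covariates. Because corpora of this kind are not publicly shareable, the
package ships a seeded synthetic-corpus generator with known ground truth,
so every stage is testable end to end.

## The measurement in brief

For user *u*, clock hour *h* (pooled across days) and dimension *d* with
word list *W_d*:

* hourly probability: `P_d(u,h) = ||W_d(u,h)|| / ||W(u,h)||` — matched
  tokens over total tokens; hours with no tokens are missing, not zero;
* composite scores from signed counts: positive sentiment score
  `pos − neg`, positive emotion score `joy − (sadness+anger+fear+disgust)`,
  normalized the same way;
* user baseline `P̄_d(u)`: the user's average across hours (active-hours
  mean by default; the literal divide-by-24 convention is also available)
  — the regression outcome;
* relative probability `R_d(u,h) = P_d(u,h) − P̄_d(u) + grand mean`, and
  the population diurnal curve `R_d(h)` = mean over users active in hour
  *h*;
* association stage: univariate permutation screen at p < 0.20, one
  multivariate linear model with Freedman–Lane permutation p-values
  (p = (b+1)/(B+1), two-sided via |t|), significance at p < 0.05; plus
  Cohen's kappa for inter-rater theme coding and exact reproduction of
  published-table percentages (half-away-from-zero rounding).

## Worked example

Generate a synthetic study in which users' latent sexual-word rate also
raises their positive-affect emission (logit slope 1), then recover both
the diurnal structure and the regression effect:

```r
library(affectrhythm)
library(dplyr)

cfg <- sim_config(
  n_users = 200,
  covariate_effects = list(positive_affect = c(sexual = 1)),
  seed = 7
)
sim <- generate_corpus(cfg)

active <- filter_active_users(sim$postings)          # >= 25 postings
counts <- count_user_hours(filter(sim$postings, user_id %in% active),
                           sim$lexicon)
pa <- hour_probabilities(counts)
baselines <- affect_baselines(pa)
curves <- diurnal_curve(relative_probabilities(pa))

peak_window(filter(curves,
                   dimension %in% c("positive_affect", "negative_affect", "joy")),
            width = 3)
#> # A tibble: 3 × 5
#>   dimension       start_hour end_hour peak_hour mean_value
#>   <fct>                <int>    <int>     <int>      <dbl>
#> 1 positive_affect          7        9         8     0.0360
#> 2 negative_affect          1        3         2     0.0365
#> 3 joy                      7        9         8     0.0309
```

The generator placed the positive-affect and joy peaks at hour 8 and the
negative-affect peak at hour 3; the recovered 3-hour windows (7–9 and
1–3) contain them. `mean_value` is the window's mean relative probability
— about 3.6% of tokens at the morning peak are positive-affect words.

```r
summary_tbl <- build_user_summary(baselines, derive_covariates(sim$profiles))
fit <- screen_then_fit(summary_tbl, "positive_affect",
                       c("sexual", "health", "log_followers"),
                       B = 999, seed = 8)
filter(fit, stage == "multivariate")
#> # A tibble: 1 × 10
#>   stage        outcome         term   coefficient estimate p_value     B  seed
#>   multivariate positive_affect sexual sexual         0.821   0.001   999     8
#>   ... screened_in TRUE, significant TRUE
```

Only the sexual-word exposure survives the univariate screen; its
multivariate coefficient is positive (0.82: users whose sexual-word
baseline is higher by 0.01 average a positive-affect baseline higher by
about 0.008) at the smallest attainable p-value (1/1000) — the generated
coupling, recovered with the correct sign. `autoplot(curves)` draws the
24-point rhythm per dimension; `tidy()`/`glance()` work on `perm_lm()`
fits; `run_pipeline()` executes the whole sequence from a YAML config and
writes tidy CSVs plus a reproducibility manifest.

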