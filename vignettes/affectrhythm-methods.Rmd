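---
title: "Measuring affective states and diurnal mood rhythms from social-media postings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring affective states and diurnal mood rhythms from social-media postings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

`affectrhythm` implements a lexicon-based (word-count) measurement of
affective states in time-stamped postings, the standard instrument family
of LIWC-style text analysis. The measurement rests on one assumption:
the probability that a posted token belongs to a dimension's word list is
a proxy for the intensity of that affective dimension at posting time.
Nine dimensions are scored with the same machinery: two sentiment
dimensions (positive affect, negative affect), five basic emotions (joy,
sadness, anger, fear, disgust), and two behaviour/health dimensions
(sexual, health) used as regression exposures.

For user $u$ and clock hour $h$ (postings are pooled by clock hour across
calendar days), let $\|W(u,h)\|$ be the total tokens posted and
$\|W_d(u,h)\|$ the tokens matching dimension $d$. The pipeline computes:

1. **Hourly probability** $P_d(u,h) = \|W_d(u,h)\| / \|W(u,h)\|$
   (`hour_probabilities()`). An hour with zero tokens is *missing*, not
   zero: inactivity carries no affect information.
2. **Composite scores** from signed count differences before dividing:
   the positive sentiment score uses
   $\|W_{pos}\| - \|W_{neg}\|$ and the positive emotion score
   $\|W_{joy}\| - (\|W_{sad}\| + \|W_{ang}\| + \|W_{fear}\| + \|W_{disg}\|)$,
   giving scores in $[-1, 1]$ that summarize each user-hour in one number.
3. **User baseline** $\bar P_d(u)$ (`affect_baselines()`), the user's
   average affective state and the regression outcome. Two denominator
   conventions exist: dividing the sum of defined hourly probabilities by
   the full 24-hour cycle treats unobserved hours as zero affect and
   shrinks sparse users toward 0; the default `active_hours` averages over
   the hours the user actually posted in, which estimates the emission
   rate itself. Both are exposed so results can be compared.
4. **Relative probability**
   $R_d(u,h) = P_d(u,h) - \bar P_d(u) + \text{grand mean}$
   (`relative_probabilities()`), the user's deviation from his own
   baseline, recentred so all users share a common diurnal scale. The
   grand mean is computed over *defined* user-hours only. Two exact
   identities follow and are tested to $10^{-12}$: the mean of $R$ over
   defined user-hours equals the grand mean, and each user's deviations
   sum to zero under the `active_hours` baseline.
5. **Population diurnal curve** $R_d(h)$ (`diurnal_curve()`): the mean of
   $R_d(u,h)$ over the users active in hour $h$. `peak_window()`
   summarizes a curve by the contiguous circular window of given width
   with the highest mean, ties broken by the earliest start hour.

## Matching rules

Word lists are held in an `affect_lexicon` (TSV, JSON, or LIWC `.dic`
files). Matching choices that the instrument leaves open are fixed as
follows:

* matching is case-insensitive after Unicode NFC normalization;
* a trailing `*` marks a stem that matches any token beginning with it
  (the `.dic` convention);
* dimensions may share entries, and a token matching $k$ dimensions
  increments all $k$ counts — affect dictionaries overlap by design;
* **token mode** (default) matches whole tokens, so a posting's match
  count never exceeds its token count;
* **substring mode** serves unsegmented CJK text: entries are scanned
  left-to-right over the raw text, preferring the longest entry at each
  position, never overlapping. This makes multiword phrase entries match
  as single units. The rule is deterministic and is verified against an
  exhaustive enumerator in the tests.

Tokenization is pluggable because no single segmentation is right for all
corpora: `whitespace` mode (runs of letters/digits, punctuation-only
tokens dropped) suits space-delimited text and the synthetic corpora;
`segmenter` mode accepts any deterministic user-supplied segmentation
function for Chinese text. Negation scope and emoticons are out of scope:
a bag-of-words instrument scores "not good" as one negative-adjacent
token pattern it cannot see; this is a known limitation of the instrument
family, not of this implementation.

## Covariate coding

`derive_covariates()` codes profiles the way the epidemiological analysis
uses them: age dichotomized at 25 years; education as high-school-or-below
/ above / unknown; geolocation as Guangzhou / Shenzhen / Dongguan / other;
hometown as Guangdong / non-Guangdong / unknown; BMI (kg/m²) classified
with the NIH cut-points 18.5 / 25 / 30, intervals closed on the left so a
BMI of exactly 25 is overweight; sex role as receptive / insertive /
versatile / unknown. Missing categorical values become explicit `unknown`
levels so users are tabulated, not dropped. Follower, followee and
chat-group counts are transformed as $\log_{10}(x+1)$: network counts are
heavily right-skewed, base 10 matches the magnitude conventions of the
field (a user with hundreds of followers scores around 2.3), and the $+1$
guards zeros. The base is configurable.

## Permutation inference

Baseline scores are bounded ratios with strongly skewed distributions, so
the regression stage (`perm_lm()`, `screen_then_fit()`) uses permutation
tests rather than normal-theory inference. Both standard schemes are
implemented:

* **response permutation** — permute the outcome, refit, compare $|t|$;
  exact under full exchangeability and the default for univariate screens;
* **Freedman–Lane** — permute the residuals of the reduced model (all
  terms except the tested one), add them to the reduced fit, refit the
  full model, compare the tested term's $|t|$; the standard choice for
  testing one term adjusted for others and the multivariate default.

p-values are two-sided via $|t|$ and computed as $(b+1)/(B+1)$, never
zero; $B$ defaults to 4999 and at least 99 is enforced. The two-stage
analysis mirrors common epidemiological practice: candidates pass a
univariate screen at $p < 0.20$, survivors enter one multivariate model,
and significance is declared at $p < 0.05$; no further multiplicity
adjustment is applied, matching the analysis this package operationalizes.
Inter-rater reliability of qualitative theme coding is summarized by
Cohen's kappa with marginal-product expected agreement
(`cohen_kappa()`), reported as missing (with 100% agreement) in the
degenerate both-raters-constant case. `proportion_summary()` reproduces
published-table percentages with half-away-from-zero rounding (base R
rounds ties to even, which published tables do not).

## The synthetic corpus generator

No public corpus of this kind exists, so `sim_config()` /
`generate_corpus()` provide a generator whose *defaults are the study
conditions* the analysis assumes, with known ground truth for recovery
tests:

* **Baseline emission rates** per dimension anchor to the magnitudes
  published for this population (positive affect 0.014, negative affect
  0.016, joy 0.015, sadness 0.005, anger 0.0005, fear 0.0006, disgust
  0.004, sexual 0.009, health 0.008 — probabilities per token).
* **Posting volume**: negative binomial, mean 80 postings per user
  (the published corpus averages roughly 81 = 477,374/5871 postings per
  active user), dispersion 2 — social-media activity is heavily skewed.
  Tokens per posting: NB mean 20, dispersion 4, floor of 1.
* **Diurnal signal** on the logit scale,
  $\operatorname{logit} p_d(u,h) = \operatorname{logit}(\text{base}_d) +
  b_{ud} + A_d \cos(2\pi (h - \text{peak}_d)/24) + \text{effects}$,
  which keeps probabilities in $(0,1)$ at any amplitude. Default peaks:
  hour 8 for the positive dimensions, hour 3 for the negative and health
  dimensions, hour 23 for the sexual dimension — the morning/late-night
  pattern reported for this population. Default amplitude 0.8 (about a
  5-fold peak-to-trough rate ratio); user random effect SD 0.4.
* **Covariate couplings**: `covariate_effects` adds, e.g., the user's
  latent sexual-rate random effect to the positive-affect logit with a
  chosen slope — the ground truth the regression stage must recover in
  sign and screening.
* **Vocabularies**: disjoint 20-word synthetic lists per dimension plus
  200 filler words, whitespace-delimited, which sidesteps segmentation
  while exercising every counting path; `overlap_frac` shares words
  between consecutive dimensions to exercise multi-dimension matching.
* Posting times are i.i.d. categorical over 24 hours (the measurement
  model needs no within-user temporal dependence); demographics are drawn
  from marginals matching the published sample composition.

What the generator deliberately does **not** emulate: real Chinese text
(no segmentation ambiguity), within-user temporal autocorrelation, bursty
reposting, network structure (follower counts are covariates only), or
topic-correlated vocabulary use. Passing recovery tests therefore show
that the pipeline's arithmetic and inference recover the generating
process they assume — not that the instrument is valid for real postings,
which depends on dictionary quality and segmentation.

## Numerical and design choices

* Zero-token user-hours are missing, never zero, and excluded from
  baselines, grand means and curve denominators; a user with no defined
  hours at all is an error, not a silent `NA`.
* `peak_window()` requires fully defined windows, breaks ties by earliest
  start, and reports the window centre as `peak_hour`.
* Degenerate perfect fits (zero residual variance) yield infinite $|t|$,
  so a perfectly collinear outcome attains the minimum attainable p-value
  $1/(B+1)$ rather than `NaN`.
* Rank-deficient designs abort naming the collinear columns; unused
  factor levels are dropped before the design matrix is built so small
  subsamples do not fabricate zero columns.
* Timezone defaults to Asia/Shanghai (the study region) and is explicit
  because hour-of-day extraction is meaningless without it.
* Every stochastic stage requires a seed; pipeline stages derive child
  seeds deterministically so one run seed fixes the whole run.

## Problem sizes used by the checks

The packaged tests and the acceptance script run, by choice, at
desk-scale versions of the study conditions: corpora of 100–500 users
(the published analysis had 5871), 30–80 postings per user, permutation
counts of 199–999, 100–500 replicate simulations for size and recovery
properties. These sizes give Monte-Carlo error small enough for the
binomial acceptance bands used in the tests.

## Known limitations

* **Co-measured baselines are not independent under null effects.** The
  exposure (sexual/health baseline) and outcome (affect baseline) are
  ratios computed from the *same* postings of each user, so a user's
  posting volume scales the sampling noise of both. When per-user
  information is low (few postings), this shared noise scale makes the
  pair dependent even when the generating rates are independent, and any
  test of independence — permutation or classical — rejects above the
  nominal level. At the default study conditions (mean 80 postings per
  user with the 25-posting activity filter) per-user information is high
  enough that user-level heterogeneity dominates and the tests hold their
  size, which is what the acceptance checks verify; analysts applying the
  pipeline to much sparser corpora should expect anticonservative
  associations between co-measured baselines. Splitting each user's
  postings and measuring exposure and outcome on disjoint halves removes
  error *correlation* but not this shared-scale effect.
* The `active_hours`/`all_hours` baseline choice matters for sparse
  users: the literal cycle-length denominator conflates inactivity with
  neutral affect.
* Substring-mode counts on unsegmented text are not bounded by a token
  total, so the probability scale differs from token mode; use a
  segmenter when a comparable denominator matters.
* Bag-of-words scoring cannot see negation, irony, or emoticons.
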