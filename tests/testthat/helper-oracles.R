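# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive per-element loops, distinct from the vectorized
# implementation paths they check.

# Token-mode counting: plain membership scan, one token at a time.
oracle_token_count <- function(tokens, entries) {
  tokens <- tolower(tokens)
  hits <- 0L
  for (tok in tokens) {
    matched <- FALSE
    for (e in tolower(entries)) {
      if (endsWith(e, "*")) {
        stem <- substr(e, 1, nchar(e) - 1)
        if (nchar(stem) > 0 && startsWith(tok, stem)) matched <- TRUE
      } else if (tok == e) {
        matched <- TRUE
      }
    }
    if (matched) hits <- hits + 1L
  }
  hits
}

# Substring counting: enumerate every (position, entry) match in the text,
# then walk left to right taking the longest match at each reachable
# position, never overlapping.
oracle_substring_count <- function(text, entries) {
  entries <- unique(sub("\\*$", "", tolower(entries)))
  entries <- entries[nchar(entries) > 0]
  text <- tolower(text)
  n <- nchar(text)
  matches <- list()
  for (e in entries) {
    le <- nchar(e)
    if (le > n) next
    for (i in seq_len(n - le + 1)) {
      if (substr(text, i, i + le - 1) == e) {
        matches[[length(matches) + 1]] <- c(start = i, len = le)
      }
    }
  }
  if (length(matches) == 0) return(0L)
  m <- do.call(rbind, matches)
  count <- 0L
  pos <- 1L
  while (pos <= n) {
    here <- m[m[, "start"] == pos, , drop = FALSE]
    if (nrow(here) > 0) {
      count <- count + 1L
      pos <- pos + max(here[, "len"])
    } else {
      pos <- pos + 1L
    }
  }
  count
}

# OLS by explicit normal equations (the implementation under test uses QR
# or a precomputed pseudoinverse).
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X) %*% (t(X) %*% y))
}

tiny_lexicon <- function() {
  lexicon(list(
    positive_affect = c("sweet", "honor", "happ*"),
    negative_affect = c("hurt", "agony", "nasty"),
    joy = c("love", "excited", "high"),
    sadness = c("tear", "alone", "anxious"),
    anger = c("roar", "abuse"),
    fear = c("panic", "hell"),
    disgust = c("wordy", "speechless"),
    sexual = c("kiss", "condom"),
    health = c("infection", "insomnia", "exercise")
  ))
}

make_postings <- function(user_id, hour, text) {
  tibble::tibble(user_id = user_id, hour = as.integer(hour), text = text)
}

# A small deterministic scored corpus for scoring-module tests.
scored_fixture <- function(seed = 101, n_users = 30) {
  cfg <- sim_config(
    n_users = n_users,
    postings_per_user = c(mean = 40, dispersion = 2),
    tokens_per_posting = c(mean = 20, dispersion = 4),
    seed = seed
  )
  sim <- generate_corpus(cfg)
  counts <- count_user_hours(sim$postings, sim$lexicon)
  list(sim = sim, counts = counts, pa = hour_probabilities(counts))
}
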