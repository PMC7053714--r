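#' Construct an affect lexicon
#'
#' A lexicon maps named dimensions (e.g. `positive_affect`, `joy`, `sexual`)
#' to word lists. An entry is either a literal word/phrase or a stem with a
#' single trailing `*`, which matches any token beginning with the stem
#' (the LIWC `.dic` wildcard convention). Dimensions may share entries:
#' dictionaries in this field overlap, and a token matching entries in k
#' dimensions increments all k counts.
#'
#' All entries are case-folded and NFC-normalized at construction so that
#' matching is case- and composition-insensitive.
#'
#' @param dimensions Named list of character vectors, one per dimension.
#'   Dimension names are normalized to lower-case snake-case.
#' @return An object of class `affect_lexicon`: a named list of entry
#'   vectors with precomputed literal/stem splits.
#' @examples
#' lex <- lexicon(list(joy = c("love", "excited"), sadness = c("tear", "happ*")))
#' dimension_names(lex)
#' @export
lexicon <- function(dimensions) {
  if (!is.list(dimensions) || is.null(names(dimensions)) ||
      any(!nzchar(names(dimensions)))) {
    abort("`dimensions` must be a named list of character vectors.")
  }
  nm <- normalize_dimension_name(names(dimensions))
  if (anyDuplicated(nm)) {
    abort(sprintf("Duplicate dimension name(s) after normalization: %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  entries <- lapply(seq_along(dimensions), function(i) {
    e <- as.character(dimensions[[i]])
    if (length(e) == 0) {
      abort(sprintf("Dimension '%s' has no entries.", nm[i]))
    }
    if (any(is.na(e)) || any(!nzchar(e))) {
      abort(sprintf("Dimension '%s' contains empty or NA entries.", nm[i]))
    }
    e <- fold_text(e)
    if (anyDuplicated(e)) {
      warn(sprintf("Dimension '%s': %d duplicate entr%s collapsed.",
                   nm[i], sum(duplicated(e)),
                   if (sum(duplicated(e)) == 1) "y" else "ies"))
      e <- unique(e)
    }
    e
  })
  names(entries) <- nm
  structure(entries, class = "affect_lexicon")
}

#' @export
print.affect_lexicon <- function(x, ...) {
  cat(sprintf("<affect_lexicon: %d dimensions>\n", length(x)))
  for (d in names(x)) {
    ex <- paste(head(x[[d]], 4), collapse = ", ")
    cat(sprintf("  %-24s %5d entries  (%s%s)\n", d, length(x[[d]]), ex,
                if (length(x[[d]]) > 4) ", ..." else ""))
  }
  invisible(x)
}

#' @describeIn lexicon Dimension names of a lexicon.
#' @param x An `affect_lexicon`.
#' @export
dimension_names <- function(x) names(x)

#' @method as_tibble affect_lexicon
#' @export
as_tibble.affect_lexicon <- function(x, ...) {
  tibble::tibble(
    dimension = rep(names(x), lengths(x)),
    entry = unlist(x, use.names = FALSE)
  )
}

normalize_dimension_name <- function(x) {
  x <- fold_text(x)
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N}]+", "_")
  stringr::str_remove_all(x, "^_+|_+$")
}

#' Read a lexicon file
#'
#' Supports three dialects, all UTF-8:
#' * `tsv` — two columns `dimension<TAB>word`, no header;
#' * `json` — a JSON object mapping dimension names to arrays of words;
#' * `liwc_dic` — the LIWC `.dic` layout: a `%`-delimited header block of
#'   `category_id<TAB>category_name` lines followed by
#'   `word<TAB>id[<TAB>id...]` entry lines. Trailing-`*` stems are kept as
#'   prefix-match entries.
#'
#' @param path Path to the lexicon file.
#' @param dialect One of `"tsv"`, `"json"`, `"liwc_dic"`.
#' @return An [lexicon()] object.
#' @export
read_lexicon <- function(path, dialect = c("tsv", "json", "liwc_dic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Lexicon file not found: %s", path))
  }
  dims <- switch(dialect,
    tsv = read_lexicon_tsv(path),
    json = read_lexicon_json(path),
    liwc_dic = read_lexicon_dic(path)
  )
  lexicon(dims)
}

read_lexicon_tsv <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("Lexicon file is empty: %s", path))
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  bad <- which(!nzchar(parts[, 1]) | !nzchar(parts[, 2]))
  if (length(bad) > 0) {
    abort(sprintf("Malformed TSV lexicon at line %d of %s: expected 'dimension<TAB>word'.",
                  bad[1], path))
  }
  split(parts[, 2], factor(parts[, 1], levels = unique(parts[, 1])))
}

read_lexicon_json <- function(path) {
  dims <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(sprintf("Malformed JSON lexicon %s: %s",
                                      path, conditionMessage(e)))
  )
  if (!is.list(dims) && !is.character(dims)) {
    abort(sprintf("JSON lexicon %s must be an object of word arrays.", path))
  }
  lapply(as.list(dims), as.character)
}

read_lexicon_dic <- function(path) {
  lines <- readr::read_lines(path)
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2) {
    abort(sprintf("Malformed .dic lexicon %s: missing %%-delimited header block.",
                  path))
  }
  header <- lines[(pct[1] + 1):(pct[2] - 1)]
  header <- header[nzchar(trimws(header))]
  hp <- stringr::str_split_fixed(trimws(header), "\\s+", 2)
  bad <- which(!nzchar(hp[, 1]) | !nzchar(hp[, 2]) | is.na(suppressWarnings(as.integer(hp[, 1]))))
  if (length(bad) > 0) {
    abort(sprintf("Malformed .dic header at line %d of %s: expected 'id<TAB>name'.",
                  pct[1] + bad[1], path))
  }
  cat_names <- setNames(hp[, 2], hp[, 1])
  body <- lines[(pct[2] + 1):length(lines)]
  body_ln <- (pct[2] + 1):length(lines)
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_ln <- body_ln[keep]
  dims <- list()
  for (i in seq_along(body)) {
    fields <- stringr::str_split_1(trimws(body[i]), "\\s+")
    if (length(fields) < 2) {
      abort(sprintf("Malformed .dic entry at line %d of %s: expected 'word<TAB>id...'.",
                    body_ln[i], path))
    }
    word <- fields[1]
    ids <- fields[-1]
    unknown <- setdiff(ids, names(cat_names))
    if (length(unknown) > 0) {
      abort(sprintf("Unknown category id '%s' at line %d of %s.",
                    unknown[1], body_ln[i], path))
    }
    for (id in ids) {
      cn <- cat_names[[id]]
      dims[[cn]] <- c(dims[[cn]], word)
    }
  }
  empty <- setdiff(unname(cat_names), names(dims))
  if (length(empty) > 0) {
    abort(sprintf("Dimension '%s' is declared in %s but has no entries.",
                  empty[1], path))
  }
  dims
}

#' Tokenize posting text
#'
#' @param text Character vector of posting texts (may be empty strings).
#' @param mode `"whitespace"` splits on runs of whitespace and punctuation,
#'   dropping punctuation-only tokens (a token is a maximal run of letters
#'   and digits, with internal apostrophes kept); `"segmenter"` delegates to
#'   a user-supplied word segmenter, e.g. a dictionary-based Chinese
#'   segmenter, which must be a deterministic `function(text)` returning a
#'   character vector of tokens.
#' @param segmenter Segmentation function, required when
#'   `mode = "segmenter"`.
#' @return A list of character vectors of tokens, one per input text.
#' @examples
#' tokenize(c("love tear love", "a,b!!", ""))
#' @export
tokenize <- function(text, mode = c("whitespace", "segmenter"),
                     segmenter = NULL) {
  mode <- match.arg(mode)
  text <- as.character(text)
  text[is.na(text)] <- ""
  if (mode == "whitespace") {
    toks <- stringi::stri_extract_all_regex(
      text, "[\\p{L}\\p{N}_]+(?:['’][\\p{L}\\p{N}_]+)*"
    )
    lapply(toks, function(t) if (length(t) == 1 && is.na(t[1])) character(0) else t)
  } else {
    if (!is.function(segmenter)) {
      abort("`segmenter` must be a function(text) -> character vector when mode = 'segmenter'.")
    }
    lapply(text, function(x) {
      if (!nzchar(x)) return(character(0))
      as.character(segmenter(x))
    })
  }
}

#' Count lexicon matches in one posting
#'
#' @param x For `match_mode = "token"`, a character vector of tokens; for
#'   `match_mode = "substring"`, the raw posting text (a character vector is
#'   concatenated without separators, suiting unsegmented CJK text).
#' @param lex An [lexicon()].
#' @param dimension Dimension name to count.
#' @param match_mode `"token"`: a token matches an entry when it equals a
#'   literal entry or begins with a stem entry (trailing `*`); each token
#'   contributes at most 1 per dimension. `"substring"`: entries are scanned
#'   left to right over the raw text, preferring the longest entry at each
#'   position, and matches never overlap; stems are treated as literal
#'   substrings since there are no token boundaries.
#' @return A non-negative integer count.
#' @examples
#' lex <- lexicon(list(joy = c("love", "excited")))
#' count_matches(c("love", "tear", "love"), lex, "joy") # 2
#' @export
count_matches <- function(x, lex, dimension,
                          match_mode = c("token", "substring")) {
  match_mode <- match.arg(match_mode)
  if (!inherits(lex, "affect_lexicon")) {
    abort("`lex` must be an affect_lexicon (see `lexicon()`).")
  }
  if (!dimension %in% names(lex)) {
    abort(sprintf("Unknown dimension '%s'. Available: %s.",
                  dimension, paste(names(lex), collapse = ", ")))
  }
  if (match_mode == "token") {
    sum(token_match_flags(fold_text(as.character(x)), lex[[dimension]]))
  } else {
    text <- fold_text(paste(as.character(x), collapse = ""))
    count_substring_matches(text, lex[[dimension]])
  }
}

## Logical flag per token: matches a literal entry or a stem prefix.
token_match_flags <- function(tokens, entries) {
  if (length(tokens) == 0) return(logical(0))
  is_stem <- stringr::str_ends(entries, stringr::fixed("*"))
  literals <- entries[!is_stem]
  stems <- stringr::str_sub(entries[is_stem], 1, -2)
  stems <- stems[nzchar(stems)]
  hit <- tokens %in% literals
  for (s in stems) {
    hit <- hit | startsWith(tokens, s)
  }
  hit
}

## Greedy left-to-right scan, longest entry first, non-overlapping.
count_substring_matches <- function(text, entries) {
  entries <- unique(stringr::str_remove(entries, "\\*$"))
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0 || !nzchar(text)) return(0L)
  entries <- entries[order(-nchar(entries))]
  lens <- nchar(entries)
  n <- nchar(text)
  count <- 0L
  pos <- 1L
  while (pos <= n) {
    matched <- FALSE
    for (j in seq_along(entries)) {
      end <- pos + lens[j] - 1L
      if (end <= n && substr(text, pos, end) == entries[j]) {
        count <- count + 1L
        pos <- end + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) pos <- pos + 1L
  }
  count
}
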