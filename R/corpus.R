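#' Read a posting corpus
#'
#' Reads time-stamped postings from JSONL (one object per line with fields
#' `user_id`, `ts`, `text`) or CSV. Timestamps are parsed as ISO-8601 (a
#' bare offset-free timestamp is taken to already be local time) and
#' converted to the study timezone before the clock hour is extracted, so
#' all diurnal aggregation is in local time. Rows with a missing user id or
#' an unparseable timestamp are skipped with a message; if more than half
#' the rows are malformed the file is rejected.
#'
#' @param path Path to the postings file.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @param timezone Olson timezone name used for hour-of-day extraction.
#'   Defaults to `"Asia/Shanghai"`, the study region.
#' @param column_map Named character vector mapping the canonical fields
#'   `user_id`, `ts`, `text` to the column/field names used in the file.
#' @return A tibble with columns `user_id` (character), `timestamp`
#'   (POSIXct in `timezone`), `hour` (integer 0-23) and `text`.
#' @export
read_postings <- function(path, format = c("auto", "jsonl", "csv"),
                          timezone = "Asia/Shanghai", column_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Postings file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  cmap <- c(user_id = "user_id", ts = "ts", text = "text")
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map

  if (format == "jsonl") {
    raw <- jsonlite::stream_in(file(path), verbose = FALSE)
    raw <- tibble::as_tibble(raw)
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  assert_columns(raw, unname(cmap), path)
  n_raw <- nrow(raw)
  if (n_raw == 0) abort(sprintf("Postings file has no rows: %s", path))

  user_id <- as.character(raw[[cmap[["user_id"]]]])
  ts_chr <- as.character(raw[[cmap[["ts"]]]])
  text <- as.character(raw[[cmap[["text"]]]])
  text[is.na(text)] <- ""

  ts <- suppressWarnings(
    lubridate::parse_date_time(ts_chr, orders = c("ymd HMS z", "ymd HMS", "ymd HM"),
                               tz = timezone, quiet = TRUE)
  )
  bad <- is.na(ts) | is.na(user_id) | !nzchar(user_id)
  if (sum(bad) > n_raw / 2) {
    abort(sprintf("More than half of the rows in %s are malformed (%d of %d).",
                  path, sum(bad), n_raw))
  }
  if (any(bad)) {
    inform(sprintf("Skipped %d malformed posting row(s) in %s.", sum(bad), path))
  }
  ts <- lubridate::with_tz(ts, tzone = timezone)
  tibble::tibble(
    user_id = user_id[!bad],
    timestamp = ts[!bad],
    hour = as.integer(lubridate::hour(ts[!bad])),
    text = text[!bad]
  )
}

#' Read a user-profile table
#'
#' @param path CSV file with one row per user. Recognized columns:
#'   `user_id`, `age`, `education`, `geolocation`, `hometown`, `height`
#'   (metres), `weight` (kg), `sex_role`, `followers`, `followees`,
#'   `chat_groups`. Missing columns are filled with `NA`.
#' @param column_map Optional named character vector renaming file columns
#'   to the canonical names above.
#' @return A tibble with the canonical columns.
#' @export
read_profiles <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(sprintf("Profiles file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      if (column_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == column_map[[canon]]] <- canon
      }
    }
  }
  assert_columns(raw, "user_id", path)
  canon <- c("user_id", "age", "education", "geolocation", "hometown",
             "height", "weight", "sex_role", "followers", "followees",
             "chat_groups")
  for (col in setdiff(canon, names(raw))) raw[[col]] <- NA
  out <- raw[canon]
  out$user_id <- as.character(out$user_id)
  for (col in c("age", "height", "weight", "followers", "followees", "chat_groups")) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  tibble::as_tibble(out)
}

#' Identify active users
#'
#' The study inclusion rule: a user enters the analysis with at least
#' `min_postings` postings (default 25). Postings of excluded users are
#' dropped downstream.
#'
#' @param postings Tibble with a `user_id` column (e.g. [read_postings()]).
#' @param min_postings Minimum posting count for inclusion; must be >= 1.
#' @return Sorted character vector of active user ids.
#' @export
filter_active_users <- function(postings, min_postings = 25) {
  assert_columns(postings, "user_id", "postings")
  if (!is.numeric(min_postings) || min_postings < 1) {
    abort("`min_postings` must be >= 1.")
  }
  counts <- table(postings$user_id)
  keep <- names(counts)[counts >= min_postings]
  if (is.null(keep)) character(0) else sort(keep)
}

education_levels <- c("high_school_or_below", "above_high_school", "unknown")
geolocation_levels <- c("guangzhou", "shenzhen", "dongguan", "other")
hometown_levels <- c("guangdong", "non_guangdong", "unknown")
bmi_levels <- c("normal", "underweight", "overweight", "obese", "unknown")
sex_role_levels <- c("receptive", "insertive", "versatile", "unknown")

#' Derive regression covariates from user profiles
#'
#' Codes the profile fields the way the analysis uses them:
#' * age dichotomized at 25 years (`le25` vs `gt25`);
#' * education as high-school-or-below / above-high-school / unknown;
#' * geolocation as Guangzhou / Shenzhen / Dongguan / other;
#' * hometown as Guangdong / non-Guangdong / unknown;
#' * BMI = weight / height^2 classified with the NIH cut-points, intervals
#'   closed on the left: underweight < 18.5 <= normal < 25 <= overweight
#'   < 30 <= obese (a BMI of exactly 25 is overweight);
#' * sex role as receptive / insertive / versatile / unknown;
#' * follower, followee and chat-group counts log-transformed as
#'   `log(x + 1)` in base `log_base` (default 10) to tame skew.
#'
#' Missing categorical fields become the explicit `unknown` level (missing
#' geolocation falls in `other`) so no user is dropped; factor levels are
#' ordered so that treatment coding uses the analysis reference levels
#' (age `le25`, education `high_school_or_below`, geolocation `guangzhou`,
#' hometown `guangdong`, BMI `normal`, sex role `receptive`).
#'
#' @param profiles Tibble from [read_profiles()].
#' @param log_base Base of the log transform for network counts.
#' @return A tibble with `user_id`, the factor covariates, numeric `bmi`,
#'   and `log_followers`, `log_followees`, `log_chat_groups`.
#' @examples
#' derive_covariates(tibble::tibble(
#'   user_id = "u1", age = 24, education = "above_high_school",
#'   geolocation = "Shenzhen", hometown = "Hunan", height = 1.75,
#'   weight = 70, sex_role = "insertive", followers = 120, followees = 30,
#'   chat_groups = 2
#' ))
#' @export
derive_covariates <- function(profiles, log_base = 10) {
  assert_columns(profiles, "user_id", "profiles")
  p <- profiles
  n <- nrow(p)
  get_num <- function(col) if (col %in% names(p)) suppressWarnings(as.numeric(p[[col]])) else rep(NA_real_, n)
  get_chr <- function(col) if (col %in% names(p)) as.character(p[[col]]) else rep(NA_character_, n)

  age <- get_num("age")
  age_group <- factor(ifelse(is.na(age), NA_character_,
                             ifelse(age <= 25, "le25", "gt25")),
                      levels = c("le25", "gt25"))

  edu_raw <- fold_text(get_chr("education"))
  education <- dplyr::case_when(
    is.na(edu_raw) | !nzchar(edu_raw) ~ "unknown",
    edu_raw %in% c("high_school_or_below", "high school or below",
                   "high_school", "middle_school", "primary_school") ~
      "high_school_or_below",
    edu_raw %in% c("above_high_school", "above high school", "college",
                   "university", "bachelor", "master", "doctorate") ~
      "above_high_school",
    .default = "unknown"
  )
  education <- factor(education, levels = education_levels)

  geo_raw <- fold_text(get_chr("geolocation"))
  geolocation <- dplyr::case_when(
    !is.na(geo_raw) & geo_raw %in% c("guangzhou", "shenzhen", "dongguan") ~ geo_raw,
    .default = "other"
  )
  geolocation <- factor(geolocation, levels = geolocation_levels)

  home_raw <- fold_text(get_chr("hometown"))
  hometown <- dplyr::case_when(
    is.na(home_raw) | !nzchar(home_raw) ~ "unknown",
    stringr::str_detect(home_raw, "guangdong") ~ "guangdong",
    .default = "non_guangdong"
  )
  hometown <- factor(hometown, levels = hometown_levels)

  height <- get_num("height")
  weight <- get_num("weight")
  bad_height <- !is.na(weight) & !is.na(height) & height <= 0
  if (any(bad_height)) {
    inform(sprintf("%d profile(s) have non-positive height; BMI marked missing.",
                   sum(bad_height)))
  }
  bmi <- ifelse(!is.na(height) & height > 0 & !is.na(weight),
                weight / height^2, NA_real_)
  bmi_class <- dplyr::case_when(
    is.na(bmi) ~ "unknown",
    bmi < 18.5 ~ "underweight",
    bmi < 25 ~ "normal",
    bmi < 30 ~ "overweight",
    .default = "obese"
  )
  bmi_class <- factor(bmi_class, levels = bmi_levels)

  role_raw <- fold_text(get_chr("sex_role"))
  sex_role <- dplyr::case_when(
    is.na(role_raw) | !nzchar(role_raw) ~ "unknown",
    role_raw %in% c("insertive", "top", "1") ~ "insertive",
    role_raw %in% c("receptive", "bottom", "0") ~ "receptive",
    role_raw %in% c("versatile", "0.5") ~ "versatile",
    .default = "unknown"
  )
  sex_role <- factor(sex_role, levels = sex_role_levels)

  log_count <- function(x) log(pmax(x, 0) + 1, base = log_base)
  tibble::tibble(
    user_id = as.character(p$user_id),
    age_group = age_group,
    education = education,
    geolocation = geolocation,
    hometown = hometown,
    bmi = bmi,
    bmi_class = bmi_class,
    sex_role = sex_role,
    log_followers = log_count(get_num("followers")),
    log_followees = log_count(get_num("followees")),
    log_chat_groups = log_count(get_num("chat_groups"))
  )
}
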