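#' Read a geolocated message corpus from JSON Lines
#'
#' One JSON object per line with fields `id`, `text`, `lat`, `lon`,
#' `created_at` (ISO-8601), `lang`. Malformed lines (unparseable JSON,
#' missing fields, out-of-bounds coordinates, empty text) are counted and
#' skipped; messages in other languages than `lang` are dropped at read
#' time.
#'
#' @param path Path to a JSONL file.
#' @param lang Language code to keep; `NULL` keeps all languages.
#' @return A tibble with columns `tweet_id`, `text`, `lat`, `lon`,
#'   `created_at`, `lang`, with attributes `n_malformed` and `n_other_lang`.
#' @export
read_corpus <- function(path, lang = "en") {
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse_one <- function(line) {
    rec <- tryCatch(jsonlite::fromJSON(line), error = function(e) NULL)
    if (is.null(rec)) return(NULL)
    need <- c("id", "text", "lat", "lon", "created_at", "lang")
    if (!all(need %in% names(rec))) return(NULL)
    lat <- suppressWarnings(as.numeric(rec$lat))
    lon <- suppressWarnings(as.numeric(rec$lon))
    if (is.na(lat) || is.na(lon) || abs(lat) > 90 || abs(lon) > 180) {
      return(NULL)
    }
    txt <- as.character(rec$text)
    if (!nzchar(txt)) return(NULL)
    list(tweet_id = as.character(rec$id), text = txt, lat = lat, lon = lon,
         created_at = as.character(rec$created_at),
         lang = as.character(rec$lang))
  }
  parsed <- lapply(lines, parse_one)
  ok <- !vapply(parsed, is.null, logical(1))
  n_malformed <- sum(!ok)
  if (length(lines) > 0 && n_malformed > length(lines) / 2) {
    stop("more than half of the lines are malformed (", n_malformed, "/",
         length(lines), "): not a corpus file?", call. = FALSE)
  }
  parsed <- parsed[ok]
  tweets <- tibble::tibble(
    tweet_id   = vapply(parsed, `[[`, character(1), "tweet_id"),
    text       = vapply(parsed, `[[`, character(1), "text"),
    lat        = vapply(parsed, `[[`, numeric(1), "lat"),
    lon        = vapply(parsed, `[[`, numeric(1), "lon"),
    created_at = vapply(parsed, `[[`, character(1), "created_at"),
    lang       = vapply(parsed, `[[`, character(1), "lang")
  )
  n_other_lang <- 0L
  if (!is.null(lang)) {
    keep <- tweets$lang == lang
    n_other_lang <- sum(!keep)
    tweets <- tweets[keep, ]
  }
  if (anyDuplicated(tweets$tweet_id)) {
    stop("duplicate tweet ids in corpus", call. = FALSE)
  }
  attr(tweets, "n_malformed") <- n_malformed
  attr(tweets, "n_other_lang") <- n_other_lang
  tweets
}

#' Write a corpus to JSON Lines
#'
#' Inverse of [read_corpus()]; field names follow the corpus dialect
#' (`id`, `text`, `lat`, `lon`, `created_at`, `lang`).
#'
#' @param tweets Tweet tibble.
#' @param path Output path.
#' @export
write_corpus <- function(tweets, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(tweets))) {
    rec <- list(id = tweets$tweet_id[i], text = tweets$text[i],
                lat = tweets$lat[i], lon = tweets$lon[i],
                created_at = tweets$created_at[i], lang = tweets$lang[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Default noise-removal rule set
#'
#' Two families of case-insensitive regular expressions: job advertisements
#' (hiring/job-opening boilerplate) and predefined location-sharing
#' check-ins ("I'm at <place>" templates). Both are user-overridable, e.g.
#' from the `noise.job_patterns` / `noise.checkin_patterns` keys of a YAML
#' config.
#'
#' @param job_patterns,checkin_patterns Optional replacement pattern
#'   vectors; each family must keep at least one pattern.
#' @return A list of class `noise_rules` with elements `job_patterns` and
#'   `checkin_patterns`.
#' @export
noise_rules <- function(job_patterns = NULL, checkin_patterns = NULL) {
  if (is.null(job_patterns)) {
    job_patterns <- c(
      "#hiring",
      "#job\\b",
      "\\bjob opening\\b",
      "\\b(we'?re|we are) hiring\\b",
      "\\bapply (now|today)\\b.*\\bjob\\b"
    )
  }
  if (is.null(checkin_patterns)) {
    checkin_patterns <- c(
      "^i'?m at\\b",
      "^just arrived at\\b.*\\(@",
      "\\(@ .+\\) https?://"
    )
  }
  if (length(job_patterns) < 1 || length(checkin_patterns) < 1) {
    stop("each noise family needs at least one pattern", call. = FALSE)
  }
  for (p in c(job_patterns, checkin_patterns)) {
    ok <- tryCatch({ suppressWarnings(grepl(p, "", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("pattern does not compile: ", p, call. = FALSE)
  }
  structure(list(job_patterns = job_patterns,
                 checkin_patterns = checkin_patterns),
            class = "noise_rules")
}

#' Classify messages against the noise rules
#'
#' A message matching any job pattern is labelled `"job"`; otherwise a
#' check-in match gives `"checkin"` (job takes precedence when both
#' families match, for stable reporting); otherwise `NA`.
#'
#' @param text Character vector of message texts.
#' @param rules A `noise_rules` object.
#' @return Character vector: `"job"`, `"checkin"`, or `NA_character_`.
#' @export
classify_noise <- function(text, rules = noise_rules()) {
  match_any <- function(patterns) {
    hit <- rep(FALSE, length(text))
    for (p in patterns) {
      hit <- hit | grepl(p, text, ignore.case = TRUE, perl = TRUE)
    }
    hit
  }
  job <- match_any(rules$job_patterns)
  checkin <- match_any(rules$checkin_patterns)
  out <- rep(NA_character_, length(text))
  out[checkin] <- "checkin"
  out[job] <- "job"
  out
}

#' Test a single message for noise
#'
#' @param text A single message text.
#' @param rules A `noise_rules` object.
#' @return A list with `is_noise` (logical) and `family` (`"job"`,
#'   `"checkin"`, or `NA`).
#' @export
is_noise <- function(text, rules = noise_rules()) {
  fam <- classify_noise(text, rules)
  list(is_noise = !is.na(fam), family = fam)
}

#' Remove noise messages from a corpus
#'
#' @param tweets Tweet tibble.
#' @param rules A `noise_rules` object.
#' @return The kept tibble, with attribute `noise` holding the removed rows
#'   plus their `noise_family` label.
#' @export
filter_corpus <- function(tweets, rules = noise_rules()) {
  fam <- classify_noise(tweets$text, rules)
  kept <- tweets[is.na(fam), ]
  noise <- tweets[!is.na(fam), ]
  noise$noise_family <- fam[!is.na(fam)]
  attr(kept, "noise") <- noise
  kept
}
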