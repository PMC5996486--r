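# Word boundaries are transitions between word characters (letters/digits/_)
# and anything else, so "#flu" matches a single-word term inside the hashtag
# body while "influenza" never matches "flu".
surface_regex <- function(surface) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surface)
  body <- gsub(" ", "[[:space:]]+", esc, fixed = TRUE)
  paste0("(?<![[:alnum:]_])", body, "(?![[:alnum:]_])")
}

#' Find strict disease-term mentions in message texts
#'
#' Case-insensitive whole-token-sequence matching of every lexicon surface
#' form: a canonical-name pass first, then a synonym pass over the same
#' text. Candidate matches are resolved longest-first, then leftmost, then
#' canonical before synonym, and each character position contributes to at
#' most one mention. Multi-word terms match only as the complete sequence,
#' never as combinatorial variants of their words.
#'
#' @param tweets Tweet tibble with `tweet_id` and `text` (a single text
#'   string with a `tweet_id` of `"1"` is also accepted).
#' @param lexicon A `disease_lexicon`.
#' @return A tibble with columns `tweet_id`, `canonical`, `surface`,
#'   `start`, `end` (0-based, half-open character span), `via_synonym`.
#' @export
find_mentions <- function(tweets, lexicon) {
  if (is.character(tweets)) {
    tweets <- tibble::tibble(tweet_id = as.character(seq_along(tweets)),
                             text = tweets)
  }
  map <- lexicon$surface_map
  if (length(map) == 0 || nrow(tweets) == 0) {
    return(empty_mentions())
  }
  is_canon <- names(map) == unname(map)
  # canonical pass first, then synonyms; within a pass longer forms first
  ord <- order(!is_canon, -nchar(names(map)))
  surfaces <- names(map)[ord]
  canons <- unname(map)[ord]
  synonym <- !is_canon[ord]
  regexes <- vapply(surfaces, surface_regex, character(1))
  res <- vector("list", nrow(tweets))
  for (i in seq_len(nrow(tweets))) {
    text <- tweets$text[i]
    cand <- list()
    for (j in seq_along(surfaces)) {
      m <- gregexpr(regexes[j], text, ignore.case = TRUE, perl = TRUE)[[1]]
      if (m[1] == -1) next
      len <- attr(m, "match.length")
      cand[[length(cand) + 1]] <- data.frame(
        start = as.integer(m) - 1L,
        end = as.integer(m) - 1L + len,
        canonical = canons[j],
        via_synonym = synonym[j],
        pass = as.integer(synonym[j])
      )
    }
    if (length(cand) == 0) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-(cand$end - cand$start), cand$start, cand$pass), ,
                 drop = FALSE]
    taken <- logical(nchar(text))
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      span <- (cand$start[k] + 1):cand$end[k]
      if (!any(taken[span])) {
        taken[span] <- TRUE
        sel[k] <- TRUE
      }
    }
    cand <- cand[sel, , drop = FALSE]
    cand <- cand[order(cand$start), , drop = FALSE]
    res[[i]] <- tibble::tibble(
      tweet_id = tweets$tweet_id[i],
      canonical = cand$canonical,
      surface = substr(rep(text, nrow(cand)), cand$start + 1, cand$end),
      start = cand$start,
      end = cand$end,
      via_synonym = cand$via_synonym
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) empty_mentions() else out
}

empty_mentions <- function() {
  tibble::tibble(tweet_id = character(0), canonical = character(0),
                 surface = character(0), start = integer(0),
                 end = integer(0), via_synonym = logical(0))
}

#' Write mentions to TSV
#'
#' Columns `tweet_id, canonical, surface, start, end, via_synonym`.
#'
#' @param mentions Mention tibble from [find_mentions()].
#' @param path Output path.
#' @export
write_mentions <- function(mentions, path) {
  utils::write.table(mentions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
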