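#' Dictionary-backed concept identifier
#'
#' A concept identifier is any function mapping one text to a data frame of
#' `(concept, score)` rows with scores in (0, 1000]. This constructor
#' returns a deterministic lexicon-backed identifier: every dictionary
#' mention found in the text yields its canonical term as the concept with
#' the maximum relevance score 1000. It serves as a transparent stand-in
#' for heavyweight biomedical concept identifiers whose relevance scores
#' share the same (0, 1000] scale.
#'
#' @param lexicon A `disease_lexicon`.
#' @param score Relevance assigned to each hit (default 1000).
#' @return An identifier function.
#' @export
lexicon_identifier <- function(lexicon, score = 1000) {
  force(lexicon)
  function(text) {
    m <- find_mentions(text, lexicon)
    if (nrow(m) == 0) {
      return(data.frame(concept = character(0), score = numeric(0)))
    }
    data.frame(concept = unique(m$canonical),
               score = rep(score, length(unique(m$canonical))))
  }
}

#' Run a concept identifier over a corpus
#'
#' Validates the identifier's output against the concept-hit contract:
#' non-empty concept strings, scores in (0, 1000].
#'
#' @param tweets Tweet tibble.
#' @param identifier An identifier function (see [lexicon_identifier()]).
#' @return A tibble of concept hits: `tweet_id`, `concept`, `score`.
#' @export
identify_concepts <- function(tweets, identifier) {
  rows <- vector("list", nrow(tweets))
  for (i in seq_len(nrow(tweets))) {
    hits <- identifier(tweets$text[i])
    if (is.null(hits) || nrow(hits) == 0) next
    if (any(!nzchar(hits$concept))) {
      stop("identifier contract violation: empty concept string",
           call. = FALSE)
    }
    if (any(hits$score <= 0 | hits$score > 1000)) {
      stop("identifier contract violation: score outside (0, 1000]",
           call. = FALSE)
    }
    rows[[i]] <- tibble::tibble(tweet_id = tweets$tweet_id[i],
                                concept = hits$concept, score = hits$score)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    tibble::tibble(tweet_id = character(0), concept = character(0),
                   score = numeric(0))
  } else {
    out
  }
}

#' Read concept hits from a pipe-delimited file
#'
#' One hit per line, `tweet_id|score|concept`, the shape of indexing-style
#' output from external concept identifiers. Scores are validated against
#' the (0, 1000] contract.
#'
#' @param path Path to the pipe-delimited file.
#' @return A tibble `tweet_id`, `concept`, `score`.
#' @export
read_concept_hits <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "|", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 3, logical(1))
  if (any(bad)) {
    stop("malformed concept-hit line(s): expected tweet_id|score|concept",
         call. = FALSE)
  }
  score <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (any(is.na(score)) || any(score <= 0 | score > 1000)) {
    stop("concept-hit score outside (0, 1000]", call. = FALSE)
  }
  tibble::tibble(
    tweet_id = vapply(parts, `[[`, character(1), 1),
    concept = vapply(parts, function(p) paste(p[-(1:2)], collapse = "|"), ""),
    score = score
  )
}

#' Agreement between identifier concepts and dictionary mentions
#'
#' Over a shared tweet universe, `n_with_hits` counts tweets where the
#' identifier found at least one concept; a tweet "matches" when any of its
#' identified concepts, normalized, equals any of its dictionary-matched
#' canonical terms. The agreement ratio is reported rounded to 2 decimals
#' with full precision retained in `agreement_raw`.
#'
#' @param hits Concept-hit tibble (`tweet_id`, `concept`, `score`).
#' @param mentions Mention tibble (`tweet_id`, `canonical`).
#' @return A list of class `agreement_report`: `n_with_hits`, `n_matching`,
#'   `agreement` (2 dp), `agreement_raw`, `mean_score` (mean of per-tweet
#'   best scores), `degenerate` (TRUE when no tweet had hits, in which case
#'   agreement is reported as 0).
#' @export
agreement_score <- function(hits, mentions) {
  with_hits <- unique(hits$tweet_id)
  n_with_hits <- length(with_hits)
  if (n_with_hits == 0) {
    return(structure(list(n_with_hits = 0L, n_matching = 0L, agreement = 0,
                          agreement_raw = 0, mean_score = NA_real_,
                          degenerate = TRUE),
                     class = "agreement_report"))
  }
  mention_terms <- split(normalize_term(mentions$canonical),
                         mentions$tweet_id)
  hit_terms <- split(normalize_term(hits$concept), hits$tweet_id)
  matching <- vapply(with_hits, function(id) {
    length(intersect(hit_terms[[id]], mention_terms[[id]])) > 0
  }, logical(1))
  n_matching <- sum(matching)
  best <- tapply(hits$score, hits$tweet_id, max)
  raw <- n_matching / n_with_hits
  structure(
    list(n_with_hits = as.integer(n_with_hits),
         n_matching = as.integer(n_matching),
         agreement = round(raw, 2),
         agreement_raw = raw,
         mean_score = mean(best),
         degenerate = FALSE),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat("  tweets with hits:", x$n_with_hits, "\n")
  cat("  matching tweets: ", x$n_matching, "\n")
  cat("  agreement:       ", format(x$agreement, nsmall = 2), "\n")
  invisible(x)
}

#' Per-collection mean relevance score
#'
#' Arithmetic mean of the per-tweet maximum score, grouped by collection.
#' By default the mean is over tweets with at least one hit; `over = "all"`
#' divides by every tweet in the collection instead (hit-less tweets
#' contributing 0), since collection averages can be defined either way.
#' Collections with no hits are absent from the output.
#'
#' @param hits Concept-hit tibble.
#' @param memberships Membership tibble from [classify_tweets()].
#' @param over `"hit_bearing"` (default) or `"all"`.
#' @return A tibble `collection`, `mean_score`, `n_tweets`.
#' @export
mean_relevance <- function(hits, memberships, over = c("hit_bearing", "all")) {
  over <- match.arg(over)
  best <- hits |>
    dplyr::group_by(.data$tweet_id) |>
    dplyr::summarise(best = max(.data$score), .groups = "drop")
  # overlap tweets appear in both the airport and the hospital stratum
  labelled <- dplyr::bind_rows(
    dplyr::mutate(memberships[memberships$in_airport, ],
                  collection_label = "airport"),
    dplyr::mutate(memberships[memberships$in_hospital, ],
                  collection_label = "hospital"),
    dplyr::mutate(memberships[!memberships$in_airport &
                                !memberships$in_hospital, ],
                  collection_label = "geolocated")
  )
  joined <- dplyr::left_join(labelled, best, by = "tweet_id")
  if (over == "hit_bearing") {
    joined <- joined[!is.na(joined$best), ]
  } else {
    joined$best[is.na(joined$best)] <- 0
  }
  out <- joined |>
    dplyr::group_by(collection = .data$collection_label) |>
    dplyr::summarise(mean_score = mean(.data$best),
                     n_tweets = dplyr::n(), .groups = "drop")
  out[out$n_tweets > 0, ]
}
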