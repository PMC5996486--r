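#' Collection summary with overlap accounting
#'
#' Counts mention-bearing tweets per collection. Tweets inside both fences
#' are counted in both the airport and the hospital totals, so the unique
#' total is `n_airport + n_hospital - n_overlap + n_geolocated`.
#'
#' @param memberships Membership tibble from [classify_tweets()], restricted
#'   to mention-bearing tweets.
#' @return A list of class `collection_summary`: `n_airport`, `n_hospital`,
#'   `n_overlap`, `n_geolocated`, `n_unique_total`.
#' @export
summarize_collections <- function(memberships) {
  n_a <- sum(memberships$in_airport)
  n_h <- sum(memberships$in_hospital)
  n_o <- sum(memberships$in_airport & memberships$in_hospital)
  n_g <- sum(!memberships$in_airport & !memberships$in_hospital)
  total <- n_a + n_h - n_o + n_g
  stopifnot(total == nrow(memberships), n_o <= min(n_a, n_h))
  structure(
    list(n_airport = as.integer(n_a), n_hospital = as.integer(n_h),
         n_overlap = as.integer(n_o), n_geolocated = as.integer(n_g),
         n_unique_total = as.integer(total)),
    class = "collection_summary"
  )
}

#' @export
print.collection_summary <- function(x, ...) {
  cat("<collection_summary>\n")
  cat(sprintf("  airport: %d  hospital: %d  overlap: %d  geolocated: %d\n",
              x$n_airport, x$n_hospital, x$n_overlap, x$n_geolocated))
  cat("  unique total:", x$n_unique_total, "\n")
  invisible(x)
}

#' Per-collection disease-term frequency distribution
#'
#' The frequency unit is tweets containing the term: a term found several
#' times in one tweet counts once for that tweet, and a tweet with several
#' distinct terms contributes one count to each. Terms whose count is below
#' `threshold` are omitted from the rows and tallied in `n_omitted`
#' ("frequency lower than k omitted" means counts >= k are retained).
#'
#' @param mentions Mention tibble.
#' @param memberships Membership tibble.
#' @param collection `"airport"`, `"hospital"`, `"geolocated"`, or `"all"`.
#'   Overlap tweets belong to both the airport and hospital distributions.
#' @param threshold Minimum tweet count to retain (default 1).
#' @return A list of class `term_distribution`: `collection`, `rows`
#'   (tibble `canonical`, `n_tweets`, descending), `threshold`,
#'   `n_omitted`, `n_terms_total`.
#' @export
term_distribution <- function(mentions, memberships, collection = "all",
                              threshold = 1) {
  if (!collection %in% c("airport", "hospital", "geolocated", "all")) {
    stop("unknown collection label: ", collection, call. = FALSE)
  }
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  ids <- switch(collection,
    airport = memberships$tweet_id[memberships$in_airport],
    hospital = memberships$tweet_id[memberships$in_hospital],
    geolocated = memberships$tweet_id[!memberships$in_airport &
                                        !memberships$in_hospital],
    all = memberships$tweet_id
  )
  sub <- mentions[mentions$tweet_id %in% ids, c("tweet_id", "canonical")]
  sub <- dplyr::distinct(sub)
  counts <- sub |>
    dplyr::count(.data$canonical, name = "n_tweets") |>
    dplyr::arrange(dplyr::desc(.data$n_tweets), .data$canonical)
  kept <- counts[counts$n_tweets >= threshold, ]
  structure(
    list(collection = collection,
         rows = tibble::as_tibble(kept),
         threshold = threshold,
         n_omitted = nrow(counts) - nrow(kept),
         n_terms_total = nrow(counts)),
    class = "term_distribution"
  )
}

#' Terms common to all collections, and rare-term intersections
#'
#' Exact set intersection of canonical terms across the supplied
#' distributions (computed on the full term sets, before the display
#' threshold). Rare sets collect, per collection, the terms whose count is
#' strictly below that collection's cutoff; their intersection identifies
#' terms that are rare everywhere.
#'
#' @param distributions A named list of `term_distribution` objects (counts
#'   are re-read from their unthresholded totals via `rows` plus omitted
#'   terms only when threshold = 1; pass threshold-1 distributions here).
#' @param rare_cutoffs Numeric vector, one cutoff per distribution
#'   (recycled); a term is "rare" when its count < cutoff.
#' @return A list: `common` (character vector of terms present in every
#'   collection), `rare_sets` (named list of per-collection rare term
#'   vectors), `rare_common` (intersection of the rare sets).
#' @export
common_terms <- function(distributions, rare_cutoffs = 10) {
  if (length(distributions) < 2) {
    stop("need at least two distributions", call. = FALSE)
  }
  term_sets <- lapply(distributions, function(d) d$rows$canonical)
  common <- Reduce(intersect, term_sets)
  cutoffs <- rep_len(rare_cutoffs, length(distributions))
  rare_sets <- mapply(function(d, k) {
    d$rows$canonical[d$rows$n_tweets < k]
  }, distributions, cutoffs, SIMPLIFY = FALSE)
  list(common = common, rare_sets = rare_sets,
       rare_common = Reduce(intersect, rare_sets))
}

#' Export mention-bearing tweets as a GeoJSON FeatureCollection
#'
#' One Point feature per mention-bearing tweet, coordinates ordered
#' (longitude, latitude) per the GeoJSON standard, with the collection
#' flags and the tweet's canonical terms as properties.
#'
#' @param tweets Tweet tibble.
#' @param mentions Mention tibble.
#' @param memberships Membership tibble.
#' @param path Output path for the GeoJSON file.
#' @return The path, invisibly.
#' @export
export_geo <- function(tweets, mentions, memberships, path) {
  ids <- unique(mentions$tweet_id)
  tw <- tweets[tweets$tweet_id %in% ids, ]
  mem <- memberships[match(tw$tweet_id, memberships$tweet_id), ]
  terms_by_id <- split(unique(mentions[, c("tweet_id", "canonical")])$canonical,
                       unique(mentions[, c("tweet_id", "canonical")])$tweet_id)
  features <- lapply(seq_len(nrow(tw)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(tw$lon[i], tw$lat[i])),
      properties = list(
        tweet_id = tw$tweet_id[i],
        in_airport = mem$in_airport[i],
        in_hospital = mem$in_hospital[i],
        collection = mem$collection[i],
        terms = as.list(terms_by_id[[tw$tweet_id[i]]])
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Write a term distribution to TSV
#'
#' @param dist A `term_distribution`.
#' @param path Output path.
#' @export
write_distribution <- function(dist, path) {
  utils::write.table(dist$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
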