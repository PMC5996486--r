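#' Default pipeline configuration
#'
#' All tunables in one nested list, overridable from YAML: geofence radii
#' and airport class, noise patterns, language, frequency thresholds per
#' collection, the results-subset cutoff, and rare-term cutoffs.
#'
#' @return A nested list of configuration values.
#' @export
default_config <- function() {
  list(
    lang = "en",
    geofence = list(
      airport_radius_km = 3,
      hospital_radius_km = 0.2,
      airport_class = "large_airport"
    ),
    noise = list(
      job_patterns = NULL,     # NULL = shipped defaults, see noise_rules()
      checkin_patterns = NULL
    ),
    thresholds = list(
      airport = 1,             # omit terms with frequency lower than this
      hospital = 2,
      geolocated = 30,
      focus = 200,             # "frequency above 199" results subset
      rare = c(airport = 10, hospital = 5, geolocated = 10)
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path Path to a YAML file (optional).
#' @return A configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge_lists(cfg, user)
}

#' Run the full surveillance pipeline over a corpus
#'
#' Noise filtering, mention detection, geofencing of mention-bearing
#' tweets, per-collection term distributions, collection summary,
#' POS-pattern tables, and the dictionary-identifier agreement report.
#'
#' @param tweets Tweet tibble (already language-filtered at read time).
#' @param lexicon A `disease_lexicon`.
#' @param airports,hospitals POI tibbles.
#' @param config Configuration list, see [default_config()].
#' @param tagger Tagger for the POS stage (default [default_tagger()]).
#' @return A list: `kept`, `noise`, `mentions`, `memberships` (of
#'   mention-bearing tweets), `summary`, `distributions` (airport /
#'   hospital / geolocated at their display thresholds, plus `full`
#'   versions at threshold 1), `common`, `patterns` (per-collection
#'   frequency tables), `agreement`, `relevance`.
#' @export
run_pipeline <- function(tweets, lexicon, airports, hospitals,
                         config = default_config(),
                         tagger = default_tagger()) {
  rules <- noise_rules(config$noise$job_patterns,
                       config$noise$checkin_patterns)
  kept <- filter_corpus(tweets, rules)
  noise <- attr(kept, "noise")
  mentions <- find_mentions(kept, lexicon)
  bearing <- kept[kept$tweet_id %in% unique(mentions$tweet_id), ]
  memberships <- classify_tweets(
    bearing, airports, hospitals,
    airport_radius_km = config$geofence$airport_radius_km,
    hospital_radius_km = config$geofence$hospital_radius_km
  )
  summary <- summarize_collections(memberships)
  th <- config$thresholds
  dist_at <- function(coll, thr) {
    term_distribution(mentions, memberships, coll, thr)
  }
  distributions <- list(
    airport = dist_at("airport", th$airport),
    hospital = dist_at("hospital", th$hospital),
    geolocated = dist_at("geolocated", th$geolocated),
    full = list(
      airport = dist_at("airport", 1),
      hospital = dist_at("hospital", 1),
      geolocated = dist_at("geolocated", 1)
    )
  )
  common <- common_terms(
    distributions$full,
    rare_cutoffs = unname(th$rare[c("airport", "hospital", "geolocated")])
  )
  pats <- corpus_patterns(bearing, mentions, tagger)
  mem_of <- memberships[match(pats$tweet_id, memberships$tweet_id), ]
  patterns <- list(
    airport = pattern_frequencies(pats[mem_of$in_airport, ]),
    hospital = pattern_frequencies(pats[mem_of$in_hospital, ]),
    geolocated = pattern_frequencies(
      pats[!mem_of$in_airport & !mem_of$in_hospital, ]
    )
  )
  hits <- identify_concepts(bearing, lexicon_identifier(lexicon))
  agreement <- agreement_score(hits, mentions)
  relevance <- mean_relevance(hits, memberships)
  list(kept = kept, noise = noise, mentions = mentions,
       memberships = memberships, summary = summary,
       distributions = distributions, common = common,
       patterns = patterns, agreement = agreement, relevance = relevance)
}

#' Write pipeline outputs under a run directory
#'
#' TSV reports per distribution and pattern table, the GeoJSON export, and
#' a YAML manifest recording configuration, seed and headline counts for
#' provenance.
#'
#' @param result List from [run_pipeline()].
#' @param tweets The corpus the pipeline ran on.
#' @param dir Output directory (created if needed).
#' @param config Configuration used.
#' @param seed Seed recorded in the manifest (optional).
#' @return `dir`, invisibly.
#' @export
write_run <- function(result, tweets, dir, config = default_config(),
                      seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (coll in c("airport", "hospital", "geolocated")) {
    write_distribution(result$distributions[[coll]],
                       file.path(dir, paste0("terms_", coll, ".tsv")))
    write_patterns(result$patterns[[coll]],
                   file.path(dir, paste0("patterns_", coll, ".tsv")))
  }
  write_mentions(result$mentions, file.path(dir, "mentions.tsv"))
  export_geo(tweets, result$mentions, result$memberships,
             file.path(dir, "tweets.geojson"))
  manifest <- list(
    seed = seed,
    config = config,
    counts = list(
      corpus = nrow(tweets),
      noise_removed = nrow(result$noise),
      airport = result$summary$n_airport,
      hospital = result$summary$n_hospital,
      overlap = result$summary$n_overlap,
      geolocated = result$summary$n_geolocated,
      unique_total = result$summary$n_unique_total,
      agreement = result$agreement$agreement
    )
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
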