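#' Built-in disease term catalog for simulation
#'
#' Real disease terms with synonym pairs and relative prevalence weights:
#' a heavy head of frequently discussed conditions plus a long tail of
#' rarely mentioned ones, the frequency shape a news-driven message stream
#' exhibits (a large share of observed terms appearing in a single
#' message).
#'
#' @return A tibble `canonical`, `synonyms` (list), `weight`.
#' @export
sim_term_catalog <- function() {
  head_terms <- tibble::tibble(
    canonical = c("heart failure", "lassa fever", "heart disease",
                  "substance abuse", "mental disorder", "eating disorder",
                  "kidney disease", "brain damage", "kidney stone",
                  "multiple myeloma", "bee sting", "mosquito bite",
                  "viral hepatitis", "plantar fasciitis",
                  "metabolic acidosis"),
    synonyms = list("cardiac failure", character(0), character(0),
                    "drug abuse", character(0), character(0),
                    "renal disease", character(0), "renal calculus",
                    character(0), character(0), character(0),
                    character(0), character(0), character(0)),
    weight = c(20, 16, 14, 12, 10, 8, 6, 5, 4, 2, 1, 1, 1, 1, 1)
  )
  tail_names <- c(
    "tension headache", "nasal polyp", "peptic ulcer",
    "atrial fibrillation", "plantar wart", "frozen shoulder",
    "carpal tunnel syndrome", "shin splints", "hay fever", "dust allergy",
    "food poisoning", "strep throat", "ear infection", "sinus infection",
    "pink eye", "cold sore", "canker sore", "ingrown toenail",
    "varicose veins", "deep vein thrombosis", "iron deficiency",
    "sleep apnea", "night terrors", "panic attack", "social anxiety",
    "seasonal depression", "chronic fatigue", "tennis elbow",
    "whiplash injury", "slipped disc", "pinched nerve", "sciatica",
    "gout", "shingles", "scarlet fever", "whooping cough",
    "glandular fever", "dengue fever", "typhoid fever", "yellow fever",
    "malaria", "cholera", "measles", "mumps", "rubella", "chickenpox",
    "tonsillitis", "appendicitis", "bronchitis", "laryngitis",
    "gastritis", "dermatitis", "conjunctivitis", "acid reflux",
    "heat stroke", "altitude sickness", "motion sickness", "gallstone",
    "heel spur", "stiff neck"
  )
  tail_terms <- tibble::tibble(
    canonical = tail_names,
    synonyms = rep(list(character(0)), length(tail_names)),
    weight = rep(0.1, length(tail_names))
  )
  dplyr::bind_rows(head_terms, tail_terms)
}

#' Build the terminology tibble behind the simulation catalog
#'
#' A flat forest (one root with the catalog terms as children) in the same
#' shape as [read_terminology()] output, so the lexicon used on synthetic
#' corpora is built through the ordinary lexicon path.
#'
#' @param catalog A term catalog, see [sim_term_catalog()].
#' @return A terminology tibble with root node id `"root"`.
#' @export
sim_terminology <- function(catalog = sim_term_catalog()) {
  n <- nrow(catalog)
  ids <- paste0("d", seq_len(n))
  tibble::tibble(
    node_id = c("root", ids),
    name = c("disease", catalog$canonical),
    synonyms = c(list(character(0)), catalog$synonyms),
    children = c(list(ids), rep(list(character(0)), n))
  )
}

#' Simulation configuration
#'
#' Defaults emulate the structure of a geolocated disease-mention stream:
#' news-title duplicates inflating the frequent terms, personal statements
#' carrying the rare ones, job-ad/check-in noise, and a disease-free
#' background; locations fall near airports and hospitals with small
#' probability and uniformly at large otherwise.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_tweets Corpus size (default 5000).
#' @param frac_news Proportion of news-duplicate tweets (default 0.25:
#'   repeated news titles dominate the frequent-term head of such
#'   streams).
#' @param news_dup_factor Mean copies per news title (default 20).
#' @param frac_noise Proportion of job-ad/check-in noise (default 0.10).
#' @param frac_mention Proportion of personal tweets containing a disease
#'   term (default 0.15).
#' @param p_airport,p_hospital Probability that a message is placed inside
#'   the corresponding fence (defaults 0.03 and 0.02).
#' @param airport_scatter_km,hospital_scatter_km Radial scatter around the
#'   sampled POI, kept well inside the 3 km / 0.2 km fences (defaults 1 and
#'   0.05).
#' @param term_catalog Term catalog tibble, see [sim_term_catalog()].
#' @param lang Language code stamped on every message.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_tweets = 5000, frac_news = 0.25,
                       news_dup_factor = 20, frac_noise = 0.10,
                       frac_mention = 0.15, p_airport = 0.03,
                       p_hospital = 0.02, airport_scatter_km = 1,
                       hospital_scatter_km = 0.05,
                       term_catalog = sim_term_catalog(), lang = "en") {
  fr <- c(frac_news, frac_noise, frac_mention)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("class proportions must lie in [0, 1] and jointly sum to <= 1",
         call. = FALSE)
  }
  if (news_dup_factor < 1) stop("news_dup_factor must be >= 1", call. = FALSE)
  if (frac_mention > 0 && nrow(term_catalog) == 0) {
    stop("term_catalog is empty but frac_mention > 0", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_tweets = n_tweets, frac_news = frac_news,
         news_dup_factor = news_dup_factor, frac_noise = frac_noise,
         frac_mention = frac_mention, p_airport = p_airport,
         p_hospital = p_hospital, airport_scatter_km = airport_scatter_km,
         hospital_scatter_km = hospital_scatter_km,
         term_catalog = term_catalog, lang = lang),
    class = "sim_config"
  )
}

#' Generate synthetic POI tables
#'
#' Airports and hospitals placed uniformly at random on land-agnostic
#' mid-latitudes with at least 10 km mutual separation, so the 3 km and
#' 0.2 km fences never overlap across POIs.
#'
#' @param n_airports,n_hospitals Counts (>= 0).
#' @param seed Integer seed.
#' @param min_sep_km Minimum pairwise separation (default 10).
#' @return A list with elements `airports` and `hospitals`, POI tibbles in
#'   the [load_pois()] schema.
#' @export
generate_pois <- function(n_airports, n_hospitals, seed = 1L,
                          min_sep_km = 10) {
  set.seed(as.integer(seed))
  n <- n_airports + n_hospitals
  lat <- numeric(0)
  lon <- numeric(0)
  tries <- 0
  while (length(lat) < n) {
    tries <- tries + 1
    if (tries > 1000 * max(1, n)) {
      stop("cannot place ", n, " POIs with ", min_sep_km,
           " km separation", call. = FALSE)
    }
    cand_lat <- stats::runif(1, -60, 60)
    cand_lon <- stats::runif(1, -180, 180)
    if (length(lat) == 0 ||
        min(haversine_km(cand_lat, cand_lon, lat, lon)) >= min_sep_km) {
      lat <- c(lat, cand_lat)
      lon <- c(lon, cand_lon)
    }
  }
  mk <- function(idx, kind, cls) {
    tibble::tibble(
      poi_id = paste0(substr(kind, 1, 1), seq_along(idx)),
      kind = kind,
      name = paste(kind, seq_along(idx)),
      lat = lat[idx], lon = lon[idx],
      poi_class = cls
    )
  }
  list(
    airports = if (n_airports > 0) {
      mk(seq_len(n_airports), "airport", "large_airport")
    } else {
      mk(integer(0), "airport", character(0))
    },
    hospitals = if (n_hospitals > 0) {
      mk(n_airports + seq_len(n_hospitals), "hospital", "hospital")
    } else {
      mk(integer(0), "hospital", character(0))
    }
  )
}

sim_news_templates <- function() {
  c("%s outbreak reported in %s URL",
    "Health officials confirm rise in %s cases in %s URL",
    "New study links %s to urban stress, %s researchers say URL",
    "%s claims more lives in %s this winter URL",
    "WHO issues guidance on %s after %s cluster URL")
}

sim_personal_templates <- function() {
  c("I have %s again and it hurts",
    "my %s is acting up today",
    "dealing with %s is exhausting",
    "pretty sure this is %s honestly",
    "doctor says it might be %s",
    "my mom was diagnosed with %s yesterday",
    "can't sleep because of this %s",
    "recovering from %s slowly but surely",
    "this %s will not go away",
    "another week another %s flare up")
}

sim_noise_templates <- function() {
  list(
    job = c("We're #hiring! Read about our latest #job opening here: %s",
            "Care assistant #job opening at %s, apply now"),
    checkin = c("I'm at %s", "I'm at %s right now")
  )
}

sim_background_templates <- function() {
  c("what a beautiful sunset tonight",
    "traffic is unbelievable this morning",
    "finally finished that book everyone recommended",
    "coffee first, questions later",
    "game night was a blast with the crew",
    "rainy days call for soup and blankets",
    "new playlist on repeat all day",
    "weekend plans: absolutely nothing and proud")
}

sim_places <- function() {
  c("Lagos", "Chicago", "Mumbai", "Berlin", "Nairobi", "Toronto", "Osaka",
    "Porto Alegre", "Lyon", "Austin")
}

# offset a point by a uniform-in-disc displacement (km) on the sphere
scatter_around <- function(lat, lon, max_km) {
  bearing <- stats::runif(length(lat), 0, 360)
  dist_km <- max_km * sqrt(stats::runif(length(lat)))
  p <- geosphere::destPoint(cbind(lon, lat), bearing, dist_km * 1000,
                            r = EARTH_RADIUS_KM * 1000)
  list(lat = p[, 2], lon = p[, 1])
}

#' Generate a synthetic corpus with full ground truth
#'
#' Message classes: `news` (exact duplicate copies of sampled news titles,
#' each embedding a disease term), `personal` (template sentences, a
#' configurable fraction embedding a term), `noise` (instantiating the two
#' default noise families), `background` (disease-free chatter). Locations
#' are sampled near a POI with the configured probabilities (uniform within
#' the scatter radius) or uniformly at large, so the planted collection is
#' exact under the haversine fence.
#'
#' @param cfg A `sim_config`.
#' @param pois POI list from [generate_pois()].
#' @return A list with `tweets` (corpus tibble in the [read_corpus()]
#'   schema) and `truth` (tibble `tweet_id`, `class`, `term`,
#'   `collection`).
#' @export
generate_corpus <- function(cfg, pois) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_tweets
  classes <- sample(
    c("news", "noise", "personal_mention", "personal_plain", "background"),
    n, replace = TRUE,
    prob = c(cfg$frac_news, cfg$frac_noise, cfg$frac_mention,
             # the personal/background remainder splits evenly
             rep((1 - cfg$frac_news - cfg$frac_noise - cfg$frac_mention) / 2,
                 2))
  )
  cat_terms <- cfg$term_catalog$canonical
  cat_w <- cfg$term_catalog$weight / sum(cfg$term_catalog$weight)

  # news titles: a small pool, each with its own term, duplicated
  # geometrically with mean news_dup_factor
  n_news <- sum(classes == "news")
  titles <- character(0)
  title_terms <- character(0)
  while (length(titles) < n_news) {
    term <- sample(cat_terms, 1, prob = cat_w)
    tmpl <- sample(sim_news_templates(), 1)
    place <- sample(sim_places(), 1)
    title <- sprintf(tmpl, term, place)
    copies <- 1 + stats::rgeom(1, 1 / cfg$news_dup_factor)
    titles <- c(titles, rep(title, copies))
    title_terms <- c(title_terms, rep(term, copies))
  }
  titles <- titles[seq_len(n_news)]
  title_terms <- title_terms[seq_len(n_news)]

  text <- character(n)
  term <- rep(NA_character_, n)
  text[classes == "news"] <- titles
  term[classes == "news"] <- title_terms

  idx_pm <- which(classes == "personal_mention")
  if (length(idx_pm) > 0) {
    t_pm <- sample(cat_terms, length(idx_pm), replace = TRUE, prob = cat_w)
    tmpl <- sample(sim_personal_templates(), length(idx_pm), replace = TRUE)
    text[idx_pm] <- sprintf(tmpl, t_pm)
    term[idx_pm] <- t_pm
  }
  idx_pp <- which(classes == "personal_plain")
  if (length(idx_pp) > 0) {
    text[idx_pp] <- sample(sim_background_templates(), length(idx_pp),
                           replace = TRUE)
  }
  idx_bg <- which(classes == "background")
  if (length(idx_bg) > 0) {
    text[idx_bg] <- sample(sim_background_templates(), length(idx_bg),
                           replace = TRUE)
  }
  idx_noise <- which(classes == "noise")
  if (length(idx_noise) > 0) {
    fam <- sample(c("job", "checkin"), length(idx_noise), replace = TRUE)
    tpl <- sim_noise_templates()
    place <- sample(sim_places(), length(idx_noise), replace = TRUE)
    text[idx_noise] <- ifelse(
      fam == "job",
      sprintf(sample(tpl$job, length(idx_noise), replace = TRUE), place),
      sprintf(sample(tpl$checkin, length(idx_noise), replace = TRUE), place)
    )
  }

  # placement: near an airport / hospital with the configured probabilities,
  # uniform at large otherwise (kept >= 25 km from every POI so background
  # points never stray inside a fence)
  place_class <- sample(c("airport", "hospital", "geolocated"), n,
                        replace = TRUE,
                        prob = c(cfg$p_airport, cfg$p_hospital,
                                 1 - cfg$p_airport - cfg$p_hospital))
  if (nrow(pois$airports) == 0) place_class[place_class == "airport"] <- "geolocated"
  if (nrow(pois$hospitals) == 0) place_class[place_class == "hospital"] <- "geolocated"
  lat <- numeric(n)
  lon <- numeric(n)
  ia <- which(place_class == "airport")
  if (length(ia) > 0) {
    pick <- sample.int(nrow(pois$airports), length(ia), replace = TRUE)
    sc <- scatter_around(pois$airports$lat[pick], pois$airports$lon[pick],
                         cfg$airport_scatter_km)
    lat[ia] <- sc$lat; lon[ia] <- sc$lon
  }
  ih <- which(place_class == "hospital")
  if (length(ih) > 0) {
    pick <- sample.int(nrow(pois$hospitals), length(ih), replace = TRUE)
    sc <- scatter_around(pois$hospitals$lat[pick], pois$hospitals$lon[pick],
                         cfg$hospital_scatter_km)
    lat[ih] <- sc$lat; lon[ih] <- sc$lon
  }
  ig <- which(place_class == "geolocated")
  all_lat <- c(pois$airports$lat, pois$hospitals$lat)
  all_lon <- c(pois$airports$lon, pois$hospitals$lon)
  placed <- 0
  while (placed < length(ig)) {
    m <- length(ig) - placed
    cand_lat <- stats::runif(m, -60, 60)
    cand_lon <- stats::runif(m, -180, 180)
    ok <- rep(TRUE, m)
    if (length(all_lat) > 0) {
      for (j in seq_len(m)) {
        ok[j] <- min(haversine_km(cand_lat[j], cand_lon[j],
                                  all_lat, all_lon)) >= 25
      }
    }
    take <- which(ok)
    if (length(take) > 0) {
      slots <- ig[placed + seq_along(take)]
      lat[slots] <- cand_lat[take]
      lon[slots] <- cand_lon[take]
      placed <- placed + length(take)
    }
  }

  ts <- format(as.POSIXct("2016-10-26 00:00:00", tz = "UTC") +
                 sort(stats::runif(n, 0, 152 * 86400)),
               "%Y-%m-%dT%H:%M:%SZ")
  tweets <- tibble::tibble(
    tweet_id = sprintf("t%06d", seq_len(n)),
    text = text, lat = lat, lon = lon, created_at = ts, lang = cfg$lang
  )
  truth <- tibble::tibble(
    tweet_id = tweets$tweet_id,
    class = dplyr::recode(classes, personal_mention = "personal",
                          personal_plain = "personal"),
    term = term,
    collection = place_class
  )
  list(tweets = tweets, truth = truth)
}

#' Write ground truth to TSV
#'
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Score pipeline outputs against simulation ground truth
#'
#' @param truth Ground-truth tibble.
#' @param mentions Mention tibble from the pipeline.
#' @param memberships Membership tibble from the pipeline (mention-bearing
#'   tweets at minimum; extra rows are ignored).
#' @param noise Noise tibble (rows removed by [filter_corpus()], with
#'   `noise_family`), or `NULL` to skip noise metrics.
#' @return A list: `mention_recall`, `mention_precision` (tweet-level,
#'   against planted terms), `geofence_confusion` (3x3 table planted vs.
#'   assigned collection, overlap tweets resolved by their planted class),
#'   `geofence_accuracy`, `noise_recall`.
#' @export
evaluate_pipeline <- function(truth, mentions, memberships, noise = NULL) {
  if (!all(mentions$tweet_id %in% truth$tweet_id)) {
    stop("mention tweet ids not covered by ground truth", call. = FALSE)
  }
  planted <- truth[!is.na(truth$term), ]
  found <- unique(mentions[, c("tweet_id", "canonical")])
  hit <- mapply(function(id, tm) {
    any(found$tweet_id == id & found$canonical == normalize_term(tm))
  }, planted$tweet_id, planted$term)
  mention_recall <- if (nrow(planted) == 0) NA_real_ else mean(hit)
  correct_found <- mapply(function(id, cn) {
    any(planted$tweet_id == id & normalize_term(planted$term) == cn)
  }, found$tweet_id, found$canonical)
  mention_precision <- if (nrow(found) == 0) NA_real_ else mean(correct_found)

  mem <- memberships[memberships$tweet_id %in% truth$tweet_id, ]
  tr <- truth[match(mem$tweet_id, truth$tweet_id), ]
  assigned <- ifelse(mem$in_airport & mem$in_hospital, tr$collection,
                     ifelse(mem$in_airport, "airport",
                            ifelse(mem$in_hospital, "hospital",
                                   "geolocated")))
  levels3 <- c("airport", "hospital", "geolocated")
  confusion <- table(planted = factor(tr$collection, levels3),
                     assigned = factor(assigned, levels3))
  noise_recall <- NA_real_
  if (!is.null(noise)) {
    planted_noise <- truth$tweet_id[truth$class == "noise"]
    noise_recall <- if (length(planted_noise) == 0) NA_real_ else {
      mean(planted_noise %in% noise$tweet_id)
    }
  }
  list(
    mention_recall = mention_recall,
    mention_precision = mention_precision,
    geofence_confusion = confusion,
    geofence_accuracy = sum(diag(confusion)) / max(1, sum(confusion)),
    noise_recall = noise_recall
  )
}
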