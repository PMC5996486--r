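# Independent oracles used across the suite. Each deliberately takes a
# different route than the implementation it checks.

# spherical law of cosines, R = 6371 km
slc_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  cosang <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  6371 * acos(pmin(1, pmax(-1, cosang)))
}

# breadth-first reachable set over the terminology child relation
bfs_reachable <- function(nodes, root) {
  frontier <- root
  seen <- character(0)
  while (length(frontier) > 0) {
    id <- frontier[1]
    frontier <- frontier[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    frontier <- c(frontier, nodes$children[[match(id, nodes$node_id)]])
  }
  seen
}

# brute-force mention finder: enumerate every token window up to the
# longest lexicon entry and test surface-map membership; returns the set of
# matched (canonical, token-window) pairs ignoring overlap resolution
brute_mention_terms <- function(text, lexicon) {
  toks <- regmatches(text, gregexpr("[[:alnum:]_]+", text))[[1]]
  if (length(toks) == 0) return(character(0))
  max_len <- max(vapply(strsplit(names(lexicon$surface_map), " "),
                        length, integer(1)))
  found <- character(0)
  for (w in 1:max_len) {
    if (w > length(toks)) break
    for (s in 1:(length(toks) - w + 1)) {
      cand <- tolower(paste(toks[s:(s + w - 1)], collapse = " "))
      if (cand %in% names(lexicon$surface_map)) {
        found <- c(found, unname(lexicon$surface_map[cand]))
      }
    }
  }
  sort(unique(found))
}

# brute-force admissible context-shape enumeration
brute_shapes <- function(L, R) {
  out <- list()
  for (l in 0:L) for (r in 0:R) {
    if (abs(l - r) <= 1 && l + r >= 1) out[[length(out) + 1]] <- c(l, r)
  }
  out
}

# small terminology fixture built in code: three-level hierarchy plus a
# sibling branch with synonyms
fixture_terminology <- function() {
  tibble::tibble(
    node_id = c("n1", "n2", "n3", "n4", "n5", "n6"),
    name = c("idiopathic disease",
             "idiopathic thrombocytopenic purpura",
             "acute idiopathic thrombocytopenic purpura",
             "heart failure",
             "kidney stone",
             "muscle atrophy"),
    synonyms = list(character(0),
                    character(0),
                    character(0),
                    c("cardiac failure", "myocardial failure"),
                    "renal calculus",
                    character(0)),
    children = list(c("n2", "n4", "n5", "n6"), "n3", character(0),
                    character(0), character(0), character(0))
  )
}

fixture_lexicon <- function() {
  build_lexicon(collect_terms(fixture_terminology(), "n1"))
}

# deterministic fixture tagger used wherever pattern tests need stable tags
fixture_tagger <- function() {
  make_lookup_tagger(c(
    i = "PRP", have = "VBP", my = "PRP$", the = "DT", a = "DT",
    "in" = "IN", at = "IN", of = "IN", and = "CC", again = "RB",
    hurts = "VBZ", is = "VBZ", outbreak = "NN", reported = "VBD",
    DISEASE = "NN", URL = "NN", "@username" = "NN"
  ), default = "NNP")
}

# small in-code corpus of hand-written tweets
fixture_tweets <- function() {
  tibble::tibble(
    tweet_id = c("w1", "w2", "w3", "w4", "w5"),
    text = c("my kidney stone hurts",
             "cardiac failure again",
             "muscle soreness and atrophy",
             "We're #hiring! Read about our latest #job opening here: St. Louis Trauma Hospital Seeking Multiple Specialties",
             "I'm at Terrabela Zona Sul in Porto Alegre, RS"),
    lat = c(10, 10.1, 10.2, 10.3, 10.4),
    lon = c(20, 20.1, 20.2, 20.3, 20.4),
    created_at = rep("2016-11-01T00:00:00Z", 5),
    lang = "en"
  )
}

# random word soup with occasional planted lexicon terms, for matcher
# equivalence testing
random_fixture_tweet <- function(lexicon, vocab, n_tokens) {
  toks <- sample(vocab, n_tokens, replace = TRUE)
  if (stats::runif(1) < 0.7) {
    surf <- sample(names(lexicon$surface_map), 1)
    pos <- sample(seq_len(n_tokens), 1)
    toks[pos] <- surf
  }
  paste(toks, collapse = " ")
}
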