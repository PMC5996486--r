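---
title: "Disease-mention surveillance in geolocated short messages: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-mention surveillance in geolocated short messages: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tweetsurv)
```

## The problem

Public streams of short geolocated messages are an attractive signal for
syndromic surveillance: people mention illnesses in real time, and the
attached coordinates make it possible to stratify mentions by the kind of
place they come from. Two kinds of places are of particular epidemiological
interest — airports, where travel-associated infections would surface, and
hospitals, where sick people congregate. `tweetsurv` implements the full
analysis chain for this setting: harvest a disease dictionary from a
hierarchical clinical terminology, clean the message stream, detect strict
dictionary mentions, stratify them by proximity to points of interest,
characterise the grammatical context of each mention, and quantify how much
of the apparent signal is actually duplicated news content rather than
personal health statements.

A central, well-documented confounder in this kind of data is
**news-duplication bias**: a large share of messages that mention a disease
are verbatim or near-verbatim copies of news-article titles. Because many
users repeat the same title, frequently mentioned terms are inflated by
news events, while rarely mentioned terms tend to come from genuine
personal statements. The package treats this as a first-class phenomenon:
the synthetic corpus generator plants it deliberately, and the analytics
quantify it.

## The lexicon

The dictionary is harvested from a terminology organised as a class
hierarchy (SNOMED-CT-shaped: each node has a preferred name, optional
synonyms, and subclass links). `collect_terms()` walks the child relation
from a chosen root, visiting each reachable node exactly once and raising
an error on cycles; `build_lexicon()` then applies a length filter: a
surface form is retained only if it has at most `max_content_words`
(default 3) content words, where the six function words *of, from, the, a,
and, to* do not count. Long clinical names ("acute idiopathic
thrombocytopenic purpura", four content words) are unlikely to appear in
informal messages, and their removal keeps the matching dictionary
practical.

Three choices here were genuinely open and are worth recording:

* **Normalization** for lookup is lowercasing plus whitespace collapsing —
  message text is case-chaotic, and nothing stronger (stemming, accent
  folding) is attempted, because the matcher is deliberately strict.
* **The filter is applied per surface form.** A synonym short enough to
  keep is retained even if its canonical name is itself too long; the
  canonical concept name is still used as the normalization target. The
  alternative (dropping the whole node) discards usable layman synonyms
  for no gain.
* **Synonym collisions** (one surface form claimed by two concepts) keep
  the mapping encountered first in traversal order and warn. Polysemy is
  real in clinical synonym sets; resolving it properly is a
  word-sense-disambiguation problem that the identifier-agreement stage
  addresses, not the lexicon.
* Tokens are whitespace-delimited, so hyphenated compounds count as one
  content word.

## Corpus cleaning and geofencing

`read_corpus()` reads JSON Lines records, validates coordinates and
non-empty text, skips (and counts) malformed lines, and drops messages in
other languages than the configured one. Two regular-expression families
then remove structured noise: job advertisements (hiring boilerplate) and
templated location check-ins ("I'm at …"). The shipped default patterns
reproduce the canonical examples of both families and are user-overridable
through the YAML config; a message matching both families counts as a job
ad, so reports are stable.

Geofencing is radial: a message belongs to the **airport collection** when
its great-circle distance to the nearest large airport is at most 3 km
(airports are big), to the **hospital collection** within 0.2 km of a
hospital, and to the background **geolocated collection** otherwise.
Distances use the haversine formula on a sphere of radius 6371 km — at
fence scales of 0.2–3 km the ellipsoidal correction is far below a metre
and irrelevant. Three deliberate choices:

* **Boundary inclusive** (distance ≤ radius): with an inclusive boundary,
  enlarging a radius can only grow a collection, which makes monotonicity
  checks clean.
* **Membership is a pair of flags, not an exclusive label**: a message can
  sit inside both fences simultaneously, and the collection accounting
  reports the overlap explicitly (`total = airport + hospital − overlap +
  geolocated`).
* **Nearest-POI search** is brute force by default — exact and fast at the
  problem sizes involved. An optional grid index (`method = "grid"`) maps
  points to unit-sphere Cartesian coordinates, buckets them into cubic
  cells, and searches expanding Chebyshev rings; because chord length is
  monotone in arc length, it returns identical distances, and the test
  suite asserts exact agreement with brute force.

## Mention detection

`find_mentions()` performs strict dictionary matching: case-insensitive,
whole-token-sequence matches only, with word boundaries at transitions
between word characters and anything else. "muscle atrophy" matches only
as the complete phrase, never as a co-occurrence of "muscle" and
"atrophy". The canonical-name pass runs before the synonym pass;
overlapping candidates are resolved longest-first, then leftmost, and each
character position feeds at most one mention, so a term nested inside a
longer term is suppressed. Hashtag bodies are searchable ("#flu" matches a
single-word term) — hashtags are how such messages often carry the
topical word. A brute-force oracle that enumerates every token window up
to the longest dictionary entry verifies the matcher on randomized
fixtures.

Frequency is counted in tweets, not raw occurrences: a term mentioned
twice in one message counts once, and a message with two distinct terms
contributes to both terms' counts.

## POS context patterns

Before tagging, five substitutions are applied in a fixed order: (1) the
matched disease term becomes the single placeholder `DISEASE`; (2)
`@`-prefixed usernames become `@username`; (3) URLs become `URL`; (4) a
free-standing `@` becomes "at"; (5) remaining punctuation is removed. Each
step applies exactly once and the composition is idempotent. Punctuation
is replaced by a space (never deleted in place), so removal cannot glue
two words into a new token; the `@` of `@username` and the `#` of a
hashtag survive so those remain single tokens. When a message has several
mentions, only the leftmost becomes `DISEASE`, preserving the
single-placeholder invariant.

The tagger is a pluggable contract — any function from a token vector to
an equal-length Penn-Treebank tag vector. The package ships two: a
dictionary-lookup tagger (`make_lookup_tagger()`), used throughout the
test suite so pattern tests never depend on a trained model's versioned
behaviour, and a compact rule-based tagger (`default_tagger()`: closed
class lexicon, suffix heuristics, capitalisation) used by the analysis
drivers. For pattern work only the tag sequence shape matters, so a
deterministic tagger is preferable to a heavyweight statistical one.

Patterns are tag windows around the placeholder. With `L` tags available
on the left and `R` on the right, one pattern is emitted for every shape
`(l, r)` with `0 ≤ l ≤ L`, `0 ≤ r ≤ R`, `|l − r| ≤ 1` and `l + r ≥ 1`,
always using the tags adjacent to the placeholder. The imbalance bound
`|l − r| ≤ 1` encodes the expansion rule that a window grows one side at a
time and stops when a side runs out: a `(2, 1)` context yields exactly
four patterns — `(0,1), (1,0), (1,1), (2,1)` — and asymmetric shapes such
as `'NNP','NNP','DISEASE','NNP'` arise naturally. The expansion rule is
isolated in `generate_patterns()` so an alternative enumeration can be
swapped in; every emitted instance is counted (no per-tweet
deduplication), and frequency tables are thresholded and sorted with a
lexicographic tie-break.

## Identifier agreement

Dictionary matching is precise but blind to word sense; concept
identifiers (MetaMap-style tools scoring concepts up to a maximum
relevance of 1000) are semantically richer but brittle on short informal
text. The package abstracts the identifier as a contract — text in,
`(concept, score)` rows out, scores validated into `(0, 1000]` — with two
implementations: a transparent dictionary-backed stand-in
(`lexicon_identifier()`, score 1000 for every exact dictionary hit) and a
file adapter (`read_concept_hits()`) for pipe-delimited
`tweet_id|score|concept` output produced by an external tool.

`agreement_score()` reports the fraction of concept-bearing messages
whose identified concept coincides with the dictionary-matched term,
rounded to two decimals for reporting with full precision retained. When
no message has hits the ratio is undefined and is reported as 0 with a
`degenerate` flag. Per-message relevance is reduced by **maximum** score
(relevance is a best-interpretation notion); collection averages are
available both over hit-bearing messages (default) and over all messages,
since either convention is defensible and the choice materially changes
the number.

## The synthetic corpus generator

No large geolocated message collection can be redistributed, so the
package generates corpora with the statistical structure the analysis
assumes, plus complete ground truth (per-message class, planted term,
planted collection):

* **News messages** (default 25% of the corpus) are exact duplicate copies
  of sampled news titles, each embedding a disease term; the number of
  copies per title is geometric with mean `news_dup_factor` (default 20).
  News dominance of the frequent-term head is the qualitative phenomenon
  the generator exists to reproduce.
* **Personal messages** embed a term into template sentences ("I have
  &lt;TERM&gt; again …") at rate `frac_mention` (default 15% of the
  corpus); these are iid draws from the term catalog.
* **Noise** (default 10%) instantiates the two default noise families, so
  filter recall is 1 by construction — the filter test exercises the
  plumbing, not pattern cleverness.
* **Background** chatter contains no disease terms.

The term catalog pairs a heavy head of widely discussed conditions with a
long tail of rare ones (weights 20 down to 0.1), emulating the empirical
shape in which a substantial fraction of observed terms appear in exactly
one message. Locations are sampled near a POI with small probability
(scatter 1 km around airports, 0.05 km around hospitals — well inside the
3 km / 0.2 km fences) or uniformly at large but at least 25 km from every
POI, and POIs are mutually separated by at least 10 km; planted
collections are therefore exact under the haversine fence, and the
geofence confusion matrix must be diagonal. Coordinates are displaced by
bearing and distance on the same sphere the fences use.

What the generator does **not** emulate: real linguistic variety
(misspellings, slang, negation, sarcasm), location-dependent language,
temporal bursts, user networks, and near-duplicate (rather than exact)
news copies. Passing tests on synthetic corpora therefore demonstrate
that the pipeline's machinery is correct and internally consistent —
mention recall 1.0 means exact planting is always recovered — not that
recall would be 1.0 on real messages, where strict matching is known to
miss colloquial mentions.

## Numerical and reporting choices

* Threshold semantics: "terms with frequency lower than *k* omitted"
  retains counts ≥ *k*; the results-subset filter "frequency above 199"
  retains counts ≥ 200. Omitted terms are tallied, never silently
  dropped.
* Display thresholds default to 1 (airport), 2 (hospital), 30
  (geolocated); rare-term cutoffs to 10/5/10. All are config keys.
* The distance oracle (spherical law of cosines) is compared at relative
  tolerance 1e-6 only for separations above ~1 m, where it is
  numerically well-conditioned; the haversine formulation is stable
  everywhere.
* Per-term prevalence recovery is checked with 3-sigma binomial bounds on
  the **personal** plantings only: news copies are clustered by title
  (one term draw serves ~20 messages), so per-message binomial bounds do
  not apply to them.
* Problem sizes: the simulation studies use corpora of 5,000 messages
  with 4 airports and 6 hospitals, matcher equivalence uses 500
  randomized fixtures, and the distance-oracle comparison uses 10,000
  random coordinate pairs — sizes at which every statistical bound in the
  suite is already tight.

## A worked run

```{r example, eval = FALSE}
pois <- generate_pois(4, 6, seed = 1)
sim  <- generate_corpus(sim_config(seed = 1, n_tweets = 5000), pois)
lex  <- build_lexicon(collect_terms(sim_terminology(), "root"))
res  <- run_pipeline(sim$tweets, lex, pois$airports, pois$hospitals)
res$summary
evaluate_pipeline(sim$truth, res$mentions, res$memberships, res$noise)
```

The numbered drivers under `analysis/` run exactly this sequence against
files on disk (corpus JSONL, POI CSVs, lexicon TSV) and write every
report — term distributions, pattern tables, GeoJSON export, manifest,
evaluation — under `results/`.

## Known limitations

* Strict matching has no fuzzy or edit-distance mode; spelling variants
  of a term are missed by design.
* The noise filter only knows the two shipped families; real streams
  contain other structured noise (weather bots, now-playing messages).
* The rule-based tagger is deterministic and fast but unsuitable for
  linguistic conclusions about tag identities; swap in a trained tagger
  through the contract for that.
* The news/personal dichotomy in the generator is crisp; real messages
  blend commentary and quotation.
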