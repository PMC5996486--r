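test_that("the five normalization steps apply in order", {
  text <- "@john I have heart failure http://t.co/x"
  m <- find_mentions(text, fixture_lexicon())
  expect_equal(normalize_text(text, m$start, m$end, m$surface),
               "@username I have DISEASE URL")

  # free-standing @ becomes "at"
  expect_equal(normalize_text("meet me @ the clinic"), "meet me at the clinic")

  # only punctuation removal applies
  expect_equal(normalize_text("no mention, no url, no user"),
               "no mention no url no user")

  # hashtag bodies survive as single tokens
  expect_equal(normalize_text("#flu season!"), "#flu season")

  # stale span is an error
  expect_error(normalize_text("something else entirely", 0, 13,
                              "heart failure"), "stale")
})

test_that("normalization is idempotent on its own output", {
  texts <- c("@john I have heart failure http://t.co/x at 5pm!!",
             "meet me @ the clinic #flu",
             "RT @mary: kidney stone... again :( www.example.com/a?b=c",
             "plain words only")
  for (t in texts) {
    once <- normalize_text(t)
    expect_identical(normalize_text(once), once)
  }
})

test_that("tagging honours the tagger contract and finds the placeholder", {
  tg <- tag_text("I have DISEASE", fixture_tagger())
  expect_equal(tg$tags, c("PRP", "VBP", "NN"))
  expect_equal(tg$disease_index, 3)

  tg <- tag_text("", fixture_tagger())
  expect_length(tg$tokens, 0)
  expect_true(is.na(tg$disease_index))

  broken <- function(tokens) character(0)
  expect_error(tag_text("some words", broken), "contract")
})

test_that("two conforming taggers produce the same token stream", {
  texts <- vapply(fixture_tweets()$text, normalize_text, "")
  t1 <- lapply(texts, function(x) tag_text(x, fixture_tagger())$tokens)
  t2 <- lapply(texts, function(x) tag_text(x, default_tagger())$tokens)
  expect_identical(t1, t2)
})

test_that("pattern enumeration matches the worked (2,1) example", {
  # two tags left of the placeholder, one right: exactly four patterns
  tg <- structure(list(tokens = c("a", "b", "DISEASE", "c"),
                       tags = c("IN", "JJ", "NN", "NNP"),
                       disease_index = 3L),
                  class = "tagged_tweet")
  pats <- generate_patterns(tg)
  expect_equal(nrow(pats), 4)
  expect_equal(Map(c, pats$l, pats$r),
               list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(2L, 1L)))
  expect_equal(pats$pattern[1], "'DISEASE','NNP'")
  expect_equal(pats$pattern[4], "'IN','JJ','DISEASE','NNP'")

  # no context, no patterns
  lone <- structure(list(tokens = "DISEASE", tags = "NN", disease_index = 1L),
                    class = "tagged_tweet")
  expect_equal(nrow(generate_patterns(lone)), 0)

  # symmetric (1,1) context: three patterns
  tg11 <- structure(list(tokens = c("a", "DISEASE", "b"),
                         tags = c("DT", "NN", "NNP"), disease_index = 2L),
                    class = "tagged_tweet")
  expect_equal(nrow(generate_patterns(tg11)), 3)
})

test_that("pattern counts match brute-force shape enumeration for L,R <= 6", {
  for (L in 0:6) {
    for (R in 0:6) {
      tags <- c(rep("NNP", L), "NN", rep("IN", R))
      tg <- structure(list(tokens = c(rep("x", L), "DISEASE", rep("y", R)),
                           tags = tags, disease_index = L + 1L),
                      class = "tagged_tweet")
      pats <- generate_patterns(tg)
      shapes <- brute_shapes(L, R)
      expect_equal(nrow(pats), length(shapes))
      got <- Map(c, pats$l, pats$r)
      expect_setequal(lapply(got, as.integer), lapply(shapes, as.integer))
    }
  }
})

test_that("emitted patterns are contiguous tag slices around the placeholder", {
  set.seed(31)
  tagset <- c("NN", "NNP", "IN", "JJ", "VB", "CC", "DT")
  for (i in 1:50) {
    L <- sample(0:4, 1); R <- sample(0:4, 1)
    tags <- c(sample(tagset, L, TRUE), "NN", sample(tagset, R, TRUE))
    tg <- structure(list(tokens = c(rep("x", L), "DISEASE", rep("y", R)),
                         tags = tags, disease_index = L + 1L),
                    class = "tagged_tweet")
    pats <- generate_patterns(tg)
    d <- L + 1
    for (j in seq_len(nrow(pats))) {
      l <- pats$l[j]; r <- pats$r[j]
      want_left <- if (l > 0) tags[(d - l):(d - 1)] else character(0)
      want_right <- if (r > 0) tags[(d + 1):(d + r)] else character(0)
      expect_identical(pats$left[[j]], want_left)
      expect_identical(pats$right[[j]], want_right)
    }
  }
})

test_that("pattern frequencies aggregate, threshold and order correctly", {
  one <- tibble::tibble(left = rep(list(character(0)), 14),
                        right = rep(list("NNP"), 14),
                        l = 0L, r = 1L,
                        pattern = rep("'DISEASE','NNP'", 14))
  freq <- pattern_frequencies(one, min_count = 5)
  expect_equal(nrow(freq), 1)
  expect_equal(freq$count, 14)
  expect_equal(freq$shape_l, 0L)

  expect_equal(nrow(pattern_frequencies(one[0, ], min_count = 1)), 0)

  three <- dplyr::bind_rows(
    tibble::tibble(left = list("IN"), right = list(character(0)),
                   l = 1L, r = 0L, pattern = "'IN','DISEASE'"),
    tibble::tibble(left = list("JJ"), right = list(character(0)),
                   l = 1L, r = 0L, pattern = "'JJ','DISEASE'")
  )
  three <- dplyr::bind_rows(three, three)
  expect_equal(nrow(pattern_frequencies(three, min_count = 5)), 0)
  # tie on count breaks lexicographically
  freq <- pattern_frequencies(three, min_count = 1)
  expect_equal(freq$pattern, c("'IN','DISEASE'", "'JJ','DISEASE'"))
})

test_that("corpus_patterns normalizes only the first mention per tweet", {
  lex <- fixture_lexicon()
  tweets <- tibble::tibble(
    tweet_id = "m1",
    text = "kidney stone and cardiac failure today",
    lat = 0, lon = 0, created_at = "2016-11-01T00:00:00Z", lang = "en"
  )
  mentions <- find_mentions(tweets, lex)
  expect_equal(nrow(mentions), 2)
  pats <- corpus_patterns(tweets, mentions, fixture_tagger())
  # single placeholder: normalized text keeps the second term verbatim
  norm <- normalize_text(tweets$text, mentions$start[1], mentions$end[1],
                         mentions$surface[1])
  expect_equal(norm, "DISEASE and cardiac failure today")
  expect_true(all(pats$tweet_id == "m1"))
  expect_true(nrow(pats) > 0)
})
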