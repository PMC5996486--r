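test_that("collect_terms traverses the hierarchy exactly once per node", {
  nodes <- fixture_terminology()
  # three-level chain: root -> purpura -> acute purpura
  chain <- tibble::tibble(
    node_id = c("n1", "n2", "n3"),
    name = nodes$name[1:3],
    synonyms = rep(list(character(0)), 3),
    children = list("n2", "n3", character(0))
  )
  got <- collect_terms(chain, "n1")
  expect_equal(nrow(got), 3)
  expect_setequal(got$name, c("idiopathic disease",
                              "idiopathic thrombocytopenic purpura",
                              "acute idiopathic thrombocytopenic purpura"))

  # leaf: exactly its own name
  leaf <- collect_terms(nodes, "n3")
  expect_equal(leaf$name, "acute idiopathic thrombocytopenic purpura")
  expect_length(leaf$synonyms[[1]], 0)

  # node with 2 synonyms and 2 leaf children each with 1 synonym
  small <- tibble::tibble(
    node_id = c("p", "c1", "c2"),
    name = c("parent disease", "child one", "child two"),
    synonyms = list(c("syn a", "syn b"), "syn c", "syn d"),
    children = list(c("c1", "c2"), character(0), character(0))
  )
  got <- collect_terms(small, "p")
  expect_equal(nrow(got), 3)
  expect_equal(sum(lengths(got$synonyms)), 4)
})

test_that("traversal matches a breadth-first reachability oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    ids <- paste0("x", seq_len(n))
    children <- lapply(seq_len(n), function(i) {
      # edges only to higher ids keeps the forest acyclic
      if (i == n) return(character(0))
      pool <- ids[(i + 1):n]
      sample(pool, sample(0:min(3, length(pool)), 1))
    })
    nodes <- tibble::tibble(node_id = ids, name = ids,
                            synonyms = rep(list(character(0)), n),
                            children = children)
    root <- ids[1]
    expect_equal(nrow(collect_terms(nodes, root)),
                 length(bfs_reachable(nodes, root)))
  }
})

test_that("collect_terms signals unknown roots and cycles", {
  nodes <- fixture_terminology()
  expect_error(collect_terms(nodes, "nope"), "unknown root")
  cyc <- tibble::tibble(node_id = c("a", "b"), name = c("a", "b"),
                        synonyms = rep(list(character(0)), 2),
                        children = list("b", "a"))
  expect_error(collect_terms(cyc, "a"), "cycle")
})

test_that("content words are counted without the six function words", {
  expect_equal(content_word_count("acute idiopathic thrombocytopenic purpura"), 4)
  expect_equal(content_word_count("disease of the heart"), 2)
  expect_equal(content_word_count("muscle atrophy"), 2)
  expect_equal(content_word_count("pain from a fall to the ground"), 3)
  expect_error(content_word_count(""), "non-empty")
})

test_that("build_lexicon drops long surface forms and maps synonyms", {
  # a 4-content-word name with no synonyms disappears entirely
  lex <- build_lexicon(tibble::tibble(
    name = "acute idiopathic thrombocytopenic purpura",
    synonyms = list(character(0))
  ))
  expect_length(lex$surface_map, 0)

  lex <- build_lexicon(tibble::tibble(
    name = "heart failure", synonyms = list("cardiac failure")
  ))
  expect_length(lex$surface_map, 2)
  expect_true(all(lex$surface_map == "heart failure"))
  expect_false(lex$surface_map[["cardiac failure"]] != "heart failure")

  # 5 names (one too long) + 3 synonyms (one too long):
  # 4 canonical terms, 6 surface forms survive
  terms <- tibble::tibble(
    name = c("heart failure", "kidney stone", "muscle atrophy",
             "brain damage", "chronic obstructive airway flow limitation"),
    synonyms = list("cardiac failure", "renal calculus",
                    "progressive wasting weakness syndrome of muscle",
                    character(0), character(0))
  )
  lex <- build_lexicon(terms)
  expect_length(lex$canonical_terms, 4)
  expect_length(lex$surface_map, 6)
})

test_that("every retained surface form satisfies the content-word bound", {
  lex <- fixture_lexicon()
  counts <- content_word_count(names(lex$surface_map), lex$stopwords)
  expect_true(all(counts <= lex$max_content_words))
})

test_that("build_lexicon is idempotent on its own output", {
  lex <- fixture_lexicon()
  terms2 <- tibble::tibble(
    name = unique(unname(lex$surface_map)),
    synonyms = lapply(unique(unname(lex$surface_map)), function(cn) {
      setdiff(names(lex$surface_map)[lex$surface_map == cn], cn)
    })
  )
  lex2 <- build_lexicon(terms2, lex$stopwords, lex$max_content_words)
  expect_identical(lex2$surface_map[sort(names(lex2$surface_map))],
                   lex$surface_map[sort(names(lex$surface_map))])
})

test_that("synonym collisions keep the first mapping with a warning", {
  terms <- tibble::tibble(
    name = c("heart failure", "cardiac insufficiency"),
    synonyms = list("cardiac failure", "cardiac failure")
  )
  expect_warning(lex <- build_lexicon(terms), "already maps")
  expect_equal(unname(lex$surface_map[["cardiac failure"]]), "heart failure")
})

test_that("normalization lowercases and collapses whitespace", {
  expect_equal(normalize_term("  Heart   FAILURE "), "heart failure")
})

test_that("terminology and lexicon round-trip through their file formats", {
  nodes <- fixture_terminology()
  csv <- tempfile(fileext = ".csv")
  df <- data.frame(
    node_id = nodes$node_id,
    name = nodes$name,
    synonyms = vapply(nodes$synonyms, paste, "", collapse = "|"),
    children = vapply(nodes$children, paste, "", collapse = ",")
  )
  write.csv(df, csv, row.names = FALSE, fileEncoding = "UTF-8")
  back <- read_terminology(csv)
  expect_equal(back$name, nodes$name)
  expect_equal(back$synonyms, nodes$synonyms)
  expect_equal(back$children, nodes$children)

  lex <- fixture_lexicon()
  tsv <- tempfile(fileext = ".tsv")
  write_lexicon(lex, tsv)
  lex2 <- read_lexicon(tsv)
  expect_identical(sort(names(lex2$surface_map)), sort(names(lex$surface_map)))
  expect_identical(lex2$surface_map[names(lex$surface_map)],
                   lex$surface_map)
})
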