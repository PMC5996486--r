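#' Default function-word list for content-word counting
#'
#' Determiners, conjunctions and prepositions that do not count towards the
#' length of a disease term: "of", "from", "the", "a", "and", "to".
#'
#' @return Character vector of six lowercase stopwords.
#' @export
disease_stopwords <- function() {
  c("of", "from", "the", "a", "and", "to")
}

#' Normalize a surface form for lexicon lookup
#'
#' Lowercases and collapses internal whitespace so that matching is robust to
#' the case-chaotic, spacing-chaotic style of short social-media messages.
#'
#' @param x Character vector of surface forms.
#' @return Character vector, same length.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Read a hierarchical terminology from CSV
#'
#' One record per node with columns `node_id,name,synonyms,children`;
#' synonyms pipe-delimited, child ids comma-delimited. Empty cells mean no
#' synonyms / no children.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A tibble with columns `node_id`, `name`, `synonyms` (list of
#'   character vectors), `children` (list of character vectors).
#' @export
read_terminology <- function(path) {
  if (!file.exists(path)) {
    stop("terminology file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  required <- c("node_id", "name", "synonyms", "children")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("terminology file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  split_field <- function(x, sep) {
    lapply(x, function(cell) {
      if (is.na(cell) || !nzchar(trimws(cell))) character(0)
      else trimws(strsplit(cell, sep, fixed = TRUE)[[1]])
    })
  }
  nodes <- tibble::tibble(
    node_id  = trimws(df$node_id),
    name     = trimws(df$name),
    synonyms = split_field(df$synonyms, "|"),
    children = split_field(df$children, ",")
  )
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id in terminology", call. = FALSE)
  }
  all_children <- unique(unlist(nodes$children))
  unknown <- setdiff(all_children, nodes$node_id)
  if (length(unknown) > 0) {
    stop("children reference unknown nodes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nodes
}

#' Collect names and synonyms from a terminology subtree
#'
#' Depth-first traversal from `root` through child links; every reachable
#' node contributes its name and synonym list exactly once. A cycle in the
#' child relation is a malformed terminology and raises an error.
#'
#' @param nodes Terminology tibble as returned by [read_terminology()].
#' @param root Node id to start from.
#' @return A tibble with columns `name` (character) and `synonyms`
#'   (list of character vectors), one row per reachable node.
#' @export
collect_terms <- function(nodes, root) {
  idx <- match(root, nodes$node_id)
  if (is.na(idx)) {
    stop("unknown root node id: ", root, call. = FALSE)
  }
  visited <- character(0)
  on_path <- character(0)
  order <- character(0)
  # explicit stack DFS with a path set for cycle detection
  walk <- function(id, path) {
    if (id %in% path) {
      stop("cycle detected in terminology at node: ", id, call. = FALSE)
    }
    if (id %in% visited) return(invisible(NULL))
    visited <<- c(visited, id)
    order <<- c(order, id)
    pos <- match(id, nodes$node_id)
    if (is.na(pos)) {
      stop("children reference unknown node: ", id, call. = FALSE)
    }
    kids <- nodes$children[[pos]]
    for (k in kids) walk(k, c(path, id))
    invisible(NULL)
  }
  walk(root, character(0))
  sel <- match(order, nodes$node_id)
  tibble::tibble(name = nodes$name[sel], synonyms = nodes$synonyms[sel])
}

#' Count content words in a term
#'
#' Whitespace-delimited tokens not in the stopword list (case-insensitive).
#' Hyphenated compounds count as one token.
#'
#' @param term Non-empty character scalar or vector.
#' @param stopwords Character vector of function words; defaults to
#'   [disease_stopwords()].
#' @return Integer vector of content-word counts.
#' @export
content_word_count <- function(term, stopwords = disease_stopwords()) {
  if (length(term) == 0 || any(is.na(term)) || any(!nzchar(trimws(term)))) {
    stop("term must be non-empty", call. = FALSE)
  }
  stopwords <- tolower(stopwords)
  vapply(term, function(t) {
    toks <- strsplit(trimws(t), "[[:space:]]+")[[1]]
    sum(!(tolower(toks) %in% stopwords))
  }, integer(1), USE.NAMES = FALSE)
}

#' Build a disease lexicon from collected terms
#'
#' Applies the content-word length filter to every surface form (canonical
#' name or synonym) independently: forms with more than `max_content_words`
#' content words are dropped. Surviving forms are normalized with
#' [normalize_term()] and mapped to their canonical name. A synonym already
#' claimed by a different canonical term keeps its first mapping (traversal
#' order) and emits a warning. A name whose every surface form is dropped is
#' absent from the lexicon entirely.
#'
#' @param terms Tibble with columns `name` and `synonyms` as produced by
#'   [collect_terms()].
#' @param stopwords Function words excluded from the count.
#' @param max_content_words Maximum content words per surface form
#'   (default 3).
#' @return An object of class `disease_lexicon`: a list with
#'   `canonical_terms` (character), `surface_map` (named character vector,
#'   surface form -> canonical term), `stopwords`, `max_content_words`.
#' @export
build_lexicon <- function(terms, stopwords = disease_stopwords(),
                          max_content_words = 3) {
  surface <- character(0)
  canonical <- character(0)
  keep <- function(x) content_word_count(x, stopwords) <= max_content_words
  for (i in seq_len(nrow(terms))) {
    nm <- normalize_term(terms$name[i])
    forms <- character(0)
    if (nzchar(nm) && keep(nm)) forms <- nm
    syns <- terms$synonyms[[i]]
    if (length(syns) > 0) {
      syns <- normalize_term(syns)
      syns <- syns[nzchar(syns)]
      if (length(syns) > 0) syns <- syns[keep(syns)]
      forms <- c(forms, syns)
    }
    if (length(forms) == 0) next
    for (f in unique(forms)) {
      j <- match(f, surface)
      if (is.na(j)) {
        surface <- c(surface, f)
        canonical <- c(canonical, nm)
      } else if (canonical[j] != nm) {
        warning("surface form '", f, "' already maps to '", canonical[j],
                "'; keeping first mapping", call. = FALSE)
      }
    }
  }
  # canonical terms are those names that survived as their own surface form
  canon <- unique(canonical[surface == canonical])
  # drop synonym entries whose canonical name itself was filtered out but
  # keep the synonym pointing at the (still valid) canonical concept name
  map <- stats::setNames(canonical, surface)
  structure(
    list(canonical_terms = unique(canonical),
         surface_map = map,
         stopwords = tolower(stopwords),
         max_content_words = max_content_words,
         canonical_surface = canon),
    class = "disease_lexicon"
  )
}

#' @export
print.disease_lexicon <- function(x, ...) {
  cat("<disease_lexicon>\n")
  cat("  canonical terms:", length(x$canonical_terms), "\n")
  cat("  surface forms:  ", length(x$surface_map), "\n")
  cat("  content-word bound:", x$max_content_words, "\n")
  invisible(x)
}

#' Serialize a lexicon to TSV
#'
#' Two columns, `surface_form` and `canonical_term`, tab-separated.
#'
#' @param lexicon A `disease_lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- data.frame(surface_form = names(lexicon$surface_map),
                   canonical_term = unname(lexicon$surface_map))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a lexicon from its TSV serialization
#'
#' @param path TSV with columns `surface_form`, `canonical_term`.
#' @param stopwords,max_content_words Stored alongside the map; the filter is
#'   assumed to have been applied at build time.
#' @return A `disease_lexicon`.
#' @export
read_lexicon <- function(path, stopwords = disease_stopwords(),
                         max_content_words = 3) {
  df <- utils::read.delim(path, colClasses = "character",
                          fileEncoding = "UTF-8")
  map <- stats::setNames(df$canonical_term, df$surface_form)
  structure(
    list(canonical_terms = unique(unname(map)),
         surface_map = map,
         stopwords = tolower(stopwords),
         max_content_words = max_content_words,
         canonical_surface = unique(unname(map)[names(map) == unname(map)])),
    class = "disease_lexicon"
  )
}
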