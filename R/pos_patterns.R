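#' Normalize a message text for part-of-speech tagging
#'
#' Five substitutions, applied in this order, each exactly once:
#' \enumerate{
#'   \item the matched disease term (if any) becomes the single placeholder
#'     `DISEASE`;
#'   \item usernames (`@`-prefixed words) become `@username`;
#'   \item URLs become `URL`;
#'   \item a free-standing `@` (no word character on either side) becomes
#'     `at`;
#'   \item remaining punctuation is removed. The `@` of `@username` and the
#'     `#` introducing a hashtag survive so those stay single tokens.
#' }
#' Punctuation is replaced by a space and whitespace collapsed, so removal
#' never glues two words together.
#'
#' @param text Message text.
#' @param start,end Optional 0-based half-open character span of the mention
#'   to normalize into `DISEASE`; when several mentions exist, callers pass
#'   the leftmost one so the output has a single placeholder.
#' @param surface Optional expected surface at the span; a mismatch (stale
#'   span) raises an error.
#' @return The normalized text.
#' @export
normalize_text <- function(text, start = NULL, end = NULL, surface = NULL) {
  stopifnot(length(text) == 1)
  if (!is.null(start) && !is.null(end)) {
    got <- substr(text, start + 1, end)
    if (!is.null(surface) && tolower(got) != tolower(surface)) {
      stop("mention span does not match text (stale span): expected '",
           surface, "', found '", got, "'", call. = FALSE)
    }
    text <- paste0(substr(text, 1, start), "DISEASE",
                   substring(text, end + 1))
  }
  # (2) usernames; @username itself maps to itself, keeping the step
  # idempotent
  text <- gsub("@(\\w+)", "@username", text, perl = TRUE)
  # (3) URLs
  text <- gsub("(https?://[^[:space:]]+|www\\.[^[:space:]]+)", "URL", text,
               perl = TRUE)
  # (4) free-standing @ -> "at"
  text <- gsub("(?<!\\w)@(?!\\w)", "at", text, perl = TRUE)
  # (5) drop remaining punctuation; keep @ before a word (only @username
  # remains by now) and # introducing a hashtag body
  text <- gsub("(?!@(?=\\w))(?!#(?=\\w))[^\\w\\s]", " ", text, perl = TRUE)
  gsub("[[:space:]]+", " ", trimws(text))
}

#' Whitespace tokenizer for normalized text
#'
#' @param text A normalized text string.
#' @return Character vector of tokens (length 0 for empty input).
#' @export
tokenize <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(character(0))
  strsplit(text, "[[:space:]]+")[[1]]
}

#' Build a dictionary-lookup tagger
#'
#' A tagger is any function mapping a token character vector to an
#' equal-length vector of Penn-Treebank-style tags. This constructor returns
#' a deterministic lookup tagger: tokens found in `dictionary`
#' (case-insensitively, except the literal placeholders) get their entry,
#' everything else gets `default`.
#'
#' @param dictionary Named character vector, token -> tag.
#' @param default Tag for unknown tokens (default `"NN"`).
#' @return A tagger function.
#' @export
make_lookup_tagger <- function(dictionary = character(0), default = "NN") {
  names(dictionary) <- tolower(names(dictionary))
  function(tokens) {
    if (length(tokens) == 0) return(character(0))
    tags <- unname(dictionary[tolower(tokens)])
    tags[is.na(tags)] <- default
    tags
  }
}

#' Small rule-based Penn Treebank tagger
#'
#' A compact deterministic tagger for normalized short-message text: a
#' closed-class lexicon (pronouns, determiners, prepositions, conjunctions,
#' auxiliaries), suffix heuristics for open-class words, `CD` for numerals,
#' and `NNP` for capitalized unknowns (`NN` otherwise). The placeholders
#' `DISEASE`, `@username` and `URL` are tagged `NN`. Not a trained model;
#' adequate for structural pattern work where only the tag sequence shape
#' matters, and swappable for any conforming tagger.
#'
#' @return A tagger function suitable for [tag_text()].
#' @export
default_tagger <- function() {
  closed <- c(
    i = "PRP", you = "PRP", he = "PRP", she = "PRP", it = "PRP", we = "PRP",
    they = "PRP", me = "PRP", him = "PRP", her = "PRP", us = "PRP",
    them = "PRP", my = "PRP$", your = "PRP$", his = "PRP$", its = "PRP$",
    our = "PRP$", their = "PRP$",
    the = "DT", a = "DT", an = "DT", this = "DT", that = "DT",
    these = "DT", those = "DT", no = "DT",
    "in" = "IN", on = "IN", at = "IN", of = "IN", "for" = "IN", with = "IN",
    by = "IN", from = "IN", about = "IN", into = "IN", near = "IN",
    after = "IN", before = "IN", over = "IN", under = "IN", out = "IN",
    "if" = "IN", because = "IN",
    and = "CC", or = "CC", but = "CC", nor = "CC",
    to = "TO",
    is = "VBZ", am = "VBP", are = "VBP", was = "VBD", were = "VBD",
    be = "VB", been = "VBN", being = "VBG",
    have = "VBP", has = "VBZ", had = "VBD",
    do = "VBP", does = "VBZ", did = "VBD",
    will = "MD", would = "MD", can = "MD", could = "MD", may = "MD",
    might = "MD", should = "MD", must = "MD",
    not = "RB", very = "RB", again = "RB", here = "RB", there = "EX",
    so = "RB", just = "RB", now = "RB", still = "RB", never = "RB",
    reported = "VBD", says = "VBZ", said = "VBD", confirmed = "VBD"
  )
  function(tokens) {
    if (length(tokens) == 0) return(character(0))
    vapply(tokens, function(tok) {
      if (tok %in% c("DISEASE", "URL", "@username")) return("NN")
      low <- tolower(tok)
      if (low %in% names(closed)) return(unname(closed[low]))
      if (grepl("^[0-9]+([.,][0-9]+)?$", tok)) return("CD")
      if (grepl("ing$", low)) return("VBG")
      if (grepl("ed$", low)) return("VBD")
      if (grepl("ly$", low)) return("RB")
      if (grepl("(ous|ful|ive|able|al|ic)$", low) && nchar(low) > 4) {
        return("JJ")
      }
      if (grepl("^#", tok)) return("NN")
      if (grepl("^[A-Z]", tok)) return("NNP")
      if (grepl("s$", low) && nchar(low) > 3) return("NNS")
      "NN"
    }, character(1), USE.NAMES = FALSE)
  }
}

#' Tokenize and tag a normalized text
#'
#' @param text A normalized text (see [normalize_text()]).
#' @param tagger A tagger function (token vector -> tag vector).
#' @return A list of class `tagged_tweet`: `tokens`, `tags`,
#'   `disease_index` (1-based position of the `DISEASE` token, or
#'   `NA_integer_` when absent). The tagger must return one tag per token
#'   and the text at most one `DISEASE` token, otherwise an error is
#'   raised.
#' @export
tag_text <- function(text, tagger = default_tagger()) {
  tokens <- tokenize(text)
  tags <- tagger(tokens)
  if (length(tags) != length(tokens)) {
    stop("tagger contract violation: ", length(tokens), " tokens but ",
         length(tags), " tags", call. = FALSE)
  }
  dis <- which(tokens == "DISEASE")
  if (length(dis) > 1) {
    stop("more than one DISEASE placeholder in text", call. = FALSE)
  }
  structure(
    list(tokens = tokens, tags = tags,
         disease_index = if (length(dis) == 1) dis else NA_integer_),
    class = "tagged_tweet"
  )
}

#' Enumerate POS context patterns around the DISEASE placeholder
#'
#' With L tags available to the left of the placeholder and R to the right,
#' one pattern is emitted for every window shape (l, r) with 0 <= l <= L,
#' 0 <= r <= R, |l - r| <= 1 and l + r >= 1, always using the tags adjacent
#' to the placeholder. The side-length imbalance bound encodes the rule
#' that expansion stops when one side runs out: a (2,1) context yields
#' exactly the four shapes (0,1), (1,0), (1,1), (2,1). Output is ordered by
#' total window size, then left length.
#'
#' @param tagged A `tagged_tweet`.
#' @return A tibble with columns `left` and `right` (list columns of tag
#'   vectors), `l`, `r`, and `pattern` (rendered form, e.g.
#'   `'IN','DISEASE','NNP'`). Empty when no placeholder is present.
#' @export
generate_patterns <- function(tagged) {
  empty <- tibble::tibble(left = list(), right = list(),
                          l = integer(0), r = integer(0),
                          pattern = character(0))
  d <- tagged$disease_index
  if (is.na(d)) return(empty)
  L <- d - 1L
  R <- length(tagged$tags) - d
  shapes <- expand.grid(l = 0:L, r = 0:R)
  shapes <- shapes[abs(shapes$l - shapes$r) <= 1 & shapes$l + shapes$r >= 1, ,
                   drop = FALSE]
  if (nrow(shapes) == 0) return(empty)
  shapes <- shapes[order(shapes$l + shapes$r, shapes$l), , drop = FALSE]
  left <- lapply(shapes$l, function(l) {
    if (l == 0) character(0) else tagged$tags[(d - l):(d - 1)]
  })
  right <- lapply(shapes$r, function(r) {
    if (r == 0) character(0) else tagged$tags[(d + 1):(d + r)]
  })
  tibble::tibble(
    left = left, right = right,
    l = as.integer(shapes$l), r = as.integer(shapes$r),
    pattern = mapply(render_pattern, left, right)
  )
}

#' Render a pattern as comma-joined quoted tags
#'
#' @param left,right Character vectors of tags on each side of the
#'   placeholder.
#' @return A string such as `'NNP','DISEASE','NNP'`.
#' @export
render_pattern <- function(left, right) {
  paste(sprintf("'%s'", c(left, "DISEASE", right)), collapse = ",")
}

#' Aggregate pattern frequencies over a corpus
#'
#' Patterns with identical rendered form are aggregated; rows below
#' `min_count` are omitted. Ordered by descending count with a
#' lexicographic tie-break on the rendered pattern.
#'
#' @param patterns A tibble of emitted patterns (rows from
#'   [generate_patterns()], concatenated over tweets); every instance
#'   counts, with no per-tweet deduplication.
#' @param min_count Minimum count to retain (default 1).
#' @return A tibble `pattern`, `shape_l`, `shape_r`, `count`.
#' @export
pattern_frequencies <- function(patterns, min_count = 1) {
  if (is.null(patterns) || nrow(patterns) == 0) {
    return(tibble::tibble(pattern = character(0), shape_l = integer(0),
                          shape_r = integer(0), count = integer(0)))
  }
  patterns |>
    dplyr::count(.data$pattern, .data$l, .data$r, name = "count") |>
    dplyr::filter(.data$count >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pattern) |>
    dplyr::transmute(.data$pattern, shape_l = .data$l, shape_r = .data$r,
                     count = .data$count)
}

#' Extract POS patterns for every mention-bearing tweet in a corpus
#'
#' Runs normalization (first mention only), tagging, and pattern
#' enumeration over each tweet; convenience driver for the per-collection
#' tables.
#'
#' @param tweets Tweet tibble.
#' @param mentions Mention tibble from [find_mentions()].
#' @param tagger A tagger function.
#' @return A tibble of emitted patterns with a `tweet_id` column.
#' @export
corpus_patterns <- function(tweets, mentions, tagger = default_tagger()) {
  first <- mentions |>
    dplyr::group_by(.data$tweet_id) |>
    dplyr::slice_min(.data$start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  rows <- vector("list", nrow(first))
  text_of <- stats::setNames(tweets$text, tweets$tweet_id)
  for (i in seq_len(nrow(first))) {
    id <- first$tweet_id[i]
    norm <- normalize_text(text_of[[id]], first$start[i], first$end[i],
                           first$surface[i])
    pats <- generate_patterns(tag_text(norm, tagger))
    if (nrow(pats) > 0) {
      pats$tweet_id <- id
      rows[[i]] <- pats
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    tibble::tibble(left = list(), right = list(), l = integer(0),
                   r = integer(0), pattern = character(0),
                   tweet_id = character(0))
  } else {
    out
  }
}

#' Write a pattern frequency table to TSV
#'
#' @param freq Tibble from [pattern_frequencies()].
#' @param path Output path.
#' @export
write_patterns <- function(freq, path) {
  utils::write.table(freq, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
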