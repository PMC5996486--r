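#!/usr/bin/env Rscript

# Step 2: harvest the disease lexicon from the hierarchical terminology —
# collect every subclass name and synonym under the disease root, drop
# surface forms with more than three content words, and normalize.
# Output: results/data/lexicon.tsv

suppressMessages(library(tweetsurv))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# the terminology behind the simulation catalog, traversed through the
# ordinary lexicon path; swap in read_terminology(<csv>) for a real export
nodes <- sim_terminology()
terms <- collect_terms(nodes, "root")
lex <- build_lexicon(terms)

write_lexicon(lex, file.path(out, "lexicon.tsv"))

n_forms <- length(lex$surface_map)
n_syn <- sum(names(lex$surface_map) != unname(lex$surface_map))
cat("collected", nrow(terms), "terminology nodes\n")
cat("lexicon:", length(lex$canonical_terms), "canonical terms,",
    n_forms, "surface forms (", n_syn, "synonyms )\n")
cat("content-word bound:", lex$max_content_words, "; stopwords:",
    paste(lex$stopwords, collapse = ", "), "\n")
cat("written to", file.path(out, "lexicon.tsv"), "\n")
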