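#!/usr/bin/env Rscript

# Step 1: generate the study inputs — a synthetic geolocated message corpus
# with known ground truth, plus airport and hospital POI tables.
# Outputs: results/data/{corpus.jsonl, truth.tsv, airports.csv,
# hospitals.csv}

suppressMessages(library(tweetsurv))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pois <- generate_pois(n_airports = 4, n_hospitals = 6, seed = seed)
cfg <- sim_config(seed = seed, n_tweets = 5000)
sim <- generate_corpus(cfg, pois)

write_corpus(sim$tweets, file.path(out, "corpus.jsonl"))
write_truth(sim$truth, file.path(out, "truth.tsv"))

write_poi_csv <- function(pois, path) {
  df <- data.frame(id = pois$poi_id, type = pois$poi_class, name = pois$name,
                   latitude_deg = pois$lat, longitude_deg = pois$lon)
  write.csv(df, path, row.names = FALSE)
}
write_poi_csv(pois$airports, file.path(out, "airports.csv"))
write_poi_csv(pois$hospitals, file.path(out, "hospitals.csv"))

cat("simulated", nrow(sim$tweets), "messages (seed", seed, "):\n")
print(table(sim$truth$class))
cat("planted collections:\n")
print(table(sim$truth$collection))
cat("written to", out, "\n")
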