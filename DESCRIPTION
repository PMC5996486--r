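Package: tweetsurv
Title: Disease-Mention Surveillance in Geolocated Short Messages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for digital disease surveillance over
    geolocated short public messages. Harvests a disease lexicon from a
    hierarchical clinical terminology (canonical names plus synonyms, with a
    content-word length filter), removes job-advertisement and location
    check-in noise with regular expressions, assigns messages to airport,
    hospital and background collections by great-circle proximity to points
    of interest, detects strict dictionary mentions of disease terms,
    extracts part-of-speech context patterns around the mention, and
    quantifies agreement between dictionary matching and a concept
    identifier. Includes a synthetic corpus generator with full ground truth
    that emulates news-title duplication and personal-statement structure
    for end-to-end evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
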