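Package: explowl
Title: Difficulty-Controlled Game AI Test Suite for 'Explorers vs Owls'
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic hexagonal-grid two-player game engine
    ('Explorers vs Owls'), a Monte Carlo Tree Search opponent with
    Outcome-Sensitive Action Selection ('True POSAS') that steers the final
    player-minus-AI score margin toward an arbitrary target, scripted
    synthetic opponents of graded skill, and an agent-vs-agent experiment
    harness that validates difficulty-target tracking across easy, balanced
    and hard conditions with Kruskal-Wallis tests and epsilon-squared effect
    sizes. Includes reproducible seeded simulation, JSON/JSONL logging, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
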