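Package: cbmgames
Title: Headless Game-Logic Engines for Cognitive Bias Modification and
    Learned Helplessness Serious Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic, seedable state machines for five serious games
    used in digital interventions for depression: a word-search game for
    automatic interpretation bias modification, a platformer-embedded
    executive control trainer with flanker/image/circle rounds, a
    face-grid game for negative attention bias modification with adaptive
    staircase difficulty, an interactive-fiction game for positive
    imagery training, and a puzzle suite (circle-triangle flip puzzle,
    15-puzzle, butterfly path, and arc nesting) that demonstrates learned
    helplessness through verified-unsolvable levels. Includes simulated
    user agents, JSON-Lines session logging, a shared points/coins/lives/
    badges economy, content-bank validation, and the acceptability
    analysis used for such games (Likert score mapping, exact Wilcoxon
    signed-rank tests against zero, percentage summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
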