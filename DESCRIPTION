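Package: pkst
Title: Procedural Knowledge Space Theory and Adaptive Assessment of Problem Solving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling human problem solving in well-structured tasks
    such as the Tower of London test. Builds problem spaces (finite labeled
    deterministic transition systems) and shortest-path goal spaces, enumerates
    solution paths and the subpath partial order, and derives competence and
    knowledge spaces by union closure of the skill map. Implements the Markov
    solution process model (MSPM) under pre-planning, interim-planning and
    mixed-planning assumptions, adaptive assessment engines (the continuous
    Markov procedure on dichotomous responses and move-by-move procedures on
    full solution processes) with half-split question selection, and a
    simulation-study harness with accuracy and efficiency metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
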