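Package: bifan
Title: Bifurcation Transitions in Asynchronous Automata Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of bifurcation transitions in asynchronous
    automata networks: local transitions whose occurrence irreversibly
    removes the ability to reach a goal local state. Provides a parser and
    canonical serializer for a textual automata-network format, an encoder
    from Boolean networks ('targets, factors' tables) via prime implicants,
    explicit reachable state graphs with attractor (terminal strongly
    connected component) detection, an exact bifurcation oracle, static
    reachability over- and under-approximations based on Local Causality
    Graphs, and the sound (no false positive) but incomplete approximate
    bifurcation search built on them. Includes a seeded random network
    generator for property-based testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
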