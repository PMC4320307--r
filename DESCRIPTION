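Package: permutoglia
Title: Permutation Systems, Hamilton Loops, and a Glial-Neuronal
    Reticular-Formation Simulator
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for n-valued permutation systems built from adjacent-value
    negation operators: lexicographic ranking, permutographs (Cayley graphs of
    the symmetric group with adjacent-transposition generators), verification,
    construction and exhaustive enumeration of Hamilton loops, and Guenther
    visit-order matrices. On top of the formalism, a simulator of brainstem
    reticular-formation behavior modes: gap-junction plaques carrying loop
    repertoires with stochastic channel turnover, an abductive command
    architecture that selects and executes behavior-mode programs against
    environmental signals, and a seeded behavior-mode scheduler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
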