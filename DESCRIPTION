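Package: songscape
Title: Agent-Based Simulation of Territorial Songbird Vocal Contact Under
    Aridifying Climates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whether territorial songbirds can maintain audible
    contact with their neighbors as mornings grow hotter and drier. Couples a
    humid-air atmospheric sound absorption model (nitrogen/oxygen relaxation,
    ISO 9613-1 style) to an agent-based sing/move/rest behavior model on a
    hexagonal territory grid, with an optional evaporative water loss budget
    that suppresses singing as birds dehydrate. Provides weather-series
    handling (Mesonet-style tables, climate-change deltas, synthetic morning
    profiles), audible-radius computation against a fixed detection
    threshold, population completion-percentage experiments, and two-bird
    frequency-by-territory-size sweeps, all with tidy tabular outputs and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
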