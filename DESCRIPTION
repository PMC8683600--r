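Package: scaletrace
Title: Quantifying Trans-National Pangolin Trafficking from Seizure Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating multi-source wildlife-seizure databases and
    quantifying the illegal pangolin trade linked to Nigeria. Provides
    deduplication of seizure records across reporting databases with a
    lowest-reported-mass rule, transport-mode and country-role (origin,
    transit, import) classification of trade routes, Kruskal-Wallis and
    Dunn post-hoc comparisons of shipment mass across transport modes, a
    log10-mass year-by-mode regression with AIC model selection, and a
    bias-corrected and accelerated (BCa) bootstrap estimator that converts
    confiscated scale mass into a minimum number of trafficked pangolin
    individuals (MNI) with 95 percent confidence intervals. Seeded synthetic
    generators emulate seizure databases and sampled scale sacks so the full
    pipeline is testable without access to enforcement data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
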