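Package: traitrates
Title: Comparing Brownian Evolutionary Rates Among Continuous Traits on a
    Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the evolutionary rate matrix of
    several continuous traits evolving by correlated Brownian motion on a
    time-calibrated phylogeny, and likelihood-ratio / AIC comparison against a
    constrained model in which all traits share a common evolutionary rate.
    Includes post hoc pairwise rate comparisons with compact-letter summaries,
    phylogenetic GLS estimation of ancestral trait means, a seeded simulator
    for trees and correlated Brownian trait data (with presets emulating
    comparative datasets on sperm heteromorphism in Drosophila and
    Lepidoptera), dataset assembly from newick + CSV inputs, and report
    rendering in text, JSON and TSV formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
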