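Package: ipasim
Title: In Silico Acquisition Simulation for Targeted Immunopeptidomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates liquid-chromatography tandem mass spectrometry
    acquisition of HLA-presented peptides as an in silico instrument.
    Provides a synthetic immunopeptidome generator with dilution-series
    mixing, inclusion-list construction with retention-time scheduling,
    a cycle-budgeted acquisition engine implementing TopN data-dependent
    acquisition (DDA), inclusion-list DDA, and a real-time-search-filtered
    targeted method with a scouting/high-sensitivity scan decision tree,
    SEQUEST-style fast cross-correlation and hyperscore/spectral-angle
    scoring, a simplified offline search engine with chimeric co-isolation
    handling and target-decoy false discovery rate control, and benchmark
    metrics for the target-sensitivity versus global-depth trade-off.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
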