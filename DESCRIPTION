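Package: spikequant
Title: Spike-In Calibrated Absolute Quantification for Low-Biomass 16S
    Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Converts zOTU read-count tables from low-biomass 16S rRNA
    amplicon experiments into absolute abundances (cell equivalents) using
    cellular spike-in calibrators with known 16S copy numbers. Provides
    sample quality control based on calibrator recovery and read ratios,
    16S copy-number correction with rank-wise fallback, screening for taxa
    sporadically enriched in case samples relative to matched controls,
    paired Wilcoxon signed-rank testing with Benjamini-Hochberg correction,
    and a ground-truthed synthetic community simulator for end-to-end
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    jsonlite,
    optparse
Config/testthat/edition: 3
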