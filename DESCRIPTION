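Package: xtalcmp
Title: Statistical Comparison and Validation of Crystallographic Model Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision and validation layer for comparing an initial against an
    optimized macromolecular crystal structure model. Provides significance
    tests for changes in global quality indicators (free R factor, free
    correlation coefficient via the Fisher transformation, restraint r.m.s.
    Z-scores, percentile ranks), a weighted van der Waals clash severity score,
    equal-count resolution binning with a paired-refinement resolution-cutoff
    decision rule, k-fold cross-validation of the free R factor for small test
    sets, occupancy sanitization, per-residue real-space correlation change
    classification, detection of discrete model changes (rotamers, peptide
    flips, His/Asn/Gln flips, deleted waters, completed side chains) with Coot
    script emission, and percentile/box-plot statistics against a reference
    databank of quality scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
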