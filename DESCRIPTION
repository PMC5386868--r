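Package: norinherit
Title: Inheritance and Stability of 45S rRNA Gene Copy Number
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of 45S rRNA gene (nucleolus organizer
    region, NOR) copy-number inheritance in Arabidopsis thaliana style
    pedigrees. Provides a pedigree simulator with Haldane crossovers and
    unequal-crossover copy-number jumps; copy-number estimation from
    sequencing-depth ratios and from qPCR delta-Ct values with plate
    standardization; windowed genotyping-by-sequencing classification;
    single-QTL interval mapping by Haley-Knott regression with
    permutation-based genome-wide thresholds and a cofactor-adjusted scan;
    and copy-number stability analysis via likelihood-ratio tests on linear
    mixed models and coefficient-of-variation trajectories across
    generations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
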