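Package: punctafiber
Title: Quantification of Immunofluorescent Puncta on Nerve Fibers
Version: 0.1.0
Authors@R: person("punctafiber", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible pipeline for quantifying punctate
    immunofluorescence (e.g. TRPV1) restricted to nerve-fiber regions
    (e.g. PGP9.5-labeled) in two-channel 16-bit microscopy images.
    Provides trainable random-forest pixel classification of curvilinear
    fiber structures, STAPLE expectation-maximization fusion of
    multi-expert annotations, mask-restricted local-maxima puncta
    detection with an exhaustive reference oracle, per-image
    quantification (punctum count, mean fluorescence intensity, fiber
    area), method-agreement statistics (Spearman, two-way mixed
    absolute-agreement ICC with qualitative bands, Kruskal-Wallis with
    Dunn post-hoc), and a seeded synthetic-image generator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
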