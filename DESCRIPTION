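Package: numadapt
Title: Model-Based Analysis of Numerosity Adaptation in Early Visual fMRI Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying numerosity adaptation in early visual cortex with
    model-based fMRI. Generates constant-area numerosity dot displays and their
    aggregate spatial-frequency (Fourier) power, builds the interleaved
    adaptor/changing stimulus sequences, and predicts BOLD time courses under a
    monotonic (log aggregate Fourier power or log numerosity) response model and a
    log-Gaussian numerosity-tuned population receptive field model. Voxel time
    series are fit by ordinary least squares and exhaustive grid search,
    classified by odd/even-run cross-validation, aggregated into visual-field-map
    examples, and summarised by a proportional slope-reduction adaptation metric
    with signed-rank, ANOVA/Tukey and correlation group statistics. Includes a
    behavioural 2AFC point-of-subjective-equality validation pipeline and a
    synthetic ground-truth data generator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    RNifti,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
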