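Package: xtopr
Title: Absolute Proteome Quantification with the xTop Peptide-to-Protein
    Inference Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Peptide-to-protein inference for label-free (DIA/SWATH)
    proteomics and conversion of inferred intensities to absolute proteome
    mass fractions. Implements the xTop maximum-a-posteriori estimator,
    which models each peptide-precursor intensity as the product of a
    sample-dependent protein intensity and a peptide-specific detection
    efficiency, alongside the TopPepN and iBAQ baselines. Includes
    calibration of relative mass fractions against an external absolute
    standard (e.g. ribosome-profiling synthesis rates), conversion to
    cellular concentrations, complex concentrations and membrane surface
    densities, a benchmarking suite (replicate CVs, log-ratio variances,
    fold-change concordance, multilinear bias regression, proteome
    distance), a growth-limitation proteome-sector classifier, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    optparse,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
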