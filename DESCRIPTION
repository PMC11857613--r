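Package: ms2fp
Title: Molecular Fingerprint Prediction from MS/MS Spectra and Metabolite Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating metabolites from tandem mass spectrometry
    (MS/MS) data. Spectra read from MSP or MGF libraries are scaled, filtered
    and binned onto a fixed 0.01 Da grid; multi-label neural networks (dense,
    convolutional and recurrent architectures trained under a differentiable
    Tanimoto objective) predict condensed molecular fingerprints from the
    binned vectors; candidate compounds are retrieved from a compound table by
    precursor m/z under adduct hypotheses within a ppm tolerance, scored by
    fingerprint Tanimoto similarity, optionally fused with external
    formula-prediction scores, and ranked. Includes supervised selection of
    informative m/z bins and well-predicted fingerprint bits, structure-disjoint
    top-k evaluation, and a synthetic-data generator with a planted
    fingerprint-to-fragment rule for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
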