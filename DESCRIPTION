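Package: petac
Title: PET Attenuation Correction via Pseudo-CT Synthesis from Uncorrected PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for quantitative PET
    attenuation correction driven by pseudo-CT images synthesized from
    non-attenuation-corrected (NAC) FDG-PET. Provides a seeded digital head
    phantom generator (paired CT and tracer-activity volumes), an attenuated
    parallel-beam projection and OSEM/MLEM reconstruction physics layer, the
    exact input conditioning used for network training (intensity scaling,
    bounding-box cropping, Softsign transform, bilinear resampling), a
    convolutional encoder-decoder with symmetric residual shortcut
    connections trained with ADAM on a mean-squared-error image loss, and
    quantitative evaluation (HU-threshold tissue discretization, Dice,
    mean absolute error, relative PET error maps, ROI statistics with paired
    t-tests and Bonferroni correction).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
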