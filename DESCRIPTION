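Package: dwikit
Title: Diffusion Tensor, Kurtosis, and White-Matter Biophysical Modelling for dMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative processing of diffusion-weighted MRI volumes: noise
    estimation in magnitude images, Rician/noncentral-chi bias correction,
    diffusion tensor fitting by ordinary, weighted, robust iteratively
    reweighted, and nonlinear least squares, diffusion kurtosis and
    axisymmetric kurtosis fitting, derived rotation-invariant scalar maps,
    reliability masking, and two-compartment Watson standard-model inversions
    (WMTI-Watson and NODDI-DTI). Includes a synthetic multi-shell phantom
    generator with noncentral-chi noise and slice-wise outlier injection, BIDS
    derivative naming, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
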