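Package: mzring
Title: Marginal-Zone Ring Model and Calcium-Imaging Analysis for Embryonic Polarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic reaction-diffusion model of BMP4, cVG1/GDF3 and
    calcium activity on the one-dimensional ring of marginal-zone cells that
    positions the primitive streak in the early chick blastoderm, including
    the anterior-half-cut experiment with an oblique bias. Companion analysis
    tools for calcium-imaging data: delta-F/F0 normalisation, asymmetric
    least squares baseline removal, transient (spike) detection with
    frequency, amplitude and FWHM statistics, linear-assignment linking of
    firing events into intercellular calcium tracks, quadrant angle classes,
    and sector histogram analysis with log-normal fitting. Seeded synthetic
    data generators with ground truth make every analysis stage testable
    end-to-end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    Matrix,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
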