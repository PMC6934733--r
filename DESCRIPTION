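Package: lufret
Title: Linear-Unmixing FRET Analysis for Metabolite Sensors in
    Autofluorescent Tissue
Version: 0.1.0
Authors@R: person("lufret", "developers", email = "lufret@example.org",
    role = c("aut", "cre"))
Description: Quantitative imaging pipeline for genetically encoded
    CFP/YFP FRET metabolite sensors (lactate, pyruvate, 2-oxoglutarate
    families) in tissues with strong, spatially heterogeneous
    autofluorescence. Implements per-pixel three-channel spectral linear
    unmixing using a dedicated long-wavelength autofluorescence channel,
    expression-independent FRET-map construction, the constant-background
    baseline it replaces, validation analyses (acceptor photobleaching,
    direct acceptor-excitation control, donor/acceptor anti-correlation),
    single-site dose-response calibration, ROI quantification, time
    courses, a Shapiro-Wilk/Levene/Box-Cox gated statistical comparison
    pipeline with Dunnett many-to-one contrasts, a forward simulator of
    sensor-expressing tissue with Poisson photon noise, and a command-line
    interface. Includes a minimal self-contained multi-page TIFF
    reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
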