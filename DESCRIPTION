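Package: glycomob
Title: Ion Mobility Mass Spectrometry Glycomics of Mucin-Type O-Glycan
    Alditols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for trapped (TIMS) and travelling-wave (TWIMS) ion
    mobility glycomics of reduced mucin-type O-glycans. Provides
    monoisotopic mass arithmetic and composition search from observed m/z,
    a tree model of O-glycan structures with core classification and motif
    detection, negative-mode glycosidic and cross-ring fragment generation
    with diagnostic core scoring, CCS calibration for both instrument
    families, extracted-ion-mobilogram construction and Gaussian
    deconvolution with isomer quantification, CCS reference-library
    matching, sample-level glycosylation profiling, and deterministic
    synthetic-data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
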