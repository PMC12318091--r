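Package: phasorfret
Title: Phasor FLIM-tmFRET Analysis of Voltage-Sensor Conformations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for frequency-domain fluorescence lifetime
    imaging (FLIM) combined with transition-metal FRET (tmFRET). Simulates
    time-correlated single-photon-counting decay images with known ground
    truth, transforms decays into calibrated phasor coordinates, reads
    ensemble FRET efficiencies off the FRET trajectory, resolves two-state
    mixtures of lifetime species by linear unmixing along the phasor chord,
    converts FRET efficiencies to mean donor-acceptor distances through a
    Forster equation convolved with a Gaussian distance distribution, and
    translates state fractions and conductance-voltage curves into
    subunit-gating energetics for tetrameric ion channels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
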