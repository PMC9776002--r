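Package: detecr
Title: LFP-Guided Monopolar Contact Selection for Directional Deep Brain
    Stimulation Leads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-contact "monopolar" beta-band spectra from the 15
    bipolar BrainSense-Survey-style local field potential recordings of a
    directional subthalamic deep brain stimulation lead by distance-weighted
    averaging, removes the aperiodic 1/f spectral component, detects beta
    peaks with an RMSE prominence criterion, and ranks stimulation levels and
    directional contacts by normalized beta activity to propose a monopolar
    stimulation configuration. Ships a geometric model of 8-contact
    directional leads, a synthetic survey simulator with known ground truth,
    evaluation utilities (rank correlation against clinical monopolar-review
    scores, sweet-spot distance analysis), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
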