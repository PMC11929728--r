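Package: vadstrain
Title: Brain Strain from Sonomicrometry in Vacuum-Assisted Delivery Phantom Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw sonomicrometry inter-crystal distance traces and
    traction-force recordings from vacuum-assisted delivery (VAD) phantom
    experiments into three-dimensional crystal trajectories, one-dimensional
    engineering strain along the traction-force direction, and force-strain
    correlation and repeatability statistics. Provides scaled-MAD outlier
    filtering, per-pair calibration against CT-derived reference distances,
    closed-form three-sphere trilateration with a least-squares fallback,
    orthogonal trajectory-direction fitting, traction-force reference frame
    construction, crystal-pair selection, peak alignment, and a synthetic
    experiment generator with known ground truth so that every stage of the
    pipeline can be validated without access to a physical phantom.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
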