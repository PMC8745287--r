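Package: optodrum
Title: Optomotor-Response Quantification from Overhead Arena Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the rodent optomotor reflex from overhead video of a
    rotating striped drum. Recovers the stimulus rotation direction per frame
    from the stripe band above the arena center, tracks the mouse by circular
    masking, constant-threshold segmentation, centroid position angle and
    principal-axis body orientation, converts the angle series to angular
    velocities, and reports the two assay endpoints: angular orientation speed
    and angular running speed, averaged over frames where the animal moves
    with the stimulus. Includes a ground-truthed synthetic arena renderer so
    the full pipeline is testable without recorded data, and a utility for the
    composite experimental autoimmune uveoretinitis (EAU) clinical score.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
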