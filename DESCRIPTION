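Package: fishbout
Title: High-Throughput Classification of Larval Zebrafish Motor Behavior
    from Keypoint Pose Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns 8-keypoint pose tracks of larval zebrafish recorded in
    24- or 96-well plates into per-frame motor-behavior calls (stationary,
    scoot, R-turn, acoustic-startle-like, visual-startle-like), behavioral
    bouts, kinematic summaries and stimulus-response rates. Pose tracks are
    sliced into overlapping 40-frame windows, egocentrically aligned,
    flattened and normalized; candidate bouts are discovered by KMeans
    clustering; a PCA plus random-forest classifier labels windows; sliding
    window majority voting converts window labels to per-frame calls which
    are segmented into bouts. A synthetic trajectory simulator with
    archetypal scoot, turn, C-start-like and O-bend-like kinematics provides
    labeled ground truth so the whole pipeline can be exercised without
    imaging hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
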