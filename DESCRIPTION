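Package: larvatrack
Title: Kinematic Scoring and Group Analysis of Larval Chemotaxis Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the behavior of individually tracked mosquito larvae
    from head-position time series sampled at 1 Hz during 5-minute arena
    assays. Each trajectory is scored into four kinematic metrics - turns
    (successive tracking vectors intersecting at more than 45 degrees),
    movement instances (per-interval head displacements exceeding a
    body-length-derived threshold of about 2.3 mm for a 3.25 mm larva),
    average velocity, and resting time. Group comparisons use single-factor
    ANOVA with Tukey-Kramer post-hoc tests, and RNAi knockdown validation
    uses Pfaffl relative quantification of qPCR data. A two-state (rest/move)
    correlated random walk simulator generates trajectories with
    attractant-, repellent-, and knockdown-modulated kinematics, providing
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
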