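Package: cellmigrl
Title: Reinforcement-Learning Tissue Environments for Cell Migration from
    Nucleus-Tracking Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Gym-style reinforcement-learning environments in which a
    migrating cell is an agent inside a 3-D tissue reconstructed from
    nucleus-tracking time series (AceTree-like lineage records). Provides
    readers, writers and temporal upsampling for tracking data, a synthetic
    embryo and migration-corridor generator, Voronoi/Delaunay neighbor graphs
    with a trainable random-forest neighbor classifier, a three-part reward
    formulation (neighbor distance, destination, and gradient or subgoal
    terms), grayscale plus depth image observations, DQN and hierarchical DQN
    agents for gradient-driven versus collective (subgoal-driven) migration
    hypotheses, multi-embryo distance-curve standardization, and
    neighbor-removal influence experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
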