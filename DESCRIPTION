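Package: metgei
Title: Genotype-by-Environment Interaction and Stability Analysis for
    Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of balanced multi-environment trials (MET): pooled
    factorial analysis of variance over genotype, location and year;
    univariate stability statistics (Eberhart-Russell joint regression,
    Perkins-Jinks regression, Wricke's ecovalence, Francis-Kannenberg
    coefficient of variation); AMMI (additive main effects and
    multiplicative interaction) decomposition with interaction principal
    component ANOVA and biplot coordinates; GGE biplot geometry
    (which-won-where mega-environment partition, mean-versus-stability
    projections on the average environment coordinate, ideal-genotype
    ranking, environment discriminativeness and representativeness); and
    pairwise trait correlation. Includes a simulator for balanced MET data
    with known additive and low-rank multiplicative interaction structure
    so every stage of the pipeline can be validated against implanted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
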