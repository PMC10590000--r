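Package: mafldtraj
Title: Temporal Disease and Death Trajectories of Metabolic
    Dysfunction-Associated Fatty Liver Disease
Version: 0.1.0
Authors@R:
    person("Maintainer", "mafldtraj", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for temporal disease- and death-trajectory
    analysis of metabolic dysfunction-associated fatty liver disease (MAFLD)
    from ICD-10 coded hospital diagnosis histories. Covers fatty-liver
    phenotyping (fatty liver index, NAFLD fibrosis score, MAFLD criteria,
    polygenic risk score), 1:1 propensity-score matching, incidence-filtered
    Cox phenome-wide association sweeps, temporal disease-pair inference
    (exact binomial direction test plus logistic confirmation), and
    trajectory-graph assembly with transitive-edge pruning. Includes a seeded
    synthetic-cohort generator with planted exposure hazards and directed
    pair amplification so every stage is verifiable without restricted
    biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    survival,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
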