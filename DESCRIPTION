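Package: phytoscreen
Title: Network and Chemoinformatic Screening of Medicinal-Plant
    Phytochemicals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A multi-phase in-silico screen that prioritises medicinal
    plants and their phytochemicals for anti-oxidant, anti-inflammatory,
    anti-aging and anti-senescence potential.  Builds taxonomy-activity
    networks and ranks hub nodes (degree and maximal-clique-count
    scores), gates compounds by quantitative estimate of drug-likeness
    (QED), toxicity alerts and target availability, clusters 1024-bit
    fingerprints against a reference-drug panel (Tanimoto distance, Ward
    linkage, elbow rule, k-means, silhouette and Dunn validation), ranks
    compound-target-pathway networks, scores pathway enrichment by
    hypergeometric tests and random-walk-with-restart XD-scores, and
    analyses carrageenan paw-edema experiments (ANOVA with Monte-Carlo
    Dunnett contrasts).  Ships a seeded synthetic-data generator with
    planted structure so every stage has a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ChemmineOB,
    ChemmineR,
    cluster,
    mclust,
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
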