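Package: chemophylo
Title: Comparative Chemo-Phylogenetics of Pheromone Production and Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline linking cuticular chemical profiles,
    olfactory detection, and phylogeny across a species radiation. From
    replicate-level chemical peak tables and a species phylogeny it calls
    sex-specific and mating-transferred compounds, estimates per-compound
    phylogenetic signal (Pagel's lambda) under a lambda-transformed
    Brownian-motion model and compares its distribution between sexes,
    fits phylogenetic regressions linking compound production to neuronal
    responses (PGLS with BIC model selection for continuous traits, a
    binary phylogenetic logistic model with parametric bootstrap for
    presence/absence), builds the interspecific olfactory detection
    network with its per-species clustering coefficient, and ranks
    candidate reference genomes by a mapping-based quality index. Seeded
    generators produce every input with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
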