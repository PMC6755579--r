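Package: chaosdock
Title: Chaos-Embedded Particle Swarm Optimization for Protein-Ligand Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid-receptor, flexible-ligand molecular docking in which the
    global conformational search is a particle swarm optimizer whose inertia
    and acceleration randomness are driven by chaotic maps (logistic, Singer,
    sinusoidal, tent, Zaslavskii), refined by a two-stage BFGS local search
    and scored with a Vina-style empirical function. Includes PDBQT input and
    output with torsion-tree handling, docking-box construction, a virtual
    screening pipeline with AUC-ROC and enrichment-factor metrics, and
    synthetic toy-complex generators so the whole engine can be exercised
    without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
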