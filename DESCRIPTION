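Package: dualbind
Title: Dual-Binding Analysis and Discovery of Protein-Protein Interaction Stabilizers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the dual-binding theory of protein-protein interaction
    (PPI) stabilizers (molecular glues). Solves the ternary receptor-ligand-
    stabilizer binding equilibrium exactly and in a dilute closed form, computes
    the optimal stabilizer dose, the effective dissociation constant K_RL,eff,
    titration (hook-effect) curves and binding-energy grid scans; aggregates
    per-frame MM/GBSA-style interaction-energy tables with replica-aware
    statistics, scores dual binding, classifies stabilization mechanisms and
    reranks candidate compounds; analyses interface pocket geometry (atom-probe
    contacts, ligand coverage fractions, interface-pocket criteria, buried
    surface area, interface RMSD); and wires these pieces into a configurable
    in-silico stabilizer discovery pipeline with pluggable docking adapters and
    a self-verifying synthetic-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
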