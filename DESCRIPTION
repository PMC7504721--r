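Package: sprfrag
Title: Fragment Screening Triage and Steady-State Affinity Analysis for SPR Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surface plasmon resonance (SPR) fragment-based drug
    discovery campaigns: simulation of 1:1 Langmuir binding cycles with DMSO
    bulk artifacts, double referencing and excluded-volume solvent correction,
    clean-screen filtering of non-specific binders, theoretical-Rmax hit
    calling with superstoichiometric exclusion, constrained steady-state KD
    fitting with replicate aggregation, stoichiometry-normalized multi-surface
    domain mapping, compound-library profiling (rule of three, ligand
    efficiency, atom-pair Tanimoto similarity and single-linkage clustering),
    and ELISA-based complement activity analysis with constrained IC50 fits.
    All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineR,
    deSolve,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
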