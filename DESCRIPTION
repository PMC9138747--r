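Package: pepnni
Title: Nearest-Neighbor Interaction Analysis of Unfolded Peptide Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Four-state Ising-type analysis of residue conformational
    equilibria in short unfolded host-guest peptides (GxG, GxyG, GxyzG).
    Derives intrinsic Gibbs energies of polyproline II, beta-strand and
    aggregated turn/helix classes from reference mole fractions, computes
    joint conformer populations of tetra- and pentapeptides under
    directional nearest-neighbor interaction (NNI) Gibbs energies, fits
    those coupling energies to observed residue mole fractions by staged
    least squares with flat-chi-square uncertainty scans, and quantifies
    the NNI-induced loss of conformational entropy relative to the
    isolated pair hypothesis. A companion Gaussian-basin Ramachandran
    module predicts ensemble-averaged scalar J-couplings through Karplus
    equations and estimates basin statistical weights from observed
    couplings. A synthetic-data generator makes every stage testable
    end to end.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
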