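Package: pennet
Title: Protein Energy Networks from Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds protein energy networks (PENs): complete weighted graphs
    over a protein's residues whose edge weights are ensemble-averaged
    pairwise non-bonded interaction energies (Lennard-Jones plus Coulomb,
    kJ/mol). Thresholding the PEN at an energy cutoff e yields unweighted
    graphs PEN_e which are analyzed over a cutoff grid with network
    statistics: largest connected component, cluster (connected-component)
    populations, hubs, k-cliques, and k-clique-percolation communities.
    Includes readers for PDB structure ensembles and tab-separated energy
    matrices, a self-contained simplified non-bonded parameter set, synthetic
    fixture generators, pairwise homolog comparison reports, and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
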