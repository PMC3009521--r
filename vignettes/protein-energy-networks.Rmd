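---
title: "Protein energy networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein energy networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pennet)
```

## The model

A protein energy network (PEN) represents a protein as a complete weighted
graph: one node per amino-acid residue, and for every unordered residue pair
$(i, j)$ an edge weighted by the pairwise non-bonded interaction energy

$$E_{ij} \;=\; \left\langle V_{LJ}(r_{ij}) + V_C(r_{ij}) \right\rangle,$$

the sum of Lennard-Jones and Coulomb terms over all atom pairs of the two
residues, averaged over an ensemble of structures (e.g. frames of an MD
trajectory, or the MODEL blocks of an NMR-style PDB file). Units are kJ/mol
throughout. The package keeps three weight channels: the total $E_{ij}$, the
LJ-only part $V_{LJ}$, and the Coulomb-only part $V_C$, so that networks can
be built from packing interactions or electrostatics alone.

Thresholding turns the weighted PEN into an unweighted graph $PEN_e$: an
edge joins $i$ and $j$ exactly when $E_{ij} \le e$. The sign convention
matters and is used consistently: *low energy* means a small negative
magnitude (weak attraction, e.g. $-5$ kJ/mol) and *high energy* a large
negative magnitude (strong attraction, e.g. $-25$ kJ/mol). Because lowering
$e$ can only remove edges, the family $\{PEN_e\}$ is nested, and every
monotone network statistic traced over a cutoff grid yields a well-behaved
transition or population profile:

* **LCC** — size of the largest connected component;
* **clusters** — number of connected components with at least 3 residues;
* **hubs** — nodes of degree $\ge 4$;
* **cliques** — number of $k$-cliques (complete $k$-subsets, all
  $k(k-1)/2$ edges present);
* **largest community** — clique-percolation communities: two $k$-cliques
  are adjacent when they share $k-1$ nodes, a community is a maximal set of
  cliques chained by this adjacency, and its size is the number of distinct
  residues it covers ($k = 3$ by default).

## The energy model and its parameters

The energies are plain pairwise sums — no periodic boundary conditions, no
solvent, no Ewald summation — because the network uses only residue–residue
terms. Per atom pair at distance $r$ (nm):

$$V_{LJ}(r) = 4\varepsilon\left[\left(\tfrac{\sigma}{r}\right)^{12} -
\left(\tfrac{\sigma}{r}\right)^{6}\right], \qquad
V_C(r) = \frac{k_e\, q_i q_j}{\varepsilon_r\, r},$$

with $k_e = 138.935485$ kJ·mol⁻¹·nm·e⁻² and $\varepsilon_r = 1$ by default.
Cross-parameters use Lorentz–Berthelot combining (arithmetic $\sigma$,
geometric $\varepsilon$); a geometric rule is available. The package ships a
self-contained simplified parameter table (`inst/extdata/nonbonded_params.tsv`)
covering heavy atoms and polar hydrogens of the 20 standard amino acids in a
united-atom style (aliphatic hydrogens folded into their carbons). It is a
deliberately small, transparent set: energies computed with it are
internally consistent and reproduce the qualitative LJ/electrostatic regimes,
but they are not interchangeable with energies from a full MD force field —
users wanting production energetics should import their own matrices
(`read_energy_matrix()`) or parameter table (`read_forcefield()`).

Tunable parameters, defaults, and why:

| parameter | default | rationale |
|---|---|---|
| cutoff grid | 0 to $-35$, step 1 kJ/mol | pair energies essentially span this range; half-integer grids dodge ties with integer-valued synthetic fixtures |
| hub degree | 4 | convention of packing-based protein structure network studies |
| minimum cluster size | 3 | a pair is not a stabilizing unit; 3 is the smallest cooperative motif |
| clique size $k$ | 3 | smallest $k$ with a non-trivial percolation structure |
| neighbor exclusion | on | sequence-adjacent pairs are dominated by through-bond geometry and would tie the backbone into a trivially connected chain at every cutoff |
| distance cutoff | none | matrices are small (hundreds of residues); exact sums beat truncation |
| relative dielectric | 1 | bare Coulomb, matching the vacuum-style pairwise model |

Hydrogens are used when present in the input and silently absent otherwise
(with a warning tally for unparameterized atoms); no protonation engine is
bundled. Alternate locations keep the highest-occupancy conformer so all
frames share one topology.

## The synthetic generator

`generate_synthetic_matrix()` emulates the empirical shape of PEN energy
distributions: a dense LJ-dominated mode of weak contacts (Gaussian, mean
$-5$, sd $1.5$ kJ/mol) and a sparse electrostatics-dominated mode of strong
contacts (mean $-27$, sd $2$ kJ/mol), with half of all residue pairs
non-interacting (zero). The electrostatic fraction defaults to 0.02 of
interacting pairs: strong electrostatic contacts (salt bridges) number on
the order of the residue count in real proteins — a vanishing fraction of
all $n(n-1)/2$ pairs — which keeps the high-energy subgraph sparse and
sub-percolative, so electrostatic cliques appear without aggregating into
communities. Planted cliques force the total energy of all internal pairs
of a chosen node set to a target value (the LJ channel absorbs the
adjustment), making recovery assertions exact.

What the generator does *not* emulate: spatial correlation of contacts
(real interaction graphs are geometric, not Erdős–Rényi), residue-type
composition effects, correlated frame-to-frame fluctuations, and repulsive
tails. Tests passing on synthetic matrices therefore validate the graph
machinery and the qualitative two-mode behavior, not biological conclusions
about any particular protein.

`generate_toy_ensemble()` builds a poly-alanine chain on an ideal helical
curve (CA radius 0.23 nm, rise 0.15 nm, 100° per residue — the geometry of
an α-helix) with fixed local offsets for N, H, C, O, CB and per-frame
isotropic Gaussian jitter standing in for thermal fluctuation. It exists so
the coordinate → energy → network pipeline is testable end to end with no
downloads; it is not a conformational model.

## Numerical choices

* **Inclusive threshold.** $E_{ij} \le e$ is taken literally, with no
  tolerance band; ties at exact equality draw edges. Grid points are
  generated exactly as $\mathrm{start} - i\cdot\mathrm{step}$ (no
  accumulation) and written with 3 decimals.
* **Determinism.** Components are ordered by smallest member; cliques are
  sorted lexicographically; communities by size descending then smallest
  member; profile peaks break ties toward the least negative cutoff. All
  generators take mandatory seeds and restore the caller's RNG state, so
  the same inputs give byte-identical output files.
* **Degenerate inputs.** Empty graphs yield singleton components (LCC 1);
  a metric with no qualifying structure reports 0; `transition_width()`
  refuses all-zero profiles and profiles that never fall below the low
  fraction, rather than inventing a bracket.
* **Exclusions carry through.** Pairs excluded from the energy computation
  are zero in all channels *and* flagged, so a cutoff of 0 cannot turn
  them into edges.

## Problem sizes

The shipped tests and the acceptance script run at deliberately compact
scales chosen to exercise every code path: oracle comparisons on 100 random
graphs of up to 20 nodes; synthetic matrices of 20–60 residues over the
full 36-point default grid; toy ensembles of up to 20 residues and 10
frames. The algorithms themselves are polynomial in residue count (the
clique enumeration is exponential in $k$ only) and handle
hundreds of residues comfortably.

## Known limitations

* The bundled parameter set is simplified; absolute energies differ from
  MD-grade force fields, so cutoff positions of real proteins' transitions
  will shift with the parameter source.
* No mmCIF or trajectory (XTC/DCD) input; structures come as PDB files and
  precomputed matrices as TSV.
* Clique percolation is exact and enumerative; for very dense graphs at
  permissive cutoffs the $k$-clique count grows combinatorially.
* The comparison report quantifies profiles (peaks, transition brackets,
  high-energy totals, difference series) but deliberately attaches no
  thermostability verdicts; interpreting profile differences remains the
  user's task.
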