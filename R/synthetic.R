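#' Specify a synthetic energy matrix
#'
#' Synthetic matrices emulate the empirical shape of real PEN energy
#' landscapes: a Lennard-Jones-dominated mode of many weak contacts at low
#' negative energies (around -5 kJ/mol) and a sparser electrostatics-
#' dominated mode at high negative energies (beyond about -20 kJ/mol),
#' plus optional planted cliques whose internal pair energies are forced
#' to a target value so recovery can be asserted exactly. A fraction of
#' residue pairs is non-interacting (zero energy). Seeds are mandatory:
#' generation never consumes global randomness silently.
#'
#' @param n_residues number of residues (>= 2).
#' @param seed integer RNG seed.
#' @param lj_mode_mean,lj_mode_sd mean/sd of the LJ mode, kJ/mol.
#' @param elec_mode_mean,elec_mode_sd mean/sd of the electrostatic mode,
#'   kJ/mol.
#' @param elec_pair_fraction fraction of interacting pairs that receive an
#'   additional Coulomb-channel draw. The default is small: strong
#'   electrostatic contacts (salt bridges) number on the order of the
#'   residue count in real proteins, a vanishing fraction of all residue
#'   pairs, which keeps the high-energy subgraph sparse.
#' @param planted_cliques list of `list(nodes = <integer vector>,
#'   energy = <kJ/mol>)` entries.
#' @param background_fraction fraction of non-interacting (zero) pairs.
#' @return an object of class `pen_synth_spec`.
#' @export
synthetic_spec <- function(n_residues, seed,
                           lj_mode_mean = -5, lj_mode_sd = 1.5,
                           elec_mode_mean = -27, elec_mode_sd = 2,
                           elec_pair_fraction = 0.02,
                           planted_cliques = list(),
                           background_fraction = 0.5) {
  stopifnot(n_residues >= 2, !missing(seed))
  if (elec_pair_fraction < 0 || elec_pair_fraction > 1 ||
      background_fraction < 0 || background_fraction > 1) {
    abort("fractions must lie in [0, 1]")
  }
  if (lj_mode_sd < 0 || elec_mode_sd < 0) abort("mode sds must be >= 0")
  for (pc in planted_cliques) {
    if (!all(c("nodes", "energy") %in% names(pc))) {
      abort("each planted clique needs `nodes` and `energy`")
    }
    if (any(pc$nodes < 1 | pc$nodes > n_residues)) {
      abort("planted clique node out of range")
    }
  }
  structure(
    list(n_residues = as.integer(n_residues), seed = as.integer(seed),
         lj_mode_mean = lj_mode_mean, lj_mode_sd = lj_mode_sd,
         elec_mode_mean = elec_mode_mean, elec_mode_sd = elec_mode_sd,
         elec_pair_fraction = elec_pair_fraction,
         planted_cliques = planted_cliques,
         background_fraction = background_fraction),
    class = "pen_synth_spec"
  )
}

# run code under a local seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic energy matrix
#'
#' Deterministic given the spec's seed. Interacting pairs draw their LJ
#' channel from the LJ mode; an `elec_pair_fraction` of them additionally
#' draw a Coulomb-channel energy from the electrostatic mode. Planted
#' cliques have every internal pair's total energy forced to the target
#' (the LJ channel absorbs the adjustment). `total = lj + coulomb`
#' everywhere and all channels are symmetric.
#'
#' @param spec a [synthetic_spec()].
#' @return an [energy_matrix()] with all three channels.
#' @export
generate_synthetic_matrix <- function(spec) {
  stopifnot(inherits(spec, "pen_synth_spec"))
  n <- spec$n_residues
  res <- residue_table(chain = "A", seq_number = seq_len(n),
                       insertion_code = NA_character_,
                       name = rep("UNK", n))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(ut)
  .with_seed(spec$seed, {
    interacting <- stats::runif(np) >= spec$background_fraction
    lj_v <- ifelse(interacting,
                   stats::rnorm(np, spec$lj_mode_mean, spec$lj_mode_sd), 0)
    elec <- interacting & (stats::runif(np) < spec$elec_pair_fraction)
    cl_v <- ifelse(elec,
                   stats::rnorm(np, spec$elec_mode_mean, spec$elec_mode_sd), 0)
    lj <- matrix(0, n, n)
    cl <- matrix(0, n, n)
    lj[ut] <- lj_v; lj[ut[, c(2, 1)]] <- lj_v
    cl[ut] <- cl_v; cl[ut[, c(2, 1)]] <- cl_v
    for (pc in spec$planted_cliques) {
      nodes <- sort(unique(as.integer(pc$nodes)))
      for (a in seq_along(nodes)[-1]) {
        for (b in seq_len(a - 1)) {
          i <- nodes[b]; j <- nodes[a]
          lj[i, j] <- lj[j, i] <- pc$energy - cl[i, j]
        }
      }
    }
    energy_matrix(res, lj = lj, coulomb = cl)
  })
}

#' Generate a toy peptide structure ensemble
#'
#' Builds a poly-alanine chain laid out on an ideal helical curve (CA
#' radius 0.23 nm, rise 0.15 nm and 100 degrees of turn per residue, the
#' geometry of an alpha-helix), with backbone N, H, C, O and a CB placed
#' at fixed local offsets. Each frame perturbs every atom with isotropic
#' Gaussian jitter of the given standard deviation, emulating thermal
#' fluctuation in an MD ensemble. All atom names are covered by the
#' bundled parameter table. Deterministic given the seed.
#'
#' @param n_residues chain length (>= 2).
#' @param n_frames number of frames (>= 1).
#' @param jitter_sd per-coordinate Gaussian jitter, nm.
#' @param seed integer RNG seed.
#' @return a `structure_ensemble`.
#' @export
generate_toy_ensemble <- function(n_residues, n_frames = 1, jitter_sd = 0.01,
                                  seed = 1) {
  if (n_residues < 2) abort("n_residues must be at least 2")
  if (n_frames < 1) abort("n_frames must be at least 1")
  if (jitter_sd < 0) abort("jitter_sd must be >= 0")
  res <- residue_table(chain = "A", seq_number = seq_len(n_residues),
                       insertion_code = NA_character_,
                       name = rep("ALA", n_residues))
  atom_names <- c("N", "H", "CA", "CB", "C", "O")
  elements <- c("N", "H", "C", "C", "C", "O")
  theta <- (seq_len(n_residues) - 1) * 100 * pi / 180
  ca <- cbind(0.23 * cos(theta), 0.23 * sin(theta),
              (seq_len(n_residues) - 1) * 0.15)
  # local axes per residue: radial (outward), tangential, axial
  radial <- cbind(cos(theta), sin(theta), 0)
  tangent <- cbind(-sin(theta), cos(theta), 0)
  axial <- matrix(rep(c(0, 0, 1), each = n_residues), ncol = 3)
  base <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    rbind(
      ca[i, ] - 0.10 * tangent[i, ] - 0.10 * axial[i, ],   # N
      ca[i, ] - 0.10 * tangent[i, ] - 0.19 * axial[i, ],   # H (on N)
      ca[i, ],                                             # CA
      ca[i, ] + 0.153 * radial[i, ],                       # CB
      ca[i, ] + 0.10 * tangent[i, ] + 0.10 * axial[i, ],   # C
      ca[i, ] + 0.21 * radial[i, ] + 0.12 * axial[i, ]     # O
    )
  }))
  atoms <- tibble(
    residue_index = rep(seq_len(n_residues), each = length(atom_names)),
    name = rep(atom_names, n_residues),
    element = rep(elements, n_residues)
  )
  frames <- .with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      base + matrix(stats::rnorm(length(base), 0, jitter_sd), ncol = 3)
    })
  })
  structure(list(residues = res, atoms = atoms, frames = frames),
            class = "structure_ensemble")
}
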