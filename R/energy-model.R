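#' Pairwise non-bonded energy terms
#'
#' `lj_pair()` evaluates the 12-6 Lennard-Jones potential
#' 4 eps \[ (sigma/r)^12 - (sigma/r)^6 \] for one atom pair, with sigma and
#' epsilon obtained from the per-atom parameters through a combining rule:
#' Lorentz-Berthelot uses sigma = (sigma_i + sigma_j)/2 and
#' eps = sqrt(eps_i eps_j); geometric takes the geometric mean of both.
#' `coulomb_pair()` evaluates k q_i q_j / (eps_r r). All distances are nm,
#' charges elementary charges, energies kJ/mol. Both are vectorized over `r`.
#'
#' @param r interatomic distance(s), nm; must be > 0.
#' @param sigma_i,sigma_j per-atom LJ diameters, nm.
#' @param epsilon_i,epsilon_j per-atom LJ well depths, kJ/mol.
#' @param rule combining rule, `"lorentz-berthelot"` or `"geometric"`.
#' @return energy (or energies) in kJ/mol.
#' @export
lj_pair <- function(r, sigma_i, epsilon_i, sigma_j, epsilon_j,
                    rule = c("lorentz-berthelot", "geometric")) {
  rule <- match.arg(rule)
  if (any(r <= 0)) abort("distance r must be positive")
  sigma <- if (rule == "lorentz-berthelot") (sigma_i + sigma_j) / 2 else sqrt(sigma_i * sigma_j)
  eps <- sqrt(epsilon_i * epsilon_j)
  sr6 <- (sigma / r)^6
  4 * eps * (sr6 * sr6 - sr6)
}

#' @rdname lj_pair
#' @param q_i,q_j partial charges, elementary charges.
#' @param params a `pen_forcefield` supplying `coulomb_constant` and
#'   `relative_dielectric`.
#' @export
coulomb_pair <- function(r, q_i, q_j, params = default_forcefield()) {
  if (any(r <= 0)) abort("distance r must be positive")
  params$coulomb_constant * q_i * q_j / (params$relative_dielectric * r)
}

#' Interaction energy between two residues in one frame
#'
#' Sums [lj_pair()] and [coulomb_pair()] over every atom pair (a in residue
#' i, b in residue j) whose distance does not exceed the force field's
#' `distance_cutoff` (all pairs when the cutoff is `NULL`). Atoms absent
#' from the parameter table contribute zero energy.
#'
#' @param ensemble a `structure_ensemble`.
#' @param i,j distinct residue indices (1-based, `residues$index`).
#' @param frame frame number, 1-based.
#' @param params a `pen_forcefield`.
#' @return named numeric: `lj` and `coulomb` (kJ/mol).
#' @export
residue_pair_energy <- function(ensemble, i, j, frame = 1,
                                params = default_forcefield()) {
  if (i == j) abort("i and j must be distinct residues")
  ap <- .assign_atom_params(ensemble, params)
  .pair_energy_core(ensemble$frames[[frame]],
                    which(ensemble$atoms$residue_index == i),
                    which(ensemble$atoms$residue_index == j),
                    ap, params)
}

.pair_energy_core <- function(xyz, ai, aj, ap, params) {
  di <- xyz[ai, , drop = FALSE]
  dj <- xyz[aj, , drop = FALSE]
  # squared distance matrix |a - b|^2 = |a|^2 + |b|^2 - 2 a.b
  r2 <- outer(rowSums(di^2), rowSums(dj^2), `+`) - 2 * tcrossprod(di, dj)
  r <- sqrt(pmax(r2, 0))
  if (any(r <= 0)) abort("coincident atoms: zero interatomic distance")
  within <- if (is.null(params$distance_cutoff)) TRUE else r <= params$distance_cutoff
  if (params$combining_rule == "lorentz-berthelot") {
    sigma <- outer(ap$sigma[ai], ap$sigma[aj], `+`) / 2
  } else {
    sigma <- sqrt(outer(ap$sigma[ai], ap$sigma[aj]))
  }
  eps <- sqrt(outer(ap$eps[ai], ap$eps[aj]))
  sr6 <- (sigma / r)^6
  ljm <- 4 * eps * (sr6 * sr6 - sr6)
  cm <- params$coulomb_constant * outer(ap$q[ai], ap$q[aj]) /
    (params$relative_dielectric * r)
  c(lj = sum(ljm * within), coulomb = sum(cm * within))
}

#' Ensemble-averaged residue-pair energy matrix
#'
#' For every included unordered residue pair, computes the Lennard-Jones
#' and Coulomb interaction energies in each frame and averages them over
#' the ensemble; the total channel is their sum. This is the edge-weight
#' matrix of the protein energy network. By default, sequence-adjacent
#' residue pairs in the same chain are excluded (zero in all channels and
#' flagged), since those pairs are dominated by through-bond geometry and
#' would tie the backbone into a trivially connected chain at any cutoff.
#'
#' @param ensemble a `structure_ensemble` with at least one frame.
#' @param params a `pen_forcefield`.
#' @param exclude_adjacent exclude sequence-adjacent same-chain pairs?
#' @return an [energy_matrix()] with `lj`, `coulomb`, `total` and the
#'   exclusion mask.
#' @export
compute_energy_matrix <- function(ensemble, params = default_forcefield(),
                                  exclude_adjacent = TRUE) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (length(ensemble$frames) < 1) abort("ensemble must have at least one frame")
  res <- ensemble$residues
  n <- nrow(res)
  ap <- .assign_atom_params(ensemble, params)
  if (ap$n_missing > 0) {
    warn(sprintf("%d atom(s) lack force-field parameters and contribute zero energy",
                 ap$n_missing))
  }
  atom_idx <- split(seq_len(nrow(ensemble$atoms)), ensemble$atoms$residue_index)

  excl <- matrix(FALSE, n, n)
  if (exclude_adjacent && n > 1) {
    adj <- which(res$chain[-n] == res$chain[-1])
    excl[cbind(adj, adj + 1L)] <- TRUE
    excl <- excl | t(excl)
  }

  lj <- matrix(0, n, n)
  cl <- matrix(0, n, n)
  nf <- length(ensemble$frames)
  for (i in seq_len(n - 1)) {
    ai <- atom_idx[[as.character(i)]]
    for (j in seq.int(i + 1, n)) {
      if (excl[i, j]) next
      aj <- atom_idx[[as.character(j)]]
      acc <- c(lj = 0, coulomb = 0)
      for (f in seq_len(nf)) {
        acc <- acc + .pair_energy_core(ensemble$frames[[f]], ai, aj, ap, params)
      }
      acc <- acc / nf
      lj[i, j] <- lj[j, i] <- acc[["lj"]]
      cl[i, j] <- cl[j, i] <- acc[["coulomb"]]
    }
  }
  energy_matrix(res, lj = lj, coulomb = cl, excluded = excl)
}
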