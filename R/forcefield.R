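#' Non-bonded force-field parameters
#'
#' The package ships a self-contained, simplified per-atom parameter table
#' (partial charge in elementary charges, Lennard-Jones sigma in nm and
#' epsilon in kJ/mol) covering heavy atoms and polar hydrogens of the 20
#' standard amino acids, in a united-atom style where aliphatic hydrogens
#' are folded into their carbons. Users may substitute any table with the
#' same columns via [read_forcefield()].
#'
#' @param combining_rule `"lorentz-berthelot"` (arithmetic sigma, geometric
#'   epsilon) or `"geometric"` (geometric both).
#' @param coulomb_constant electric conversion factor, kJ mol^-1 nm e^-2.
#' @param relative_dielectric dimensionless relative permittivity (>= 1).
#' @param distance_cutoff atom-pair distance cutoff in nm, or `NULL` for
#'   no cutoff (all atom pairs are summed; matrices here are small enough
#'   that exactness beats speed).
#' @return an object of class `pen_forcefield`.
#' @export
default_forcefield <- function(combining_rule = c("lorentz-berthelot", "geometric"),
                               coulomb_constant = 138.935485,
                               relative_dielectric = 1,
                               distance_cutoff = NULL) {
  read_forcefield(
    system.file("extdata", "nonbonded_params.tsv", package = "pennet",
                mustWork = TRUE),
    combining_rule = combining_rule,
    coulomb_constant = coulomb_constant,
    relative_dielectric = relative_dielectric,
    distance_cutoff = distance_cutoff
  )
}

#' @rdname default_forcefield
#' @param path TSV file with columns `residue_name`, `atom_name`,
#'   `charge_e`, `sigma_nm`, `epsilon_kJmol`.
#' @export
read_forcefield <- function(path,
                            combining_rule = c("lorentz-berthelot", "geometric"),
                            coulomb_constant = 138.935485,
                            relative_dielectric = 1,
                            distance_cutoff = NULL) {
  combining_rule <- match.arg(combining_rule)
  tb <- as_tibble(utils::read.delim(path))
  need <- c("residue_name", "atom_name", "charge_e", "sigma_nm", "epsilon_kJmol")
  if (!all(need %in% names(tb))) {
    abort(sprintf("parameter table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(tb$epsilon_kJmol < 0) || any(tb$sigma_nm <= 0)) {
    abort("parameter table requires epsilon >= 0 and sigma > 0")
  }
  if (coulomb_constant <= 0) abort("coulomb_constant must be positive")
  if (relative_dielectric < 1) abort("relative_dielectric must be >= 1")
  structure(
    list(atom_params = tb,
         combining_rule = combining_rule,
         coulomb_constant = coulomb_constant,
         relative_dielectric = relative_dielectric,
         distance_cutoff = distance_cutoff),
    class = "pen_forcefield"
  )
}

#' @export
print.pen_forcefield <- function(x, ...) {
  cat(sprintf(
    "<pen_forcefield> %d atom types (%d residues), %s combining, eps_r = %g, cutoff = %s\n",
    nrow(x$atom_params), length(unique(x$atom_params$residue_name)),
    x$combining_rule, x$relative_dielectric,
    if (is.null(x$distance_cutoff)) "none" else paste0(x$distance_cutoff, " nm")))
  invisible(x)
}

# Match ensemble atoms against the parameter table. Unparameterized atoms
# get zero charge and epsilon (so they contribute no energy) and are
# counted; protonation-variant residue names map to their parent residue.
.assign_atom_params <- function(ensemble, params) {
  tb <- params$atom_params
  resname <- .normalize_residue_name(ensemble$residues$name[ensemble$atoms$residue_index])
  key <- paste(resname, ensemble$atoms$name)
  idx <- match(key, paste(tb$residue_name, tb$atom_name))
  miss <- is.na(idx)
  list(
    q = ifelse(miss, 0, tb$charge_e[idx]),
    sigma = ifelse(miss, 0.1, tb$sigma_nm[idx]),
    eps = ifelse(miss, 0, tb$epsilon_kJmol[idx]),
    n_missing = sum(miss)
  )
}
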