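# hand-built two-residue ensemble over atoms with known parameters
make_two_residue_ensemble <- function(coords_i, coords_j, names_i, names_j,
                                      resnames = c("ALA", "ALA")) {
  res <- residue_table(chain = "A", seq_number = 1:2,
                       insertion_code = NA_character_, name = resnames)
  atoms <- tibble::tibble(
    residue_index = c(rep(1L, nrow(coords_i)), rep(2L, nrow(coords_j))),
    name = c(names_i, names_j),
    element = substr(c(names_i, names_j), 1, 1)
  )
  structure(list(residues = res, atoms = atoms,
                 frames = list(rbind(coords_i, coords_j))),
            class = "structure_ensemble")
}

test_that("lj_pair matches the 12-6 closed form", {
  s <- 0.33; e <- 0.8
  expect_equal(lj_pair(s, s, e, s, e), 0, tolerance = 1e-12)
  expect_equal(lj_pair(2^(1/6) * s, s, e, s, e), -e, tolerance = 1e-12)
  expect_lt(abs(lj_pair(10 * s, s, e, s, e)), 1e-4 * e)
  # combining rules for unlike atoms
  expect_equal(lj_pair(0.5, 0.3, 1, 0.4, 4),
               4 * 2 * ((0.35 / 0.5)^12 - (0.35 / 0.5)^6), tolerance = 1e-12)
  expect_equal(lj_pair(0.5, 0.3, 1, 0.4, 4, rule = "geometric"),
               4 * 2 * ((sqrt(0.12) / 0.5)^12 - (sqrt(0.12) / 0.5)^6),
               tolerance = 1e-12)
  expect_error(lj_pair(0, s, e, s, e), "positive")
  expect_error(lj_pair(-1, s, e, s, e), "positive")
})

test_that("coulomb_pair matches the screened Coulomb closed form", {
  ff <- default_forcefield()
  expect_equal(coulomb_pair(1, 1, 1, ff), 138.935485)
  expect_equal(coulomb_pair(0.7, 0, 1, ff), 0)
  expect_equal(coulomb_pair(0.5, 1, -1, ff), -277.87097)
  ff80 <- default_forcefield(relative_dielectric = 80)
  expect_equal(coulomb_pair(1, 1, 1, ff80), 138.935485 / 80)
  expect_error(coulomb_pair(0, 1, 1, ff), "positive")
})

test_that("residue_pair_energy equals a brute-force double loop over atom pairs", {
  ff <- default_forcefield()
  set.seed(42)
  ci <- matrix(stats::runif(9, 0, 0.5), 3)            # 3-atom residue
  cj <- matrix(stats::runif(6, 0.8, 1.3), 2)          # 2-atom residue
  ni <- c("N", "CA", "CB")
  nj <- c("C", "O")
  ens <- make_two_residue_ensemble(ci, cj, ni, nj)
  got <- residue_pair_energy(ens, 1, 2, params = ff)

  tab <- ff$atom_params
  p <- function(nm) tab[tab$residue_name == "ALA" & tab$atom_name == nm, ]
  lj_acc <- 0; cl_acc <- 0
  for (a in 1:3) {
    for (b in 1:2) {
      r <- sqrt(sum((ci[a, ] - cj[b, ])^2))
      pa <- p(ni[a]); pb <- p(nj[b])
      sig <- (pa$sigma_nm + pb$sigma_nm) / 2
      eps <- sqrt(pa$epsilon_kJmol * pb$epsilon_kJmol)
      lj_acc <- lj_acc + 4 * eps * ((sig / r)^12 - (sig / r)^6)
      cl_acc <- cl_acc + 138.935485 * pa$charge_e * pb$charge_e / r
    }
  }
  expect_equal(unname(got["lj"]), lj_acc, tolerance = 1e-12)
  expect_equal(unname(got["coulomb"]), cl_acc, tolerance = 1e-12)
  expect_equal(residue_pair_energy(ens, 2, 1, params = ff), got[c("lj", "coulomb")],
               tolerance = 1e-12)
  expect_error(residue_pair_energy(ens, 1, 1, params = ff), "distinct")
})

test_that("distance cutoff drops far atom pairs from the sums", {
  ci <- matrix(c(0, 0, 0), 1)
  cj <- rbind(c(0.5, 0, 0), c(2, 0, 0))
  ens <- make_two_residue_ensemble(ci, cj, "N", c("N", "N"))
  ff_all <- default_forcefield()
  ff_cut <- default_forcefield(distance_cutoff = 1)
  full <- residue_pair_energy(ens, 1, 2, params = ff_all)
  near <- residue_pair_energy(ens, 1, 2, params = ff_cut)
  q <- ff_all$atom_params$charge_e[
    ff_all$atom_params$residue_name == "ALA" & ff_all$atom_params$atom_name == "N"]
  expect_equal(unname(full["coulomb"] - near["coulomb"]),
               138.935485 * q * q / 2, tolerance = 1e-12)
})

test_that("ensemble averaging: matrix equals the mean of per-frame matrices", {
  ens <- generate_toy_ensemble(6, n_frames = 4, jitter_sd = 0.01, seed = 13)
  m <- compute_energy_matrix(ens)
  singles <- lapply(1:4, function(f) {
    one <- ens; one$frames <- ens$frames[f]
    compute_energy_matrix(one)
  })
  avg <- Reduce(`+`, lapply(singles, `[[`, "total")) / 4
  expect_lt(max(abs(m$total - avg)), 1e-9)
  # mean of one frame is the single-frame result
  one <- ens; one$frames <- ens$frames[1]
  expect_equal(compute_energy_matrix(one)$total, singles[[1]]$total)
})

test_that("energy matrix contracts: decomposition, symmetry, exclusions", {
  ens <- generate_toy_ensemble(8, n_frames = 2, jitter_sd = 0.005, seed = 3)
  m <- compute_energy_matrix(ens)
  expect_equal(m$total, m$lj + m$coulomb, tolerance = 1e-15)
  expect_equal(m$total, t(m$total))
  expect_equal(diag(m$total), setNames(rep(0, 8), m$residues$label))
  # sequence-adjacent pairs are excluded: zero energy, flagged, never edges
  for (i in 1:7) {
    expect_true(m$excluded[i, i + 1])
    expect_equal(m$total[i, i + 1], 0)
  }
  g0 <- threshold_pen(build_pen(m), 0)
  expect_false(any(g0$adjacency[cbind(1:7, 2:8)]))
  m_incl <- compute_energy_matrix(ens, exclude_adjacent = FALSE)
  expect_false(any(m_incl$excluded))
  expect_true(any(m_incl$total[cbind(1:7, 2:8)] != 0))
})

test_that("frame order does not change the averaged matrix", {
  ens <- generate_toy_ensemble(6, n_frames = 5, jitter_sd = 0.02, seed = 8)
  m <- compute_energy_matrix(ens)
  perm <- ens; perm$frames <- ens$frames[c(4, 1, 5, 2, 3)]
  expect_equal(compute_energy_matrix(perm)$total, m$total, tolerance = 1e-12)
})

test_that("rigid motions of every frame leave the matrix unchanged", {
  ens <- generate_toy_ensemble(6, n_frames = 3, jitter_sd = 0.01, seed = 17)
  m <- compute_energy_matrix(ens)
  set.seed(99)
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  rot <- qr.Q(qr_d)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- c(1.5, -2.2, 0.7)
  moved <- ens
  moved$frames <- lapply(ens$frames, function(f) {
    sweep(f %*% rot, 2, shift, `+`)
  })
  m2 <- compute_energy_matrix(moved)
  expect_lt(max(abs(m$total - m2$total)), 1e-9)
  expect_lt(max(abs(m$lj - m2$lj)), 1e-9)
})

test_that("scaling all charges by c scales coulomb by c^2 and leaves lj alone", {
  ens <- generate_toy_ensemble(6, n_frames = 2, jitter_sd = 0.01, seed = 4)
  base <- compute_energy_matrix(ens)
  tab <- default_forcefield()$atom_params
  tab$charge_e <- tab$charge_e * 2
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  scaled <- compute_energy_matrix(ens, read_forcefield(path))
  expect_equal(scaled$coulomb, 4 * base$coulomb, tolerance = 1e-9)
  expect_equal(scaled$lj, base$lj, tolerance = 1e-12)
})

test_that("unparameterized atoms contribute zero energy with a warning", {
  ens <- generate_toy_ensemble(4, n_frames = 1, seed = 1)
  ens$atoms$name[ens$atoms$name == "CB"] <- "XX"
  expect_warning(m <- compute_energy_matrix(ens), "lack force-field parameters")
  stripped <- generate_toy_ensemble(4, n_frames = 1, seed = 1)
  keep <- stripped$atoms$name != "CB"
  stripped$atoms <- stripped$atoms[keep, ]
  stripped$frames <- lapply(stripped$frames, function(f) f[keep, , drop = FALSE])
  m2 <- compute_energy_matrix(stripped)
  expect_equal(m$total, m2$total, tolerance = 1e-12)
})
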