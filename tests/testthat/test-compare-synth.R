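test_that("synthetic matrices are deterministic and honor their spec", {
  spec <- synthetic_spec(25, seed = 6,
                         planted_cliques = list(list(nodes = c(3, 7, 11, 19),
                                                     energy = -30)))
  m1 <- generate_synthetic_matrix(spec)
  m2 <- generate_synthetic_matrix(spec)
  expect_identical(m1$total, m2$total)
  expect_identical(m1$lj, m2$lj)
  expect_identical(m1$coulomb, m2$coulomb)
  expect_equal(m1$total, m1$lj + m1$coulomb, tolerance = 1e-15)
  expect_equal(m1$total, t(m1$total))

  # planted 4-clique recovered by enumeration at the target cutoff
  g <- threshold_pen(build_pen(m1), -30)
  cliques <- enumerate_k_cliques(g, 4)
  expect_true(any(vapply(cliques, function(v) {
    identical(as.integer(v), c(3L, 7L, 11L, 19L))
  }, TRUE)))

  no_elec <- generate_synthetic_matrix(
    synthetic_spec(25, seed = 6, elec_pair_fraction = 0))
  expect_true(all(no_elec$coulomb == 0))
  expect_error(synthetic_spec(10, seed = 1,
                              planted_cliques = list(list(nodes = c(1, 99),
                                                          energy = -5))),
               "out of range")
  expect_error(synthetic_spec(10, seed = 1, background_fraction = 1.4),
               "\\[0, 1\\]")
})

test_that("generator RNG is local: global seed state is untouched", {
  set.seed(123)
  expected <- stats::runif(3)
  set.seed(123)
  invisible(generate_synthetic_matrix(synthetic_spec(10, seed = 99)))
  expect_identical(stats::runif(3), expected)
})

test_that("a denser electrostatic mode yields more high-energy cliques", {
  with_elec <- synthetic_spec(60, seed = 31, elec_pair_fraction = 0.15)
  without <- synthetic_spec(60, seed = 31, elec_pair_fraction = 0)
  s_with <- sweep_profile(build_pen(generate_synthetic_matrix(with_elec)),
                          "cliques", k = 3)
  s_without <- sweep_profile(build_pen(generate_synthetic_matrix(without)),
                             "cliques", k = 3)
  he <- s_with$e < -20
  expect_gt(sum(s_with$value[he]), sum(s_without$value[he]))
})

test_that("self-comparison gives all-zero differences; swapping negates them", {
  p <- build_pen(generate_synthetic_matrix(synthetic_spec(30, seed = 2)))
  profs_a <- list(sweep_profile(p, "lcc"), sweep_profile(p, "clusters"))
  q <- build_pen(generate_synthetic_matrix(synthetic_spec(30, seed = 3)))
  profs_b <- list(sweep_profile(q, "lcc"), sweep_profile(q, "clusters"))

  self <- compare_pair(profs_a, profs_a)
  expect_true(all(self$differences$diff == 0))
  expect_true(all(self$summary$difference == 0))

  ab <- compare_pair(profs_a, profs_b)
  ba <- compare_pair(profs_b, profs_a)
  expect_identical(ab$differences$diff, -ba$differences$diff)
})

test_that("comparison summaries match independent recomputation", {
  a <- build_pen(generate_synthetic_matrix(
    synthetic_spec(40, seed = 51, elec_pair_fraction = 0.1)))
  b <- build_pen(generate_synthetic_matrix(synthetic_spec(40, seed = 52)))
  sa <- sweep_profile(a, "clusters")
  sb <- sweep_profile(b, "clusters")
  rep <- compare_pair(sa, sb, labels = c("thermo", "meso"))
  sm <- rep$summary
  pick <- function(stat) sm[sm$statistic == stat, ]
  expect_equal(pick("peak_value")$value_a, profile_peak(sa)$value_peak)
  expect_equal(pick("peak_e")$value_b, profile_peak(sb)$e_peak)
  expect_equal(pick("high_energy_total")$value_a, sum(sa$value[sa$e < -20]))
  expect_equal(pick("peak_value")$difference,
               profile_peak(sa)$value_peak - profile_peak(sb)$value_peak)
  expect_identical(rep$labels, c("thermo", "meso"))
})

test_that("peak difference records follow the spec arithmetic", {
  grid <- c(0, -1, -2, -3)
  a <- pennet:::new_pen_profile(grid, c(0L, 1L, 5L, 2L), "clusters", "total")
  b <- pennet:::new_pen_profile(grid, c(1L, 3L, 2L, 0L), "clusters", "total")
  rep <- compare_pair(a, b)
  sm <- rep$summary
  expect_equal(sm$difference[sm$statistic == "peak_value"], 5 - 3)
  expect_equal(sm$difference[sm$statistic == "peak_e"], -2 - (-1))
})

test_that("mismatched grids are rejected", {
  p <- build_pen(generate_synthetic_matrix(synthetic_spec(10, seed = 1)))
  a <- sweep_profile(p, "lcc", grid = cutoff_grid(0, -10, 1))
  b <- sweep_profile(p, "lcc", grid = cutoff_grid(0, -12, 1))
  expect_error(compare_pair(a, b), "grid mismatch")
})

test_that("toy ensembles are deterministic with reproducible jitter", {
  e1 <- generate_toy_ensemble(8, n_frames = 4, jitter_sd = 0.02, seed = 9)
  e2 <- generate_toy_ensemble(8, n_frames = 4, jitter_sd = 0.02, seed = 9)
  expect_identical(e1$frames, e2$frames)
  frozen <- generate_toy_ensemble(8, n_frames = 3, jitter_sd = 0, seed = 1)
  expect_identical(frozen$frames[[1]], frozen$frames[[2]])
  m_multi <- compute_energy_matrix(frozen)
  one <- frozen; one$frames <- frozen$frames[1]
  expect_equal(m_multi$total, compute_energy_matrix(one)$total,
               tolerance = 1e-12)
  expect_error(generate_toy_ensemble(1), "at least 2")
  expect_error(generate_toy_ensemble(5, n_frames = 0), "at least 1")
})

test_that("ensemble averaging equals the mean of single-frame matrices", {
  ens <- generate_toy_ensemble(10, n_frames = 10, jitter_sd = 0.015, seed = 23)
  m <- compute_energy_matrix(ens)
  singles <- lapply(1:10, function(f) {
    one <- ens; one$frames <- ens$frames[f]
    compute_energy_matrix(one)$total
  })
  expect_lt(max(abs(m$total - Reduce(`+`, singles) / 10)), 1e-9)
})
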