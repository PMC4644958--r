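# diatomic helper: two atoms, one harmonic bond, no nonbonded terms
diatomic <- function(k_b = 1, r0 = 1, masses = c(1, 1)) {
  at <- rbind(toy_atom(1L, "A", "H", epsilon = 0, charge = 0),
              toy_atom(2L, "B", "H", epsilon = 0, charge = 0))
  at$mass <- masses
  list(topology = topology(at, bonds = data.frame(i = 1L, j = 2L, k_b = k_b, r0 = r0)),
       frame = rbind(c(0, 0, 0), c(r0, 0, 0)))
}

test_that("force-field gradient matches numerical differentiation", {
  sys <- hg_system()
  set.seed(9)
  fr <- sys$frame + matrix(rnorm(length(sys$frame), sd = 0.05), ncol = 3)
  g <- ff_energy(fr, sys$topology, gradient = TRUE)$gradient
  h <- 1e-6
  for (probe in list(c(1, 1), c(5, 2), c(14, 3))) {
    fp <- fr; fp[probe[1], probe[2]] <- fp[probe[1], probe[2]] + h
    fm <- fr; fm[probe[1], probe[2]] <- fm[probe[1], probe[2]] - h
    num <- (ff_energy(fp, sys$topology)$energy - ff_energy(fm, sys$topology)$energy) / (2 * h)
    expect_equal(g[probe[1], probe[2]], num, tolerance = 1e-5)
  }
})

test_that("Hessian: free atom is zero, diatomic reduces to 2 k_b, symmetric", {
  one <- topology(toy_atom(1L, "A", "C", charge = 0))
  H1 <- hessian_matrix(matrix(0, 1, 3), one)
  expect_equal(H1, matrix(0, 3, 3), tolerance = 1e-9)

  di <- diatomic(k_b = 1)
  H <- hessian_matrix(di$frame, di$topology)
  # 1D force constant along the bond axis is the second derivative of
  # k_b (r - r0)^2, i.e. 2 k_b
  expect_equal(H[1, 1], 2, tolerance = 1e-6)
  expect_equal(H[1, 4], -2, tolerance = 1e-6)
  expect_lt(max(abs(H - t(H))), 1e-6)
})

test_that("diatomic normal mode matches sqrt(2k/mu) and scaling laws", {
  # independent conversion factor from physical constants
  conv <- sqrt((4184 / 6.02214076e23) / (1e-20 * 1.66053906892e-27)) /
    (2 * pi * 2.99792458e10)
  di <- diatomic(k_b = 1, masses = c(1, 1))
  H <- hessian_matrix(di$frame, di$topology)
  nm <- normal_modes(H, c(1, 1))
  expect_length(nm$frequencies, 1L)
  expect_equal(nm$n_zero_removed, 5L)   # linear molecule: 3 trans + 2 rot
  expect_equal(nm$frequencies, conv * sqrt(2 * 1 / 0.5), tolerance = 1e-5)

  nm2 <- normal_modes(H, c(2, 2))       # doubling masses: omega / sqrt(2)
  expect_equal(nm2$frequencies, nm$frequencies / sqrt(2), tolerance = 1e-9)

  free <- normal_modes(hessian_matrix(matrix(0, 1, 3),
                                      topology(toy_atom(1L, "A", "C", charge = 0))),
                       12.0)
  expect_length(free$frequencies, 0L)

  # entropy term is invariant under atom reordering of the spectrum inputs
  sys <- hg_system()
  lig <- subset_topology(sys$topology, sys$partition$ligand)
  mz <- minimize_energy(sys$frame[sys$partition$ligand, ], lig)
  Hl <- hessian_matrix(mz$frame, lig)
  sp <- normal_modes(Hl, lig$atoms$mass)
  perm <- c(3, 1, 5, 2, 4)
  P <- matrix(0, 5, 5); P[cbind(seq_len(5), perm)] <- 1
  Px <- kronecker(P, diag(3))
  sp_perm <- normal_modes(Px %*% Hl %*% t(Px), lig$atoms$mass[perm])
  expect_equal(sp_perm$frequencies, sp$frequencies, tolerance = 1e-6)
})

test_that("vibrational entropy has the harmonic-oscillator closed form and limits", {
  R <- 1.9872041e-3
  # one mode with h c nu / kB T = 1
  Tx <- 1.4387768775 * 100
  s <- species_entropy(100, mass_total = 10, inertia = c(0, 1, 1),
                       temperature = Tx)
  expect_equal(s$s_vib, R * (1 / (exp(1) - 1) - log(1 - exp(-1))), tolerance = 1e-9)

  # T -> 0 limit: S_vib -> 0; monotone increasing in T, decreasing in frequency
  s_cold <- species_entropy(100, 10, c(0, 1, 1), temperature = 1e-3)
  expect_equal(s_cold$s_vib, 0, tolerance = 1e-12)
  temps <- c(50, 150, 300, 600)
  sv <- vapply(temps, function(T) species_entropy(100, 10, c(0, 1, 1), T)$s_vib,
               numeric(1))
  expect_true(all(diff(sv) > 0))
  freqs <- c(50, 100, 400, 1600)
  sf <- vapply(freqs, function(f) species_entropy(f, 10, c(0, 1, 1), 300)$s_vib,
               numeric(1))
  expect_true(all(diff(sf) < 0))

  expect_error(species_entropy(c(100, 0), 10, c(0, 1, 1)), "domain error")
})

test_that("binding entropy term vanishes for identical spectra and is positive for the toy complex", {
  s <- species_entropy(c(100, 200), 10, c(1, 2, 3), 300)
  expect_equal(binding_entropy_term(s, s, list(s_total = 0), 300), 0)

  sys <- hg_system()
  both <- sort(c(sys$partition$receptor, sys$partition$ligand))
  sc <- nma_entropy(sys$frame[both, ], subset_topology(sys$topology, both))
  sr <- nma_entropy(sys$frame[sys$partition$receptor, ],
                    subset_topology(sys$topology, sys$partition$receptor))
  sl <- nma_entropy(sys$frame[sys$partition$ligand, ],
                    subset_topology(sys$topology, sys$partition$ligand))
  mtds <- binding_entropy_term(sc, sr, sl, 300)
  # binding restricts motion: -T dS > 0
  expect_gt(mtds, 0)
  expect_equal(sc$spectrum$n_zero_removed, 6L)
})

test_that("minimizer reaches the gradient tolerance on the toy systems", {
  sys <- hg_system()
  mz <- minimize_energy(sys$frame, sys$topology, tol = 1e-6)
  expect_lte(mz$grad_max, 1e-6)
  # bonded-only species relaxes to its exact built minimum
  lig <- subset_topology(sys$topology, sys$partition$ligand)
  ml <- minimize_energy(sys$frame[sys$partition$ligand, ], lig)
  expect_lt(abs(ml$energy), 1e-10)
})
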