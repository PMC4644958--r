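test_that("Coulomb and Lennard-Jones pair energies match their closed forms", {
  expect_equal(coulomb_pair(0, 1, 3), 0)
  expect_equal(coulomb_pair(1, 1, 3.320637, dielectric = 1), 100.0, tolerance = 1e-12)
  expect_equal(coulomb_pair(1, -1, 3.320637), -100.0, tolerance = 1e-12)
  expect_equal(coulomb_pair(1, 1, 2 * 3.320637, dielectric = 2), 25.0, tolerance = 1e-12)
  expect_error(coulomb_pair(1, 1, 0), "singular")

  a <- list(rmin_half = 1.9, epsilon = 0.1)
  b <- list(rmin_half = 1.9, epsilon = 0.1)
  expect_equal(lj_pair(a, b, 3.8), -0.1, tolerance = 1e-12)
  expect_equal(lj_pair(list(rmin_half = 1.9, epsilon = 0), b, 2.0), 0)
  # minimum at Rmin with value -eps: derivative changes sign across Rmin
  rmin <- a$rmin_half + b$rmin_half
  grid <- seq(0.8, 1.3, by = 0.01) * rmin
  vals <- vapply(grid, function(r) lj_pair(a, b, r), numeric(1))
  expect_equal(min(vals), lj_pair(a, b, rmin), tolerance = 1e-9)
  expect_true(all(vals >= -a$epsilon - 1e-12))
})

test_that("intermolecular energy sums receptor x ligand pairs only", {
  tc <- make_two_charge(charges = c(1, -1), r = 3.320637, epsilon = 0)
  e <- intermolecular_energy(tc$frame, tc$topology, tc$partition)
  expect_equal(e$e_ele, -100.0, tolerance = 1e-12)
  expect_equal(e$e_vdw, 0)

  # zero-parameter ligand: both components vanish
  tc0 <- make_two_charge(charges = c(1, 0), r = 3, epsilon = 0)
  e0 <- intermolecular_energy(tc0$frame, tc0$topology, tc0$partition)
  expect_equal(unlist(e0), c(e_ele = 0, e_vdw = 0))

  # linearity: doubling ligand charges doubles e_ele exactly
  sys <- hg_system()
  e1 <- intermolecular_energy(sys$frame, sys$topology, sys$partition)
  top2 <- sys$topology
  top2$atoms$charge[sys$partition$ligand] <- 2 * top2$atoms$charge[sys$partition$ligand]
  e2 <- intermolecular_energy(sys$frame, top2, sys$partition)
  expect_equal(e2$e_ele, 2 * e1$e_ele, tolerance = 1e-12)
  expect_equal(e2$e_vdw, e1$e_vdw)

  # overlapping atoms are a singularity error naming the pair
  fr <- tc$frame
  fr[2, ] <- fr[1, ]
  expect_error(intermolecular_energy(fr, tc$topology, tc$partition),
               "overlapping atoms")
})

test_that("effective Born radii follow the pairwise-descreening closed form", {
  at <- toy_atom(1L, "A", "N", gb_radius = 1.5, gb_screen = 0.8)
  top1 <- topology(at)
  expect_equal(unname(effective_born_radii(matrix(0, 1, 3), top1)), 1.41)

  two <- topology(rbind(at, toy_atom(2L, "B", "N", gb_radius = 1.5, gb_screen = 0.8)))
  far <- effective_born_radii(rbind(c(0, 0, 0), c(100, 0, 0)), two)
  expect_equal(unname(far), c(1.41, 1.41), tolerance = 1e-3)

  # at contact both radii exceed the isolated value, by exactly the
  # quadrature value of the descreening integral
  r <- 2.2
  near <- effective_born_radii(rbind(c(0, 0, 0), c(r, 0, 0)), two)
  expect_true(all(near > 1.41))
  H <- hct_quadrature(r, 1.41, 0.8 * 1.41)
  expect_equal(unname(near[1]), 1 / (1 / 1.41 - H), tolerance = 1e-9)

  # engulfed regime (tiny atom near a large screened neighbour)
  big <- topology(rbind(toy_atom(1L, "A", "H", gb_radius = 0.6, gb_screen = 1.0),
                        toy_atom(2L, "B", "P", gb_radius = 2.2, gb_screen = 1.0)))
  r2 <- 0.9
  rr <- effective_born_radii(rbind(c(0, 0, 0), c(r2, 0, 0)), big)
  H2 <- hct_quadrature(r2, 0.6 - 0.09, 1.0 * (2.2 - 0.09))
  expect_equal(unname(rr[1]), 1 / (1 / 0.51 - H2), tolerance = 1e-9)
})

test_that("GB polar energy reproduces the Born ion and its invariances", {
  bi <- make_born_ion(charge = 1, radius = 2.0)
  expect_equal(gb_polar(bi$frame, bi$topology), bi$energy, tolerance = 1e-6)
  expect_equal(bi$energy, -0.5 * 332.0637 * (1 - 1 / 80) / 2, tolerance = 1e-9)

  # quadratic in charge: q -> -q leaves the energy unchanged; zero charge -> 0
  bi_neg <- make_born_ion(charge = -1, radius = 2.0)
  expect_equal(gb_polar(bi_neg$frame, bi_neg$topology),
               gb_polar(bi$frame, bi$topology))
  bi0 <- make_born_ion(charge = 0)
  expect_equal(gb_polar(bi0$frame, bi0$topology), 0)

  # two-sphere system against a direct Still-formula evaluation
  tc <- make_two_charge(charges = c(1, -1), r = 3.0)
  radii <- effective_born_radii(tc$frame, tc$topology)
  fgb <- function(r, Ri, Rj) sqrt(r^2 + Ri * Rj * exp(-r^2 / (4 * Ri * Rj)))
  K <- 332.0637
  coef <- -0.5 * K * (1 - 1 / 80)
  by_hand <- coef * (1 / radii[1] + 1 / radii[2] +
                       2 * (1 * -1) / fgb(3, radii[1], radii[2]))
  expect_equal(gb_polar(tc$frame, tc$topology), unname(by_hand), tolerance = 1e-9)

  # rigid rotation + translation invariance
  sys <- hg_system()
  both <- sort(c(sys$partition$receptor, sys$partition$ligand))
  e0 <- gb_polar(sys$frame, sys$topology, both)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fr2 <- sweep(sys$frame %*% t(R), 2, c(5, -3, 2), "+")
  e1 <- gb_polar(fr2, sys$topology, both)
  expect_equal(e1, e0, tolerance = 1e-8 * abs(e0))
})

test_that("Shrake-Rupley SASA matches sphere closed forms and converges", {
  at <- toy_atom(1L, "C1", "C", rmin_half = 1.6)
  top1 <- topology(at)
  s1 <- sasa(matrix(0, 1, 3), top1)
  expect_equal(s1$total, 4 * pi * 3.0^2, tolerance = 0.005 * 4 * pi * 9)

  # far-separated atoms: additive
  two <- topology(rbind(at, toy_atom(2L, "C2", "C", rmin_half = 1.6)))
  s2 <- sasa(rbind(c(0, 0, 0), c(50, 0, 0)), two)
  expect_equal(s2$total, 2 * s1$total)
  expect_equal(sum(s2$per_atom), s2$total)

  # atom fully inside another's probe-inflated sphere contributes zero
  big_small <- topology(rbind(toy_atom(1L, "BG", "P", rmin_half = 3.0),
                              toy_atom(2L, "SM", "H", rmin_half = 0.3)))
  s3 <- sasa(rbind(c(0, 0, 0), c(0.5, 0, 0)), big_small)
  expect_equal(unname(s3$per_atom[2]), 0)

  # quadrature convergence on the 17-atom toy complex
  sys <- hg_system()
  t1 <- sasa(sys$frame, sys$topology, n_points = 960)$total
  t2 <- sasa(sys$frame, sys$topology, n_points = 1920)$total
  expect_lt(abs(t2 - t1) / t1, 0.003)
})

test_that("nonpolar term is gamma * SASA + beta with domain checks", {
  expect_equal(nonpolar_energy(0), 0)
  expect_equal(nonpolar_energy(113.0973), 0.5654865, tolerance = 1e-6)
  expect_equal(nonpolar_energy(500, gamma = 0, beta = 1.25), 1.25)
  expect_error(nonpolar_energy(-1), "domain")
})

test_that("snapshot breakdown vanishes at infinite separation and flips sign with ligand charge", {
  sys <- hg_system()
  # ligand translated far away in the same frame: every component ~ 0
  # (host and guest carry net +-2 e, so the monopole tail decays as 1/r and
  # the separation must be large for the 1e-3 kcal/mol bound)
  fr <- sys$frame
  fr[sys$partition$ligand, 1] <- fr[sys$partition$ligand, 1] + 1e7
  b <- snapshot_breakdown(fr, sys$topology, sys$partition)
  for (comp in c("e_ele", "e_vdw", "g_pol", "g_nonpol", "h")) {
    expect_lt(abs(b[[comp]]), 1e-3)
  }

  # charge-sign flip of the ligand flips e_ele, leaves e_vdw unchanged
  top2 <- sys$topology
  top2$atoms$charge[sys$partition$ligand] <- -top2$atoms$charge[sys$partition$ligand]
  b1 <- snapshot_breakdown(sys$frame, sys$topology, sys$partition)
  b2 <- snapshot_breakdown(sys$frame, top2, sys$partition)
  expect_equal(b2$e_ele, -b1$e_ele, tolerance = 1e-12)
  expect_equal(b2$e_vdw, b1$e_vdw, tolerance = 1e-12)

  # derived fields are the stated sums
  expect_equal(b1$g_ele_pol, b1$e_ele + b1$g_pol, tolerance = 1e-9)
  expect_equal(b1$g_vdw_nonpol, b1$e_vdw + b1$g_nonpol, tolerance = 1e-9)
  expect_equal(b1$h, b1$e_ele + b1$e_vdw + b1$g_pol + b1$g_nonpol, tolerance = 1e-9)
})

test_that("per-residue decomposition conserves every component", {
  sys <- hg_system()
  set.seed(42)
  for (k in 1:3) {
    fr <- sys$frame + matrix(rnorm(length(sys$frame), sd = 0.05), ncol = 3)
    b <- snapshot_breakdown(fr, sys$topology, sys$partition)
    d <- per_residue_decomposition(fr, sys$topology, sys$partition)
    expect_equal(sum(d$e_ele), b$e_ele, tolerance = 1e-6)
    expect_equal(sum(d$e_vdw), b$e_vdw, tolerance = 1e-6)
    expect_equal(sum(d$g_pol), b$g_pol, tolerance = 1e-6)
    expect_equal(sum(d$g_nonpol), b$g_nonpol, tolerance = 1e-6)
    expect_equal(sum(d$total), b$h, tolerance = 1e-6)
  }
  d0 <- per_residue_decomposition(sys$frame, sys$topology, sys$partition)
  expect_setequal(d0$label, c("ligand", "ARG60", "ARG133", "TYR134"))

  # single-residue receptor: that residue carries the full total
  tc <- make_two_charge(charges = c(0.5, -0.5), r = 3.2, epsilon = 0.05)
  bt <- snapshot_breakdown(tc$frame, tc$topology, tc$partition)
  dt <- per_residue_decomposition(tc$frame, tc$topology, tc$partition)
  expect_equal(sum(dt$total[dt$label != "ligand"]) + sum(dt$total[dt$label == "ligand"]),
               bt$h, tolerance = 1e-9)

  # two symmetric residues equidistant from a symmetric ligand contribute equally
  at <- rbind(toy_atom(1L, "A1", "N", res_name = "RES", res_seq = 1L, charge = 0.4),
              toy_atom(2L, "A2", "N", res_name = "RES", res_seq = 2L, charge = 0.4),
              toy_atom(3L, "LG", "O", res_name = "LIG", res_seq = 9L, chain = "B",
                       charge = -0.8))
  top <- topology(at)
  fr <- rbind(c(-3, 0, 0), c(3, 0, 0), c(0, 0, 0))
  ds <- per_residue_decomposition(fr, top, complex_partition(1:2, 3L))
  for (comp in c("e_ele", "e_vdw", "g_pol")) {
    expect_equal(ds[[comp]][ds$label == "RES1"], ds[[comp]][ds$label == "RES2"],
                 tolerance = 1e-9)
  }
  # the SASA point lattice is deterministic but not mirror-symmetric, so the
  # nonpolar split matches only to quadrature resolution
  expect_lt(abs(ds$g_nonpol[ds$label == "RES1"] - ds$g_nonpol[ds$label == "RES2"]),
            0.01)
})
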