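test_that("read_pdb parses single- and multi-model files and honours model_policy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  model <- function(k, drop_last = FALSE) {
    recs <- c(sprintf("MODEL     %4d", k),
      sprintf("ATOM      1  N   ALA A   1       0.%03d   0.000   0.000  1.00  0.00           N", k),
      "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
      "ATOM      3  O1  LIG B   9       3.100   0.500   0.000  1.00  0.00           O")
    if (drop_last) recs <- recs[-4]
    c(recs, "ENDMDL")
  }
  writeLines(c(model(1), "END"), f)
  tr <- read_pdb(f)
  expect_equal(n_frames(tr), 1L)
  expect_equal(n_atoms(tr$topology), 3L)
  expect_equal(tr$topology$atoms$name, c("N", "CA", "O1"))
  expect_equal(tr$topology$atoms$res_seq, c(1L, 1L, 9L))
  expect_equal(tr$topology$atoms$chain, c("A", "A", "B"))
  expect_true(all(is.na(tr$topology$atoms$charge)))

  writeLines(c(unlist(lapply(1:5, model)), "END"), f)
  tr5 <- read_pdb(f, model_policy = "all")
  expect_equal(n_frames(tr5), 5L)
  expect_equal(tr5$topology$atoms$name, tr$topology$atoms$name)
  expect_equal(tr5$frames[[3]][2, ], tr5$frames[[1]][2, ])
  tr1 <- read_pdb(f, model_policy = "first")
  expect_equal(n_frames(tr1), 1L)

  writeLines(c(model(1), model(2, drop_last = TRUE), "END"), f)
  expect_error(read_pdb(f), "inconsistent atom counts")

  writeLines(c("ATOM      1  N   ALA A   1       0.0x0   0.000   0.000  1.00  0.00           N",
               "END"), f)
  expect_error(read_pdb(f), "malformed coordinate field at line 1")
})

test_that("PDB write/read round-trips coordinates to 3 decimals", {
  sys <- hg_system()
  traj <- jitter_trajectory(sys$frame, sys$topology, n_frames = 3, sigma = 0.2,
                            seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, f)
  back <- read_pdb(f)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$topology$atoms$name, sys$topology$atoms$name)
  for (k in 1:3) {
    expect_equal(back$frames[[k]], round(traj$frames[[k]], 3),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # the written file is also readable by the independent bio3d parser
  p <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(p$xyz), 3L)
  expect_equal(matrix(p$xyz[2, ], ncol = 3, byrow = TRUE),
               round(traj$frames[[2]], 3), ignore_attr = TRUE)
})

test_that("XYZ multi-frame write/read round-trips coordinates and times", {
  sys <- hg_system()
  traj <- jitter_trajectory(sys$frame, sys$topology, n_frames = 2, sigma = 0.1,
                            seed = 5)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, f)
  back <- read_xyz(f)
  expect_equal(n_frames(back), 2L)
  expect_equal(back$times, traj$times)
  expect_equal(back$frames[[2]], traj$frames[[2]],
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("merge_topology parameterizes atoms by (res_seq, name) without reordering", {
  sys <- hg_system()
  traj0 <- trajectory(topology(sys$topology$atoms[.ncols_struct()]),
                      list(sys$frame))
  f <- withr::local_tempfile(fileext = ".json")
  write_topology(sys$topology, f)
  merged <- merge_topology(traj0, f)
  expect_equal(merged$topology$atoms$charge, sys$topology$atoms$charge)
  expect_equal(merged$topology$atoms$name, sys$topology$atoms$name)
  expect_equal(nrow(merged$topology$bonds), nrow(sys$topology$bonds))

  # sidecar missing one atom: error names the offender
  short <- sys$topology
  short <- topology(short$atoms[-2, ], NULL, NULL, short$dielectrics)
  expect_error(merge_topology(traj0, short),
               "res_seq 100, name O1")

  # sidecar with extra entries: warning, extras ignored
  extra_atoms <- rbind(sys$topology$atoms,
                       toy_atom(99L, "XX", "C", res_seq = 999L))
  extra <- topology(extra_atoms, sys$topology$bonds, sys$topology$angles,
                    sys$topology$dielectrics)
  expect_warning(m2 <- merge_topology(traj0, extra), "no structural counterpart")
  expect_equal(n_atoms(m2$topology), n_atoms(sys$topology))
})

test_that("domain-type invariants are enforced", {
  at <- toy_atom(1L, "C1", "C")
  expect_error(topology(at, bonds = data.frame(i = 1L, j = 2L, k_b = 1, r0 = 1)),
               "non-existing atoms")
  at2 <- rbind(at, toy_atom(2L, "C2", "C"))
  expect_error(topology(at2, bonds = data.frame(i = c(1L, 2L), j = c(2L, 1L),
                                                k_b = 1, r0 = 1)),
               "duplicate bonds")
  expect_error(topology(at2, dielectrics = list(interior = 80, exterior = 1)),
               "exterior dielectric must exceed")
  top <- topology(at2)
  expect_error(trajectory(top, list(matrix(0, 3, 3))), "coordinate count")
  expect_error(trajectory(top, list(matrix(0, 2, 3), matrix(0, 2, 3)),
                          times = c(2, 1)), "strictly increasing")
  expect_error(complex_partition(1:2, 2:3), "disjoint")
  expect_error(complex_partition(integer(0), 1L), "non-empty")
  expect_error(complex_partition(1L, 2L, n_total = 3L), "cover all atoms")
})

test_that("subset_topology keeps order and remaps bonded terms", {
  sys <- hg_system()
  lig <- sys$partition$ligand
  sub <- subset_topology(sys$topology, lig)
  expect_equal(n_atoms(sub), length(lig))
  expect_equal(attr(sub, "index"), lig)
  expect_equal(sub$atoms$name, sys$topology$atoms$name[lig])
  # every remapped bond joins two ligand atoms
  expect_true(all(sub$bonds$i >= 1 & sub$bonds$j <= n_atoms(sub)))
  b_orig <- sys$topology$bonds
  n_lig_bonds <- sum(b_orig$i %in% lig & b_orig$j %in% lig)
  expect_equal(nrow(sub$bonds), n_lig_bonds)
})
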