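test_that("Kabsch superposition recovers rigid transforms and matches independent oracles", {
  set.seed(21)
  ref <- matrix(rnorm(30), 10, 3)
  # identity
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd_fit, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)
  # pure translation
  fit_t <- kabsch_superpose(sweep(ref, 2, c(5, 0, 0), "+"), ref)
  expect_equal(fit_t$rmsd_fit, 0, tolerance = 1e-10)
  # general rigid motion
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fit_r <- kabsch_superpose(ref %*% t(R) + 2, ref)
  expect_equal(fit_r$rmsd_fit, 0, tolerance = 1e-10)
  expect_equal(det(fit_r$rotation), 1, tolerance = 1e-10)

  # 4-point asymmetric toy with one displaced point: quaternion-method
  # oracle and bio3d both agree with the Kabsch result
  mob <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1.5, 0), c(0.4, 0.3, 1.2))
  tgt <- mob
  tgt[4, ] <- tgt[4, ] + c(0.3, -0.2, 0.4)
  mob_moved <- sweep(mob %*% t(R), 2, c(1, 2, 3), "+")
  fit <- kabsch_superpose(mob_moved, tgt)
  expect_equal(fit$rmsd_fit, quaternion_rmsd(mob_moved, tgt), tolerance = 1e-6)
  b3d <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(tgt)), mobile = as.vector(t(mob_moved))))
  rmsd_b3d <- sqrt(mean(rowSums((matrix(b3d, ncol = 3, byrow = TRUE) - tgt)^2)))
  expect_equal(fit$rmsd_fit, rmsd_b3d, tolerance = 1e-6)

  # degenerate (collinear) fit set
  line <- cbind(1:4, 0, 0) * 1.0
  expect_error(kabsch_superpose(line, line + 0.1), "collinear")
})

test_that("RMSD series is zero for self/rigid motion and invariant under global motion", {
  sys <- hg_system()
  n <- nrow(sys$frame)
  th <- 0.5
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  frames <- list(sys$frame,
                 sweep(sys$frame %*% t(R), 2, c(1, -2, 0.5), "+"),
                 sweep(sys$frame, 2, c(0, 0, 9), "+"))
  tr <- trajectory(sys$topology, frames)
  rs <- rmsd_series(tr, fit_subset = seq_len(n))
  expect_equal(rs$rmsd, c(0, 0, 0), tolerance = 1e-9)

  # jittered trajectory: identical series after a global rigid motion of
  # every frame (fit on receptor, measure ligand without refit)
  trj <- jitter_trajectory(sys$frame, sys$topology, n_frames = 10, sigma = 0.1,
                           seed = 31)
  moved <- trajectory(sys$topology,
                      lapply(trj$frames, function(f) sweep(f %*% t(R), 2, c(3, 3, 3), "+")),
                      trj$times)
  r1 <- rmsd_series(trj, sys$partition$receptor, sys$partition$ligand)
  r2 <- rmsd_series(moved, sys$partition$receptor, sys$partition$ligand)
  expect_equal(r2$rmsd[-1], r1$rmsd[-1], tolerance = 1e-6)
  expect_error(rmsd_series(trj, integer(0)), "non-empty")
})

test_that("mean RMSD of an isotropically jittered trajectory sits in the predicted band", {
  # per-coordinate sigma: squared displacement per atom ~ 3 sigma^2 before
  # fitting; optimal superposition can only lower it, and with 12 fit atoms
  # absorbs roughly 6/(3*12) of the variance, so the mean stays within
  # [0.8, 1.0] * sigma * sqrt(3) (the band also tolerates the sqrt-mean
  # concavity correction)
  sys <- hg_system()
  sigma <- 0.1
  trj <- jitter_trajectory(sys$frame, sys$topology, n_frames = 400,
                           sigma = sigma, seed = 77)
  # measure against the unjittered base pose so the displacement variance is
  # 3 sigma^2 per atom, not doubled by a jittered reference
  trj <- trajectory(sys$topology, c(list(sys$frame), trj$frames),
                    times = c(0, trj$times))
  rec <- sys$partition$receptor
  rs <- rmsd_series(trj, rec, rec, reference_frame = 1L)
  rs$mean <- mean(rs$rmsd[-1])
  expect_gt(rs$mean, 0.8 * sigma * sqrt(3))
  expect_lt(rs$mean, 1.0 * sigma * sqrt(3))
})

test_that("hydrogen-bond detection applies strict geometric criteria", {
  # donor D(0,0,0) - H(1,0,0) ... acceptor on the x axis
  mk <- function(apos) {
    at <- rbind(toy_atom(1L, "OD", "O", res_name = "SER", res_seq = 1L),
                toy_atom(2L, "HD", "H", res_name = "SER", res_seq = 1L),
                toy_atom(3L, "OA", "O", res_name = "LIG", res_seq = 9L, chain = "B"))
    top <- topology(at, bonds = data.frame(i = 1L, j = 2L, k_b = 300, r0 = 1))
    list(top = top, fr = rbind(c(0, 0, 0), c(1, 0, 0), apos))
  }
  s <- mk(c(2.8, 0, 0))
  hb <- find_hbonds(s$fr, s$top, donors = 1L, acceptors = 3L)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.8)
  expect_equal(hb$angle, 180)

  # distance fail at 3.6 and exactly at the 3.5 boundary (strict)
  expect_equal(nrow(find_hbonds(mk(c(3.6, 0, 0))$fr, s$top, 1L, 3L)), 0L)
  expect_equal(nrow(find_hbonds(mk(c(3.5, 0, 0))$fr, s$top, 1L, 3L)), 0L)
  expect_equal(nrow(find_hbonds(mk(c(3.499999, 0, 0))$fr, s$top, 1L, 3L)), 1L)

  # angle fail: acceptor placed for an exact angle at d = 2.9
  place_at_angle <- function(theta_deg, d = 2.9) {
    th <- theta_deg * pi / 180
    # acceptor at distance d from D such that angle D-H-A = theta
    # H at (1,0,0), D at origin; solve in the xy plane
    f <- function(phi) {
      a <- c(1, 0, 0) + 2 * c(cos(phi), sin(phi), 0)
      acos(sum(-c(1, 0, 0) * (a - c(1, 0, 0))) / (1 * 2)) * 180 / pi - theta_deg
    }
    phi <- uniroot(f, c(1e-6, pi - 1e-6))$root
    c(1, 0, 0) + 2 * c(cos(phi), sin(phi), 0)
  }
  a119 <- place_at_angle(119)
  a121 <- place_at_angle(121)
  expect_equal(nrow(find_hbonds(mk(a119)$fr, s$top, 1L, 3L)), 0L)
  expect_equal(nrow(find_hbonds(mk(a121)$fr, s$top, 1L, 3L)), 1L)
  # the boundary is strict: just below 120 degrees stays excluded
  a_under <- place_at_angle(120 - 1e-4)
  expect_equal(nrow(find_hbonds(mk(a_under)$fr, s$top, 1L, 3L)), 0L)

  # donor without bonded hydrogen is skipped
  no_h <- topology(mk(c(2.8, 0, 0))$top$atoms)
  expect_equal(nrow(find_hbonds(s$fr, no_h, 1L, 3L)), 0L)
})

test_that("occupancy counts passing frames and averages distance over them only", {
  at <- rbind(toy_atom(1L, "OD", "O", res_name = "SER", res_seq = 1L),
              toy_atom(2L, "HD", "H", res_name = "SER", res_seq = 1L),
              toy_atom(3L, "OA", "O", res_name = "LIG", res_seq = 9L, chain = "B"))
  top <- topology(at, bonds = data.frame(i = 1L, j = 2L, k_b = 300, r0 = 1))
  # constructed 1000-frame fixture: 684 frames at 2.8 A (pass), 316 at 4.5 (fail)
  n_pass <- 684L
  frames <- lapply(seq_len(1000L), function(k) {
    d <- if (k <= n_pass) 2.8 else 4.5
    rbind(c(0, 0, 0), c(1, 0, 0), c(d, 0, 0))
  })
  tr <- trajectory(top, frames)
  st <- hbond_occupancy(tr, donors = 1L, acceptors = 3L)
  expect_equal(nrow(st), 1L)
  expect_equal(st$occupancy, 68.4)
  expect_equal(st$mean_distance, 2.8)
  expect_equal(st$donor_label, "Ser1-OD")
  expect_equal(st$acceptor_label, "Lig9-OA")

  # occupancy is permutation-invariant over frames
  perm <- sample(1000L)
  st2 <- hbond_occupancy(trajectory(top, frames[perm]), 1L, 3L)
  expect_equal(st2$occupancy, st$occupancy)

  # a pair that never passes is omitted
  far <- trajectory(top, list(rbind(c(0, 0, 0), c(1, 0, 0), c(9, 0, 0))))
  expect_equal(nrow(hbond_occupancy(far, 1L, 3L)), 0L)
})

test_that("distance series averages pair distances over the window", {
  at <- rbind(toy_atom(1L, "A", "C"), toy_atom(2L, "B", "C"))
  top <- topology(at)
  tr <- trajectory(top, list(rbind(c(0, 0, 0), c(3, 0, 0)),
                             rbind(c(0, 0, 0), c(5, 0, 0))))
  ds <- distance_series(tr, 1L, 2L)
  expect_equal(ds$series, c(3, 5))
  expect_equal(ds$mean, 4)
  expect_error(distance_series(tr, 1L, 2L, window = integer(0)), "empty")
  expect_error(distance_series(tr, 1L, 9L), "out of range")

  # planted mean recovered within 3 sem on a jittered fixture
  sys <- hg_system()
  don <- which(sys$topology$atoms$name == "NH1" & sys$topology$atoms$res_seq == 60)
  acc <- which(sys$topology$atoms$name == "O1")
  d0 <- sqrt(sum((sys$frame[don, ] - sys$frame[acc, ])^2))
  trj <- jitter_trajectory(sys$frame, sys$topology, n_frames = 600, sigma = 0.02,
                           seed = 13)
  dj <- distance_series(trj, don, acc)
  sem <- sd(dj$series) / sqrt(length(dj$series))
  expect_lt(abs(dj$mean - d0), 3 * sem + 1e-4)
})
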