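# Seed-deterministic synthetic systems with known ground truth: toy
# host-guest complexes in the phosphate-in-hydrophilic-pocket motif,
# jittered bound-pose trajectories, and Crooks-consistent bidirectional work
# samples. These stand in for the (undeposited) simulation trajectories when
# validating the analysis machinery.

.LJ_PARAMS <- list(
  C = c(rmin_half = 1.908, epsilon = 0.086, gb_radius = 1.70, gb_screen = 0.72, mass = 12.011),
  N = c(rmin_half = 1.824, epsilon = 0.170, gb_radius = 1.55, gb_screen = 0.79, mass = 14.007),
  O = c(rmin_half = 1.6612, epsilon = 0.210, gb_radius = 1.50, gb_screen = 0.85, mass = 15.999),
  H = c(rmin_half = 0.6000, epsilon = 0.0157, gb_radius = 1.20, gb_screen = 0.85, mass = 1.008),
  P = c(rmin_half = 2.100, epsilon = 0.200, gb_radius = 1.85, gb_screen = 0.86, mass = 30.974))

.toy_atom <- function(serial, name, element, res_name, res_seq, chain, charge) {
  p <- .LJ_PARAMS[[element]]
  data.frame(serial = serial, name = name, element = element,
             res_name = res_name, res_seq = res_seq, chain = chain,
             charge = charge, rmin_half = p[["rmin_half"]],
             epsilon = p[["epsilon"]], gb_radius = p[["gb_radius"]],
             gb_screen = p[["gb_screen"]], mass = p[["mass"]],
             stringsAsFactors = FALSE)
}

#' A single Born ion
#'
#' One charge in a sphere: the system whose GB energy has the closed form
#' `-(K/2)(1/eps_in - 1/eps_out) q^2 / R`. The intrinsic radius is set to
#' `radius + 0.09` A so the effective Born radius equals `radius` exactly.
#'
#' @param charge ion charge (e).
#' @param radius intended effective Born radius (A).
#' @return list with `topology`, `frame`, and the closed-form `energy`.
#' @export
make_born_ion <- function(charge = 1, radius = 2.0) {
  at <- .toy_atom(1L, "ION", "N", "ION", 1L, "A", charge)
  at$gb_radius <- radius + GB_OFFSET
  top <- topology(at)
  e_ref <- -0.5 * K_COULOMB * (1 - 1 / top$dielectrics$exterior) * charge^2 / radius
  list(topology = top, frame = matrix(0, 1L, 3L), energy = e_ref)
}

#' A two-atom charge pair
#'
#' Minimal receptor/ligand system for closed-form checks of the pairwise
#' energetics.
#'
#' @param charges length-2 charges (e).
#' @param r separation (A) along x.
#' @param epsilon LJ epsilon used for both atoms (0 disables vdW).
#' @return list with `topology`, `frame`, `partition`.
#' @export
make_two_charge <- function(charges = c(1, -1), r = 3.0, epsilon = 0) {
  at <- rbind(.toy_atom(1L, "A1", "N", "REC", 1L, "A", charges[1]),
              .toy_atom(2L, "B1", "O", "LIG", 2L, "B", charges[2]))
  at$epsilon <- epsilon
  top <- topology(at)
  frame <- rbind(c(0, 0, 0), c(r, 0, 0))
  list(topology = top, frame = frame,
       partition = complex_partition(1L, 2L, n_total = 2L))
}

#' Toy host-guest complex
#'
#' A three-residue ring "host" whose two positively charged side chains and
#' one hydroxyl close around a 5-atom "guest" carrying a doubly negative
#' phosphate-like group, emulating a phosphate bound in a hydrophilic
#' pocket. Three donor-H/acceptor pairs sit at hydrogen-bonding geometry, so
#' the H-bond analyses are exercised; all parameters are physical and the
#' total charge is zero by construction (+1 +1 +0 host, -2 guest). Bond and
#' angle equilibria equal the built geometry, so the bonded terms are at
#' their minimum in the bound pose.
#'
#' @return list with `topology`, `frame` (bound pose), `partition`
#'   (receptor = host chain A, ligand = guest chain B).
#' @export
make_host_guest <- function() {
  rot2 <- function(v, ang) {
    c(cos(ang) * v[1] - sin(ang) * v[2], sin(ang) * v[1] + cos(ang) * v[2], v[3])
  }
  atoms <- list()
  coords <- list()
  bonds <- list()
  angles <- list()
  serial <- 0L
  add_atom <- function(name, element, res_name, res_seq, chain, charge, pos) {
    serial <<- serial + 1L
    atoms[[serial]] <<- .toy_atom(serial, name, element, res_name, res_seq, chain, charge)
    coords[[serial]] <<- pos
    serial
  }
  # guest: phosphate-like PO3-C group, total charge -2
  dirs <- lapply(c(0, 2 * pi / 3, -2 * pi / 3), function(a) rot2(c(1, 0, 0), a))
  iP <- add_atom("P", "P", "LIG", 100L, "B", 1.30, c(0, 0, 0))
  iO <- vapply(1:3, function(k) {
    add_atom(paste0("O", k), "O", "LIG", 100L, "B", -0.95, 1.50 * dirs[[k]])
  }, integer(1))
  iC <- add_atom("CM", "C", "LIG", 100L, "B", -0.45, c(0, 0, 1.60))
  for (k in iO) bonds[[length(bonds) + 1L]] <- c(iP, k)
  bonds[[length(bonds) + 1L]] <- c(iP, iC)
  # all O-P-O and O-P-C angles: the guest is internally rigid
  angles[[length(angles) + 1L]] <- c(iO[1], iP, iO[2])
  angles[[length(angles) + 1L]] <- c(iO[2], iP, iO[3])
  angles[[length(angles) + 1L]] <- c(iO[3], iP, iO[1])
  angles[[length(angles) + 1L]] <- c(iO[1], iP, iC)
  angles[[length(angles) + 1L]] <- c(iO[2], iP, iC)
  angles[[length(angles) + 1L]] <- c(iO[3], iP, iC)
  # host: two arginine-like (+1) residues and one tyrosine-like (0) residue,
  # each donating a hydrogen bond to one guest oxygen
  res_specs <- list(
    list(res_name = "ARG", res_seq = 60L, donor = "NH1", del = "N", hyd = "HH1",
         q = c(CB = 0.00, CZ = 0.64, D = -0.10, H = 0.46)),
    list(res_name = "ARG", res_seq = 133L, donor = "NH1", del = "N", hyd = "HH1",
         q = c(CB = 0.00, CZ = 0.64, D = -0.10, H = 0.46)),
    list(res_name = "TYR", res_seq = 134L, donor = "OH", del = "O", hyd = "HH",
         q = c(CB = 0.00, CZ = 0.15, D = -0.55, H = 0.40)))
  cb_idx <- integer(3)
  for (k in 1:3) {
    sp <- res_specs[[k]]
    u <- dirs[[k]]                       # unit vector P -> O_k
    w <- rot2(u, pi / 2)                 # in-plane perpendicular
    nD <- (1.5 + 2.85) * u               # donor heavy atom, 2.85 A from O_k
    nH <- nD - 1.0 * u                   # hydrogen on the donor-acceptor line
    nCZ <- nD + 1.33 * (cos(0.9) * u + sin(0.9) * w)
    nCB <- nCZ + 1.53 * (cos(0.6) * u + sin(0.6) * w) + c(0, 0, 0.5)
    iD <- add_atom(sp$donor, sp$del, sp$res_name, sp$res_seq, "A", sp$q[["D"]], nD)
    iH <- add_atom(sp$hyd, "H", sp$res_name, sp$res_seq, "A", sp$q[["H"]], nH)
    iCZ <- add_atom("CZ", "C", sp$res_name, sp$res_seq, "A", sp$q[["CZ"]], nCZ)
    iCB <- add_atom("CB", "C", sp$res_name, sp$res_seq, "A", sp$q[["CB"]], nCB)
    cb_idx[k] <- iCB
    bonds[[length(bonds) + 1L]] <- c(iD, iH)
    bonds[[length(bonds) + 1L]] <- c(iCZ, iD)
    bonds[[length(bonds) + 1L]] <- c(iCB, iCZ)
    angles[[length(angles) + 1L]] <- c(iH, iD, iCZ)
    angles[[length(angles) + 1L]] <- c(iD, iCZ, iCB)
  }
  # close the host ring through the CB atoms
  for (k in 1:3) {
    bonds[[length(bonds) + 1L]] <- c(cb_idx[k], cb_idx[k %% 3L + 1L])
    angles[[length(angles) + 1L]] <- c(cb_idx[(k - 2L) %% 3L + 1L], cb_idx[k],
                                       cb_idx[k %% 3L + 1L])
  }
  frame <- do.call(rbind, coords)
  at <- do.call(rbind, atoms)
  # weak elastic network bracing the host scaffold (all heavy-atom pairs,
  # plus each hydrogen to its residue's CB): torsion-free bonded terms alone
  # leave arm rotations soft, and the braces emulate the stiffness of a
  # folded scaffold so every species has one well-defined minimum
  bonded_key <- vapply(bonds, function(b) paste(min(b), max(b)), character(1))
  host_idx <- which(at$chain == "A")
  heavy <- host_idx[at$element[host_idx] != "H"]
  for (a in seq_along(heavy)) {
    for (b in seq_len(a - 1L)) {
      key <- paste(min(heavy[a], heavy[b]), max(heavy[a], heavy[b]))
      if (!(key %in% bonded_key)) {
        bonds[[length(bonds) + 1L]] <- c(heavy[b], heavy[a], 50)
        bonded_key <- c(bonded_key, key)
      }
    }
  }
  for (h in host_idx[at$element[host_idx] == "H"]) {
    res <- at$res_seq[h]
    cb <- host_idx[at$res_seq[host_idx] == res & at$name[host_idx] == "CB"]
    bonds[[length(bonds) + 1L]] <- c(h, cb, 50)
  }
  bt <- do.call(rbind, lapply(bonds, function(b) c(b[1], b[2], if (length(b) > 2L) b[3] else 300)))
  ag <- do.call(rbind, angles)
  # bonded equilibria = built geometry
  blen <- sqrt(rowSums((frame[bt[, 1], , drop = FALSE] - frame[bt[, 2], , drop = FALSE])^2))
  bonds_df <- data.frame(i = bt[, 1], j = bt[, 2], k_b = bt[, 3], r0 = blen)
  th0 <- vapply(seq_len(nrow(ag)), function(k) {
    u <- frame[ag[k, 1], ] - frame[ag[k, 2], ]
    v <- frame[ag[k, 3], ] - frame[ag[k, 2], ]
    acos(sum(u * v) / sqrt(sum(u * u) * sum(v * v)))
  }, numeric(1))
  angles_df <- data.frame(i = ag[, 1], j = ag[, 2], k = ag[, 3], k_a = 60, theta0 = th0)
  top <- topology(at, bonds_df, angles_df)
  guest <- which(at$chain == "B")
  host <- which(at$chain == "A")
  list(topology = top, frame = frame,
       partition = complex_partition(host, guest, n_total = nrow(at)))
}

#' Jittered bound-pose trajectory
#'
#' Adds i.i.d. Gaussian displacement of `sigma` A per coordinate to the base
#' frame, independently per frame; time stamps are `dt_ps` apart. The
#' default `sigma = 0.004` A keeps the ensemble in the linear-response
#' neighbourhood of the base pose even for the stiffest energy term (the
#' `r^-12` repulsive wall at hydrogen-bond contact), so the ensemble-mean
#' energies coincide with the static-pose values up to sampling error; that
#' is what makes the generator a parameter-recovery testbed. Larger jitter
#' remains useful for RMSD-style analyses but biases mean energies
#' quadratically in `sigma`.
#'
#' @param base N x 3 base coordinates (A).
#' @param top the matching [topology()].
#' @param n_frames number of frames.
#' @param sigma jitter standard deviation (A per coordinate), `>= 0`.
#' @param seed RNG seed (same seed, same trajectory).
#' @param dt_ps frame spacing (ps).
#' @return a [trajectory()].
#' @export
jitter_trajectory <- function(base, top, n_frames = 500, sigma = 0.004,
                              seed = NULL, dt_ps = 1) {
  stopifnot(sigma >= 0, n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(k) {
    base + matrix(stats::rnorm(length(base), sd = sigma), nrow(base), 3L)
  })
  trajectory(top, frames, times = seq_len(n_frames) * dt_ps)
}

#' Default planted per-segment free energies
#'
#' 16 x 1 A segments whose free-energy drops sum to -13.0 kcal/mol,
#' front-loaded over the first 7 segments (the pocket-exit region) with a
#' shallow tail.
#'
#' @return numeric vector of length 16 (kcal/mol).
#' @export
default_segment_dg <- function() {
  -13 * c(rep(0.12, 7), rep(0.16 / 9, 9))
}

#' Crooks-consistent bidirectional work sampler
#'
#' For each segment with planted free-energy change `dG_s` and work
#' fluctuation `sigma_w`, within-segment cumulative works are sums of
#' i.i.d. Gaussian increments with mean `d + beta sigma_d^2 / 2` forward and
#' `-d + beta sigma_d^2 / 2` reverse, so at every grid point the
#' forward/reverse work distributions satisfy the Crooks relation with equal
#' variances; whole-segment works are `N(dG_s + sigma_w^2/(2 kB T),
#' sigma_w^2)` and `N(-dG_s + sigma_w^2/(2 kB T), sigma_w^2)`. This is the
#' regime in which the BD-FDT estimator is exact in expectation. With
#' `sigma_w = 0` forward works are exactly the planted ramp.
#'
#' @param segment_dg per-segment free-energy changes (kcal/mol); default
#'   [default_segment_dg()].
#' @param sigma_w whole-segment work standard deviation (kcal/mol).
#' @param n_paths paths per direction per segment (the pulling protocol used
#'   four).
#' @param temperature K.
#' @param seed RNG seed.
#' @param segment_length segment span (A).
#' @param n_grid grid points per segment (includes both ends).
#' @return work-sample data.frame (see [read_works()]).
#' @export
crooks_work_sampler <- function(segment_dg = default_segment_dg(), sigma_w = 1,
                                n_paths = 4, temperature = 300, seed = NULL,
                                segment_length = 1, n_grid = 11) {
  stopifnot(n_grid >= 2L, n_paths >= 1L, sigma_w >= 0)
  if (!is.null(seed)) set.seed(seed)
  beta <- 1 / (KB_KCAL * temperature)
  nseg <- length(segment_dg)
  nstep <- n_grid - 1L
  sd_step <- sigma_w / sqrt(nstep)
  block <- n_paths * n_grid
  nrow_total <- 2L * nseg * block
  col_segment <- integer(nrow_total)
  col_dir <- character(nrow_total)
  col_path <- integer(nrow_total)
  col_disp <- numeric(nrow_total)
  col_work <- numeric(nrow_total)
  at_row <- 0L
  for (s in seq_len(nseg)) {
    grid <- (s - 1L) * segment_length + seq(0, segment_length, length.out = n_grid)
    d_mu <- segment_dg[s] / nstep + beta * sd_step^2 / 2
    r_mu <- -segment_dg[s] / nstep + beta * sd_step^2 / 2
    row_cumsum <- function(incr) {
      cum <- matrix(0, n_paths, n_grid)
      for (k in seq_len(nstep)) cum[, k + 1L] <- cum[, k] + incr[, k]
      cum
    }
    fw <- row_cumsum(matrix(stats::rnorm(n_paths * nstep, d_mu, sd_step),
                            n_paths, nstep))
    # reverse paths run from the far end; stored cumulative work is zero at
    # the far end and grows toward the segment entry
    rv <- row_cumsum(matrix(stats::rnorm(n_paths * nstep, r_mu, sd_step),
                            n_paths, nstep))[, n_grid:1, drop = FALSE]
    for (dir in c("forward", "reverse")) {
      rows <- at_row + seq_len(block)
      col_segment[rows] <- s
      col_dir[rows] <- dir
      col_path[rows] <- rep(seq_len(n_paths), each = n_grid)
      col_disp[rows] <- rep(grid, times = n_paths)
      col_work[rows] <- as.vector(t(if (dir == "forward") fw else rv))
      at_row <- at_row + block
    }
  }
  data.frame(segment = col_segment, direction = col_dir, path = col_path,
             displacement = col_disp, work = col_work,
             stringsAsFactors = FALSE)
}
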