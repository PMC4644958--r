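# MM-GBSA energetics: gas-phase pairwise interaction energies, generalized
# Born polar solvation (Hawkins-Cramer-Truhlar pairwise descreening under the
# Still interaction form), Shrake-Rupley solvent-accessible surface area, and
# the gamma*SASA + beta nonpolar term.
#
# End-state convention throughout: full pairwise sums, no cutoff, no
# periodicity. In the single-trajectory scheme only receptor x ligand terms
# survive the binding difference for the gas-phase components, while the
# solvation terms are complex - receptor - ligand differences evaluated on
# the same frame.

#' Coulomb energy of a point-charge pair
#'
#' @param qi,qj partial charges (e).
#' @param r separation (A), `> 0`.
#' @param dielectric uniform dielectric the pair is embedded in.
#' @return energy in kcal/mol, `K * qi * qj / (dielectric * r)` with
#'   `K = 332.0637`.
#' @export
coulomb_pair <- function(qi, qj, r, dielectric = 1) {
  if (any(r <= 0)) stop("singular Coulomb pair: r must be > 0")
  K_COULOMB * qi * qj / (dielectric * r)
}

#' Lennard-Jones energy of an atom pair
#'
#' Rmin/epsilon parameterization with Lorentz-Berthelot-style combination:
#' `Rmin_ij = rmin_half_i + rmin_half_j`, `eps_ij = sqrt(eps_i * eps_j)`.
#'
#' @param atom_i,atom_j one-row data frames or lists carrying `rmin_half`
#'   (A) and `epsilon` (kcal/mol).
#' @param r separation (A), `> 0`.
#' @return `eps_ij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)` in kcal/mol; the
#'   minimum is exactly `-eps_ij` at `r = Rmin_ij`.
#' @export
lj_pair <- function(atom_i, atom_j, r) {
  .lj_e(sqrt(atom_i$epsilon * atom_j$epsilon),
        atom_i$rmin_half + atom_j$rmin_half, r)
}

.lj_e <- function(eps, rmin, r) {
  if (any(r <= 0)) stop("singular Lennard-Jones pair: r must be > 0")
  s6 <- (rmin / r)^6
  eps * (s6 * s6 - 2 * s6)
}

#' Receptor-ligand gas-phase interaction energy
#'
#' Sums Coulomb and Lennard-Jones terms over all receptor x ligand pairs of
#' one frame (intramolecular terms cancel in the single-trajectory binding
#' difference). Gas-phase electrostatics use the interior dielectric.
#'
#' @param frame N x 3 coordinate matrix (A).
#' @param top a parameterized [topology()].
#' @param partition a [complex_partition()].
#' @return list with `e_ele` and `e_vdw` (kcal/mol).
#' @export
intermolecular_energy <- function(frame, top, partition) {
  at <- top$atoms
  ir <- partition$receptor
  il <- partition$ligand
  .need_params(at[c(ir, il), ], c("charge", "rmin_half", "epsilon"))
  d2 <- .cross_dist2(frame[ir, , drop = FALSE], frame[il, , drop = FALSE])
  if (any(d2 < 1e-12)) {
    w <- which(d2 < 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("overlapping atoms: receptor atom %d and ligand atom %d closer than 1e-6 A",
                 ir[w[1]], il[w[2]]))
  }
  d <- sqrt(d2)
  e_ele <- K_COULOMB / top$dielectrics$interior *
    sum(outer(at$charge[ir], at$charge[il]) / d)
  eps <- outer(sqrt(at$epsilon[ir]), sqrt(at$epsilon[il]))
  rmin <- outer(at$rmin_half[ir], at$rmin_half[il], "+")
  s6 <- (rmin / d)^6
  e_vdw <- sum(eps * (s6 * s6 - 2 * s6))
  list(e_ele = e_ele, e_vdw = e_vdw)
}

.need_params <- function(atoms, cols) {
  for (col in cols) {
    if (anyNA(atoms[[col]])) {
      stop("parameterization error: atom parameter '", col,
           "' is unset; merge a topology sidecar first")
    }
  }
}

## ---------------------------------------------------------------------------
## Generalized Born

# HCT pairwise descreening integral H(r, rho_i, s_j): the (1/4pi) r'^-4
# volume integral over the scaled sphere of j excluded from within rho_i of
# i. Closed form validated against direct quadrature of the descreening
# integral (see tests).
.hct_term <- function(r, rho_i, sj) {
  out <- numeric(length(r))
  keep <- rho_i < r + sj & sj > 0
  if (!any(keep)) return(out)
  r <- r[keep]; rho <- rho_i[keep]; s <- sj[keep]
  U <- r + s
  L <- pmax(rho, abs(r - s))
  base <- 0.5 * (1 / L - 1 / U + 0.25 * (r - s * s / r) * (1 / U^2 - 1 / L^2) +
                   0.5 * log(L / U) / r)
  engulfed <- s > r + rho
  base[engulfed] <- base[engulfed] + (1 / rho[engulfed] - 1 / L[engulfed])
  out[keep] <- base
  out
}

#' Effective Born radii by pairwise descreening
#'
#' Hawkins-Cramer-Truhlar model: `1/R_i = 1/rho_i - sum_j H(r_ij, rho_i,
#' S_j rho_j)` with intrinsic radii offset by 0.09 A. An isolated atom
#' returns its offset intrinsic radius; burial by neighbours only ever grows
#' the effective radius.
#'
#' @param frame N x 3 coordinates (A).
#' @param top a parameterized [topology()].
#' @param subset atom indices to evaluate (descreening also only by subset
#'   members, i.e. the subset is the whole solute).
#' @return named numeric vector of effective radii (A) for `subset`.
#' @export
effective_born_radii <- function(frame, top, subset = seq_len(n_atoms(top))) {
  at <- top$atoms[subset, , drop = FALSE]
  .need_params(at, c("gb_radius", "gb_screen"))
  if (any(at$gb_radius <= 0)) stop("gb_radius must be > 0 for GB evaluation")
  rho <- at$gb_radius - GB_OFFSET
  if (any(rho <= 0)) stop("intrinsic radius minus offset must stay positive")
  s <- at$gb_screen * rho
  n <- length(subset)
  xyz <- frame[subset, , drop = FALSE]
  inv <- 1 / rho
  if (n > 1L) {
    d <- sqrt(.cross_dist2(xyz, xyz))
    for (i in seq_len(n)) {
      inv[i] <- inv[i] - sum(.hct_term(d[i, -i], rep(rho[i], n - 1L), s[-i]))
    }
  }
  bad <- inv <= 0
  if (any(bad)) {
    warning(sprintf("%d nonpositive inverse effective radii clamped to 1e-3 1/A", sum(bad)))
    inv[bad] <- 1e-3
  }
  stats::setNames(1 / inv, at$name)
}

#' Generalized Born polar solvation energy
#'
#' Still interaction form including self terms:
#' `-(K/2) (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB(r_ij, R_i, R_j)`
#' with `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))` (so
#' `f_GB = R_i` on the diagonal).
#'
#' @inheritParams effective_born_radii
#' @param radii optional precomputed effective radii for `subset`.
#' @return polar solvation free energy (kcal/mol).
#' @export
gb_polar <- function(frame, top, subset = seq_len(n_atoms(top)), radii = NULL) {
  at <- top$atoms[subset, , drop = FALSE]
  .need_params(at, "charge")
  if (is.null(radii)) radii <- effective_born_radii(frame, top, subset)
  if (length(radii) != length(subset) || anyNA(radii)) {
    stop("parameterization error: effective radii missing for subset")
  }
  sum(.gb_atomwise(frame, top, subset, radii))
}

# per-atom GB contributions (row sums of the symmetric Still double sum):
# each cross term lands half on each partner, self terms on their own atom
.gb_atomwise <- function(frame, top, subset, radii) {
  at <- top$atoms[subset, , drop = FALSE]
  q <- at$charge
  xyz <- frame[subset, , drop = FALSE]
  d2 <- .cross_dist2(xyz, xyz)
  rr <- outer(radii, radii)
  fgb <- sqrt(d2 + rr * exp(-d2 / (4 * rr)))
  coeff <- -0.5 * K_COULOMB *
    (1 / top$dielectrics$interior - 1 / top$dielectrics$exterior)
  coeff * q * as.vector((1 / fgb) %*% q)
}

## ---------------------------------------------------------------------------
## Solvent-accessible surface area (Shrake-Rupley)

# deterministic quasi-uniform unit sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- pi * (3 - sqrt(5)) * (k - 0.5)
  s <- sqrt(pmax(0, 1 - z * z))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's probe-inflated sphere (`rmin_half + probe`; the Lennard-Jones
#' Rmin/2 doubles as the SASA radius) is covered with a deterministic
#' Fibonacci point lattice; points inside any neighbour's inflated sphere
#' are inaccessible. Deterministic given `n_points`; per-atom areas sum to
#' the total.
#'
#' @inheritParams effective_born_radii
#' @param probe probe radius (A), default 1.4.
#' @param n_points lattice points per atom, default 960.
#' @return list with `total` (A^2) and `per_atom` (A^2, named by subset order).
#' @export
sasa <- function(frame, top, subset = seq_len(n_atoms(top)), probe = 1.4,
                 n_points = 960) {
  at <- top$atoms[subset, , drop = FALSE]
  .need_params(at, "rmin_half")
  rad <- at$rmin_half + probe
  xyz <- frame[subset, , drop = FALSE]
  n <- length(subset)
  pts <- .fibonacci_sphere(n_points)
  per <- numeric(n)
  d2all <- if (n > 1L) .cross_dist2(xyz, xyz) else matrix(0, 1, 1)
  for (i in seq_len(n)) {
    nbr <- if (n > 1L) {
      which(d2all[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    } else integer(0)
    if (length(nbr) == 0L) {
      per[i] <- 4 * pi * rad[i]^2
      next
    }
    surf <- sweep(pts * rad[i], 2L, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nbr) {
      dj <- sweep(surf, 2L, xyz[j, ], "-")
      buried <- buried | (rowSums(dj * dj) < rad[j]^2)
      if (all(buried)) break
    }
    per[i] <- 4 * pi * rad[i]^2 * mean(!buried)
  }
  list(total = sum(per), per_atom = stats::setNames(per, at$name))
}

#' Nonpolar solvation term
#'
#' Linear surface-area model `gamma * SASA + beta` with the end-state
#' defaults `gamma = 0.005` kcal/mol/A^2 and `beta = 0` kcal/mol.
#'
#' @param sasa_total SASA (A^2), `>= 0`.
#' @param gamma surface tension coefficient (kcal/mol/A^2).
#' @param beta offset (kcal/mol).
#' @return nonpolar solvation free energy (kcal/mol).
#' @export
nonpolar_energy <- function(sasa_total, gamma = 0.005, beta = 0.0) {
  if (any(sasa_total < 0)) stop("domain error: SASA must be >= 0")
  gamma * sasa_total + beta
}

## ---------------------------------------------------------------------------
## Snapshot-level binding energy breakdown

#' Construct an energy breakdown
#'
#' Holds the component set of one snapshot (or an aggregate): gas-phase
#' electrostatic and van der Waals interaction energies, polar and nonpolar
#' solvation differences, and the derived sums. The derived fields are
#' recomputed, so the composite identities hold by construction.
#'
#' @param e_ele,e_vdw,g_pol,g_nonpol components (kcal/mol).
#' @return object of class `energy_breakdown`.
#' @export
energy_breakdown <- function(e_ele, e_vdw, g_pol, g_nonpol) {
  structure(list(e_ele = e_ele, e_vdw = e_vdw, g_pol = g_pol,
                 g_nonpol = g_nonpol,
                 g_ele_pol = e_ele + g_pol,
                 g_vdw_nonpol = e_vdw + g_nonpol,
                 h = e_ele + e_vdw + g_pol + g_nonpol),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("energy breakdown (kcal/mol): e_ele %.3f, e_vdw %.3f, ",
                     "g_pol %.3f, g_nonpol %.3f, h %.3f\n"),
              x$e_ele, x$e_vdw, x$g_pol, x$g_nonpol, x$h))
  invisible(x)
}

#' Single-snapshot MM-GBSA binding energy breakdown
#'
#' Single-trajectory scheme: gas-phase terms from the receptor x ligand
#' pairwise sum; solvation terms as complex minus receptor minus ligand
#' differences evaluated on the same frame.
#'
#' @inheritParams intermolecular_energy
#' @param probe,n_points SASA settings, see [sasa()].
#' @param gamma,beta nonpolar model, see [nonpolar_energy()].
#' @return an [energy_breakdown()].
#' @export
snapshot_breakdown <- function(frame, top, partition, probe = 1.4,
                               n_points = 960, gamma = 0.005, beta = 0.0) {
  gas <- intermolecular_energy(frame, top, partition)
  both <- sort(c(partition$receptor, partition$ligand))
  g_c <- gb_polar(frame, top, both)
  g_r <- gb_polar(frame, top, partition$receptor)
  g_l <- gb_polar(frame, top, partition$ligand)
  s_c <- sasa(frame, top, both, probe, n_points)$total
  s_r <- sasa(frame, top, partition$receptor, probe, n_points)$total
  s_l <- sasa(frame, top, partition$ligand, probe, n_points)$total
  g_np <- nonpolar_energy(s_c, gamma, beta) - nonpolar_energy(s_r, gamma, beta) -
    nonpolar_energy(s_l, gamma, beta)
  energy_breakdown(gas$e_ele, gas$e_vdw, g_c - g_r - g_l, g_np)
}

#' Per-residue decomposition of the binding energy
#'
#' Every receptor x ligand pairwise term (Coulomb, Lennard-Jones, GB cross
#' term) is split half/half between the two partners' buckets; GB self-term
#' and SASA differences are assigned to the owning atom. Receptor atoms
#' aggregate into residue buckets, ligand atoms into one ligand bucket, so
#' the bucket totals reconcile exactly with [snapshot_breakdown()].
#'
#' @inheritParams snapshot_breakdown
#' @return data.frame with columns `label`, `e_ele`, `e_vdw`, `g_pol`,
#'   `g_nonpol`, `total` (kcal/mol); one row per receptor residue plus one
#'   ligand row.
#' @export
per_residue_decomposition <- function(frame, top, partition, probe = 1.4,
                                      n_points = 960, gamma = 0.005, beta = 0.0) {
  at <- top$atoms
  ir <- partition$receptor
  il <- partition$ligand
  both <- sort(c(ir, il))
  nb <- length(both)
  pos <- stats::setNames(seq_len(nb), both)   # atom index -> position in `both`

  # gas-phase pair terms, half to each partner
  d <- sqrt(.cross_dist2(frame[ir, , drop = FALSE], frame[il, , drop = FALSE]))
  ele_mat <- K_COULOMB / top$dielectrics$interior *
    outer(at$charge[ir], at$charge[il]) / d
  eps <- outer(sqrt(at$epsilon[ir]), sqrt(at$epsilon[il]))
  rmin <- outer(at$rmin_half[ir], at$rmin_half[il], "+")
  s6 <- (rmin / d)^6
  vdw_mat <- eps * (s6 * s6 - 2 * s6)
  ele_atom <- numeric(nb)
  vdw_atom <- numeric(nb)
  ele_atom[pos[as.character(ir)]] <- 0.5 * rowSums(ele_mat)
  ele_atom[pos[as.character(il)]] <- 0.5 * colSums(ele_mat)
  vdw_atom[pos[as.character(ir)]] <- 0.5 * rowSums(vdw_mat)
  vdw_atom[pos[as.character(il)]] <- 0.5 * colSums(vdw_mat)

  # GB: atomwise complex contribution minus isolated-species contribution
  gb_c <- .gb_atomwise(frame, top, both, effective_born_radii(frame, top, both))
  gb_atom <- gb_c
  for (sp in list(ir, il)) {
    gb_s <- .gb_atomwise(frame, top, sp, effective_born_radii(frame, top, sp))
    gb_atom[pos[as.character(sp)]] <- gb_atom[pos[as.character(sp)]] - gb_s
  }

  # nonpolar: per-atom SASA difference times gamma (beta = 0 convention;
  # a nonzero beta belongs to the system total, not to any one residue)
  sa_c <- sasa(frame, top, both, probe, n_points)$per_atom
  np_atom <- gamma * sa_c
  for (sp in list(ir, il)) {
    sa_s <- sasa(frame, top, sp, probe, n_points)$per_atom
    np_atom[pos[as.character(sp)]] <- np_atom[pos[as.character(sp)]] - gamma * sa_s
  }

  lab <- character(nb)
  is_rec <- both %in% ir
  lab[is_rec] <- sprintf("%s%d", at$res_name[both[is_rec]], at$res_seq[both[is_rec]])
  lab[!is_rec] <- "ligand"
  agg <- function(v) as.numeric(tapply(v, lab, sum)[unique(lab)])
  out <- data.frame(label = unique(lab),
                    e_ele = agg(ele_atom), e_vdw = agg(vdw_atom),
                    g_pol = agg(gb_atom), g_nonpol = agg(np_atom),
                    stringsAsFactors = FALSE)
  out$total <- out$e_ele + out$e_vdw + out$g_pol + out$g_nonpol
  out
}
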