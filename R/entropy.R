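# Normal-mode conformational entropy for toy systems: a small bonded +
# nonbonded force field with analytic gradients, a quasi-Newton minimizer,
# finite-difference Hessians, mass-weighted normal modes, and standard
# ideal-gas / rigid-rotor / harmonic-oscillator thermochemistry.

## ---------------------------------------------------------------------------
## Toy force-field energy and analytic gradient

# 1-2 and 1-3 exclusion pair list derived from the bond graph plus any
# explicit angle triples
.excluded_pairs <- function(top) {
  n <- n_atoms(top)
  b <- top$bonds
  pairs <- cbind(b$i, b$j)
  if (nrow(b) > 0L) {
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (k in seq_len(nrow(b))) {
      adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
      adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
    }
    for (j in seq_len(n)) {
      nb <- adj[[j]]
      if (length(nb) > 1L) {
        cmb <- utils::combn(sort(nb), 2L)
        pairs <- rbind(pairs, t(cmb))
      }
    }
  }
  a <- top$angles
  if (nrow(a) > 0L) pairs <- rbind(pairs, cbind(a$i, a$k))
  if (nrow(pairs) == 0L) return(matrix(integer(0), ncol = 2L))
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

# precomputed term structure for repeated ff_energy evaluation; memoized per
# topology object through an attached environment
.ff_cache <- function(top) {
  cache <- attr(top, "ff_cache")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (!is.null(cache$pairs)) return(cache)
  n <- n_atoms(top)
  at <- top$atoms
  excl <- .excluded_pairs(top)
  excl_key <- if (nrow(excl)) paste(excl[, 1], excl[, 2]) else character(0)
  if (n > 1L) {
    ij <- t(utils::combn(n, 2L))
    keep <- !(paste(ij[, 1], ij[, 2]) %in% excl_key)
    ij <- ij[keep, , drop = FALSE]
  } else {
    ij <- matrix(integer(0), ncol = 2L)
  }
  cache$pairs <- ij
  cache$qq <- K_COULOMB / top$dielectrics$interior *
    at$charge[ij[, 1]] * at$charge[ij[, 2]]
  cache$eps <- sqrt(at$epsilon[ij[, 1]] * at$epsilon[ij[, 2]])
  cache$rmin <- at$rmin_half[ij[, 1]] + at$rmin_half[ij[, 2]]
  cache
}

.acc_rows <- function(g, idx, X) {
  rs <- rowsum(X, idx)
  ri <- as.integer(rownames(rs))
  g[ri, ] <- g[ri, , drop = FALSE] + rs
  g
}

#' Toy force-field energy and gradient
#'
#' Harmonic bonds `k_b (r - r0)^2`, harmonic angles `k_a (theta - theta0)^2`,
#' and nonbonded Coulomb (interior dielectric) + Lennard-Jones over all atom
#' pairs except 1-2 and 1-3 neighbours. This is the surface on which the
#' normal-mode entropy of the synthetic systems is defined.
#'
#' @param frame N x 3 coordinates (A).
#' @param top a parameterized [topology()].
#' @param gradient also return the analytic gradient.
#' @return list with `energy` (kcal/mol) and, if requested, `gradient`
#'   (N x 3, kcal/mol/A).
#' @export
ff_energy <- function(frame, top, gradient = FALSE) {
  n <- nrow(frame)
  e <- 0
  g <- matrix(0, n, 3L)
  b <- top$bonds
  if (nrow(b) > 0L) {
    dv <- frame[b$i, , drop = FALSE] - frame[b$j, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    e <- e + sum(b$k_b * (r - b$r0)^2)
    if (gradient) {
      gb <- dv * (2 * b$k_b * (r - b$r0) / r)
      g <- .acc_rows(g, b$i, gb)
      g <- .acc_rows(g, b$j, -gb)
    }
  }
  a <- top$angles
  if (nrow(a) > 0L) {
    u <- frame[a$i, , drop = FALSE] - frame[a$j, , drop = FALSE]
    v <- frame[a$k, , drop = FALSE] - frame[a$j, , drop = FALSE]
    lu <- sqrt(rowSums(u * u)); lv <- sqrt(rowSums(v * v))
    ct <- rowSums(u * v) / (lu * lv)
    ct <- pmin(1 - 1e-12, pmax(-1 + 1e-12, ct))
    th <- acos(ct)
    e <- e + sum(a$k_a * (th - a$theta0)^2)
    if (gradient) {
      st <- sqrt(1 - ct * ct)
      dth_du <- (ct * u / lu - v / lv) / (lu * st)
      dth_dv <- (ct * v / lv - u / lu) / (lv * st)
      coef <- 2 * a$k_a * (th - a$theta0)
      g <- .acc_rows(g, a$i, coef * dth_du)
      g <- .acc_rows(g, a$k, coef * dth_dv)
      g <- .acc_rows(g, a$j, -coef * (dth_du + dth_dv))
    }
  }
  cache <- .ff_cache(top)
  ij <- cache$pairs
  if (nrow(ij) > 0L) {
    dv <- frame[ij[, 1], , drop = FALSE] - frame[ij[, 2], , drop = FALSE]
    r2 <- rowSums(dv * dv)
    if (any(r2 < 1e-12)) stop("non-finite toy energy: overlapping nonbonded atoms")
    r <- sqrt(r2)
    s6 <- (cache$rmin / r)^6
    e <- e + sum(cache$qq / r) + sum(cache$eps * (s6 * s6 - 2 * s6))
    if (gradient) {
      dEdr <- -cache$qq / r2 + cache$eps * (-12 * s6 * s6 + 12 * s6) / r
      gn <- dv * (dEdr / r)
      g <- .acc_rows(g, ij[, 1], gn)
      g <- .acc_rows(g, ij[, 2], -gn)
    }
  }
  if (!is.finite(e)) stop("non-finite toy force-field energy")
  if (gradient) list(energy = e, gradient = g) else list(energy = e)
}

#' Minimize a toy structure
#'
#' Quasi-Newton (L-BFGS-B) minimization of [ff_energy()] with its analytic
#' gradient, run until the gradient norm falls below `tol` (kcal/mol/A) or
#' `max_iter` is reached; a structure not yet at `tol` is returned with a
#' warning. Normal-mode analysis expects its input pre-minimized by this
#' helper.
#'
#' @inheritParams ff_energy
#' @param tol gradient infinity-norm target (kcal/mol/A).
#' @param max_iter iteration cap per restart (up to 4 restarts).
#' @return list with `frame` (minimized coordinates), `energy`, `grad_max`.
#' @export
minimize_energy <- function(frame, top, tol = 1e-6, max_iter = 2000) {
  n <- nrow(frame)
  # atom-major coordinate vector (x1,y1,z1,x2,...), matching hessian_matrix
  unflat <- function(p) t(matrix(p, 3L, n))
  fn <- function(p) ff_energy(unflat(p), top)$energy
  gr <- function(p) as.vector(t(ff_energy(unflat(p), top, gradient = TRUE)$gradient))
  par <- as.vector(t(frame))
  gmax <- max(abs(gr(par)))
  if (gmax > tol) {
    res <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 100, pgtol = 0))
    par <- res$par
    gmax <- max(abs(gr(par)))
  }
  # Newton polish in the non-rigid subspace (quadratic convergence near the
  # minimum, where quasi-Newton line searches stall on stiff toy surfaces);
  # steps accepted on gradient-norm decrease with backtracking
  polish <- 0L
  while (gmax > tol && polish < 8L) {
    H <- hessian_matrix(unflat(par), top)
    eg <- eigen(H, symmetric = TRUE)
    lam <- eg$values
    keep <- abs(lam) > 1e-6 * max(abs(lam))
    g <- gr(par)
    step <- -as.vector(eg$vectors[, keep, drop = FALSE] %*%
                         ((crossprod(eg$vectors[, keep, drop = FALSE], g)) / lam[keep]))
    accepted <- FALSE
    for (bt in 0:4) {
      cand <- par + step / 2^bt
      gnew <- max(abs(gr(cand)))
      if (gnew < gmax) {
        par <- cand
        gmax <- gnew
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    polish <- polish + 1L
  }
  if (gmax > tol) {
    warning(sprintf("minimization stopped at |grad|max = %.3g > tol %.3g", gmax, tol))
  }
  list(frame = unflat(par), energy = fn(par), grad_max = gmax)
}

#' Finite-difference Hessian of the toy force field
#'
#' Central differences of the analytic gradient with step `step` (A);
#' symmetrized after checking that the asymmetry `||H - H'||_inf` stays
#' below `1e-6 * max(1, ||H||_inf)` (the truncation error of the central
#' difference scales with the local third derivatives, hence the relative
#' bound). Mass-unweighted, kcal/mol/A^2.
#'
#' @inheritParams ff_energy
#' @param step displacement step (A).
#' @return 3N x 3N symmetric matrix.
#' @export
hessian_matrix <- function(frame, top, step = 1e-4) {
  n <- nrow(frame)
  m <- 3L * n
  H <- matrix(0, m, m)
  for (c in seq_len(m)) {
    atom <- (c - 1L) %/% 3L + 1L
    dim_ <- (c - 1L) %% 3L + 1L
    fp <- frame; fp[atom, dim_] <- fp[atom, dim_] + step
    fm <- frame; fm[atom, dim_] <- fm[atom, dim_] - step
    gp <- ff_energy(fp, top, gradient = TRUE)$gradient
    gm <- ff_energy(fm, top, gradient = TRUE)$gradient
    H[, c] <- as.vector(t(gp - gm)) / (2 * step)
  }
  asym <- max(abs(H - t(H)))
  if (asym > 1e-6 * max(1, max(abs(H)))) {
    warning(sprintf("Hessian asymmetry %.3g exceeds tolerance; symmetrizing anyway", asym))
  }
  (H + t(H)) / 2
}

## ---------------------------------------------------------------------------
## Normal modes

#' Mass-weighted normal modes
#'
#' Eigenvalues of the mass-weighted Hessian converted to wavenumbers.
#' Rigid-body (near-zero) modes with `|nu| < zero_threshold` cm^-1 are
#' removed and counted; more than 6 removals, or surviving imaginary modes,
#' draw a "not at a minimum" warning (imaginary modes are dropped from the
#' spectrum).
#'
#' @param hessian 3N x 3N matrix from [hessian_matrix()] (kcal/mol/A^2).
#' @param masses atom masses (amu), length N.
#' @param zero_threshold rigid-body cutoff (cm^-1).
#' @return object of class `mode_spectrum`: list with `frequencies`
#'   (cm^-1, ascending), `n_zero_removed`, `n_imaginary`.
#' @export
normal_modes <- function(hessian, masses, zero_threshold = 1.0) {
  n <- length(masses)
  stopifnot(nrow(hessian) == 3L * n)
  w <- rep(1 / sqrt(masses), each = 3L)
  Hmw <- hessian * outer(w, w)
  lam <- eigen(Hmw, symmetric = TRUE, only.values = TRUE)$values
  nu <- sign(lam) * FREQ_CM1 * sqrt(abs(lam))
  near_zero <- abs(nu) < zero_threshold
  n_zero <- sum(near_zero)
  nu <- nu[!near_zero]
  n_imag <- sum(nu < 0)
  if (n_zero > 6L || n_imag > 0L) {
    warning(sprintf("structure is not at a minimum: %d near-zero and %d imaginary modes",
                    n_zero, n_imag))
  }
  structure(list(frequencies = sort(nu[nu > 0]),
                 n_zero_removed = n_zero, n_imaginary = n_imag),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("mode spectrum: %d vibrations (%.1f..%.1f cm^-1), %d zero modes removed\n",
              length(x$frequencies),
              if (length(x$frequencies)) min(x$frequencies) else NA,
              if (length(x$frequencies)) max(x$frequencies) else NA,
              x$n_zero_removed))
  invisible(x)
}

#' Principal moments of inertia
#' @param frame N x 3 coordinates (A).
#' @param masses atom masses (amu).
#' @return ascending principal moments (amu A^2).
#' @export
inertia_moments <- function(frame, masses) {
  com <- colSums(frame * masses) / sum(masses)
  x <- sweep(frame, 2L, com)
  r2 <- rowSums(x * x)
  I <- diag(c(sum(masses * (r2 - x[, 1]^2)),
              sum(masses * (r2 - x[, 2]^2)),
              sum(masses * (r2 - x[, 3]^2))))
  I[1, 2] <- I[2, 1] <- -sum(masses * x[, 1] * x[, 2])
  I[1, 3] <- I[3, 1] <- -sum(masses * x[, 1] * x[, 3])
  I[2, 3] <- I[3, 2] <- -sum(masses * x[, 2] * x[, 3])
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Ideal-gas / rigid-rotor / harmonic-oscillator entropy of one species
#'
#' Standard statistical-thermodynamics entropy at 1 atm:
#' Sackur-Tetrode translation, rigid-rotor rotation (monatomic, linear and
#' nonlinear handled from the inertia moments), and harmonic vibrations from
#' the mode spectrum. Zero or negative frequencies are a domain error; they
#' must be removed upstream by [normal_modes()].
#'
#' @param spectrum a `mode_spectrum` or numeric vector of frequencies
#'   (cm^-1, all `> 0`).
#' @param mass_total species mass (amu).
#' @param inertia principal inertia moments (amu A^2), e.g. from
#'   [inertia_moments()]; moments below 1e-8 are treated as zero.
#' @param temperature K, `> 0`.
#' @param symmetry_number rotational symmetry number.
#' @return list with `s_trans`, `s_rot`, `s_vib`, `s_total` (kcal/mol/K)
#'   and `minus_TS` (kcal/mol).
#' @export
species_entropy <- function(spectrum, mass_total, inertia,
                            temperature = 300, symmetry_number = 1) {
  if (temperature <= 0) stop("temperature must be > 0")
  freqs <- if (inherits(spectrum, "mode_spectrum")) spectrum$frequencies else spectrum
  if (any(freqs <= 0)) {
    stop("domain error: zero/negative frequency passed to vibrational entropy")
  }
  cst <- .const
  T <- temperature
  m_kg <- mass_total * cst$amu
  q_trans <- (2 * pi * m_kg * cst$kB * T / cst$h^2)^1.5 * (cst$kB * T / cst$P0)
  s_trans <- R_KCAL * (log(q_trans) + 2.5)
  I_si <- inertia * cst$amu * 1e-20
  nz <- I_si > 1e-8 * cst$amu * 1e-20
  if (sum(nz) == 0L) {
    s_rot <- 0
  } else if (sum(nz) == 2L) {  # linear rotor: two equal nonzero moments
    q_rot <- 8 * pi^2 * mean(I_si[nz]) * cst$kB * T / (symmetry_number * cst$h^2)
    s_rot <- R_KCAL * (log(q_rot) + 1)
  } else {
    q_rot <- sqrt(pi) / symmetry_number *
      (8 * pi^2 * cst$kB * T / cst$h^2)^1.5 * sqrt(prod(I_si))
    s_rot <- R_KCAL * (log(q_rot) + 1.5)
  }
  s_vib <- if (length(freqs) == 0L) 0 else {
    x <- 1.4387768775 * freqs / T   # h c / kB in cm K
    R_KCAL * sum(x / (exp(x) - 1) - log1p(-exp(-x)))
  }
  s_total <- s_trans + s_rot + s_vib
  list(s_trans = s_trans, s_rot = s_rot, s_vib = s_vib,
       s_total = s_total, minus_TS = -T * s_total)
}

#' Normal-mode entropy of one species from coordinates
#'
#' Convenience wrapper chaining [minimize_energy()], [hessian_matrix()],
#' [normal_modes()] and [species_entropy()].
#'
#' @inheritParams ff_energy
#' @param temperature K.
#' @param symmetry_number rotational symmetry number.
#' @param minimize minimize before the Hessian (recommended).
#' @param tol minimizer gradient tolerance (kcal/mol/A).
#' @return as [species_entropy()], plus `spectrum`.
#' @export
nma_entropy <- function(frame, top, temperature = 300, symmetry_number = 1,
                        minimize = TRUE, tol = 1e-6) {
  if (minimize) frame <- minimize_energy(frame, top, tol = tol)$frame
  H <- hessian_matrix(frame, top)
  spec <- normal_modes(H, top$atoms$mass)
  out <- species_entropy(spec, sum(top$atoms$mass),
                         inertia_moments(frame, top$atoms$mass),
                         temperature, symmetry_number)
  out$spectrum <- spec
  out
}

#' Binding entropy term -T dS from the three species
#'
#' `-T (S_complex - S_receptor - S_ligand)`; positive when binding restricts
#' motion.
#'
#' @param s_complex,s_receptor,s_ligand outputs of [species_entropy()] or
#'   [nma_entropy()].
#' @param temperature K (must match the species evaluations).
#' @return `-T dS` in kcal/mol.
#' @export
binding_entropy_term <- function(s_complex, s_receptor, s_ligand, temperature = 300) {
  -temperature * (s_complex$s_total - s_receptor$s_total - s_ligand$s_total)
}
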