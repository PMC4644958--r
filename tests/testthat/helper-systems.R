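# Shared fixture builders and independent oracles, all constructed in code.

# minimal parameterized atom row
toy_atom <- function(serial, name, element, res_name = "UNK", res_seq = 1L,
                     chain = "A", charge = 0, rmin_half = 1.7, epsilon = 0.1,
                     gb_radius = 1.5, gb_screen = 0.8, mass = 12.0) {
  data.frame(serial = serial, name = name, element = element,
             res_name = res_name, res_seq = res_seq, chain = chain,
             charge = charge, rmin_half = rmin_half, epsilon = epsilon,
             gb_radius = gb_radius, gb_screen = gb_screen, mass = mass,
             stringsAsFactors = FALSE)
}

# 4-residue peptide backbone (N, CA, C, O per residue) plus one CB sidechain
# atom per residue, laid out along x with residues 3.8 A apart
peptide_topology <- function(n_res = 4L) {
  rows <- list()
  coords <- list()
  s <- 0L
  for (r in seq_len(n_res)) {
    x0 <- (r - 1L) * 3.8
    for (nm in c("N", "CA", "C", "O", "CB")) {
      s <- s + 1L
      el <- substr(nm, 1, 1)
      rows[[s]] <- toy_atom(s, nm, el, res_name = "ALA", res_seq = r)
      dx <- switch(nm, N = 0, CA = 0.8, C = 1.6, O = 2.2, CB = 0.8)
      dy <- if (nm == "CB") 1.5 else 0
      coords[[s]] <- c(x0 + dx, dy, 0)
    }
  }
  list(topology = topology(do.call(rbind, rows)),
       frame = do.call(rbind, coords))
}

# quadrature oracle for the HCT pairwise descreening integral:
# (1/4pi) * int over {x : |x - c| <= sj, |x| >= rho} |x|^-4 dV at |c| = r
hct_quadrature <- function(r, rho, sj) {
  f <- function(t) {
    ct <- (r^2 + t^2 - sj^2) / (2 * r * t)
    ct <- pmin(1, pmax(-1, ct))
    0.5 * t^-2 * (1 - ct)
  }
  if (rho >= r + sj) return(0)
  lo <- max(rho, abs(r - sj))
  hi <- r + sj
  total <- 0
  if (sj > r + rho) {  # sphere j engulfs the origin region
    a <- sj - r
    if (a > rho) total <- total + integrate(function(t) t^-2, rho, a)$value
    lo <- max(rho, a)
  }
  total + integrate(f, lo, hi, rel.tol = 1e-12)$value
}

# independent quaternion-method RMSD oracle (Kearsley); returns the minimal
# RMSD of mobile onto reference without using the package's Kabsch code
quaternion_rmsd <- function(mobile, reference) {
  xm <- sweep(mobile, 2, colMeans(mobile))
  xr <- sweep(reference, 2, colMeans(reference))
  xp <- xr + xm
  xmn <- xr - xm
  K <- matrix(0, 4, 4)
  for (k in seq_len(nrow(xm))) {
    p <- xp[k, ]; m <- xmn[k, ]
    A <- rbind(c(0, -m[1], -m[2], -m[3]),
               c(m[1], 0, -p[3], p[2]),
               c(m[2], p[3], 0, -p[1]),
               c(m[3], -p[2], p[1], 0))
    K <- K + crossprod(A)
  }
  lam_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, lam_min / nrow(xm)))
}

# frozen host-guest system shared by several test files
hg_system <- function() make_host_guest()

.ncols_struct <- function() c("serial", "name", "element", "res_name", "res_seq", "chain")
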