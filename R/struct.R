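# Structural analyses: Kabsch superposition, RMSD series, geometric
# hydrogen-bond detection and occupancy, and distance time series.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation fitting `mobile` onto `reference`
#' over `fit_subset`, solved by singular value decomposition with the
#' proper-rotation (det = +1) correction. All mobile atoms are transformed.
#'
#' @param mobile,reference N x 3 coordinate matrices (A).
#' @param fit_subset atom indices used for the fit (default: all); at least
#'   3 non-collinear atoms.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `fitted`
#'   (N x 3 transformed mobile coordinates), `rmsd_fit` (RMSD over the fit
#'   subset after superposition).
#' @export
kabsch_superpose <- function(mobile, reference, fit_subset = seq_len(nrow(mobile))) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  if (length(fit_subset) < 3L) stop("need at least 3 fit atoms")
  mf <- mobile[fit_subset, , drop = FALSE]
  rf <- reference[fit_subset, , drop = FALSE]
  mc <- colMeans(mf)
  rc <- colMeans(rf)
  A <- sweep(mf, 2L, mc)
  B <- sweep(rf, 2L, rc)
  sv <- svd(crossprod(A, B))   # t(A) %*% B
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    stop("degenerate fit set: fit atoms are collinear or coincident")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(sweep(mobile, 2L, mc) %*% t(R), 2L, rc, "+")
  dfit <- fitted[fit_subset, , drop = FALSE] - rf
  list(rotation = R, translation = as.vector(rc - R %*% mc),
       fitted = fitted, rmsd_fit = sqrt(mean(rowSums(dfit * dfit))))
}

.rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series with superposition on a fit subset
#'
#' Each frame is superposed on the reference frame using `fit_subset`
#' (protein backbone, typically) and the RMSD is then measured over
#' `measure_subset` without refitting, which is what makes pocket- and
#' ligand-RMSD curves well-defined.
#'
#' @param traj a [trajectory()].
#' @param fit_subset,measure_subset atom index vectors.
#' @param reference_frame frame index the series is measured against.
#' @param window optional frame-index vector over which `mean`/`sd`
#'   (sample sd, n - 1) are reported; default: all frames.
#' @return list with `rmsd` (per frame, A), `mean`, `sd`.
#' @export
rmsd_series <- function(traj, fit_subset, measure_subset = fit_subset,
                        reference_frame = 1L, window = NULL) {
  if (length(fit_subset) == 0L || length(measure_subset) == 0L) {
    stop("fit and measure subsets must be non-empty")
  }
  ref <- traj$frames[[reference_frame]]
  r <- vapply(seq_len(n_frames(traj)), function(k) {
    fit <- kabsch_superpose(traj$frames[[k]], ref, fit_subset)
    .rmsd_of(fit$fitted[measure_subset, , drop = FALSE],
             ref[measure_subset, , drop = FALSE])
  }, numeric(1))
  w <- if (is.null(window)) seq_along(r) else window
  list(rmsd = r, mean = mean(r[w]), sd = stats::sd(r[w]))
}

## ---------------------------------------------------------------------------
## Hydrogen bonds

# donor heavy atoms with their bonded hydrogens, from the bond table
.donor_hydrogens <- function(top, donor_idx) {
  at <- top$atoms
  b <- top$bonds
  out <- list()
  for (d in donor_idx) {
    if (at$element[d] == "H") next
    hs <- c(b$j[b$i == d], b$i[b$j == d])
    hs <- hs[at$element[hs] == "H"]
    if (length(hs) == 0L) next   # donor without bonded hydrogen: skipped
    out[[length(out) + 1L]] <- cbind(d, hs)
  }
  if (length(out) == 0L) matrix(integer(0), ncol = 2L) else do.call(rbind, out)
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criteria: donor-acceptor distance strictly below `d_max` and
#' donor-hydrogen-acceptor angle (measured at the hydrogen) strictly above
#' `angle_min`. Hydrogens are assigned to donors through the topology bond
#' table; donors without a bonded hydrogen are skipped.
#'
#' @param frame N x 3 coordinates (A).
#' @param top a [topology()] with a bond table.
#' @param donors,acceptors atom index vectors (heavy atoms; hydrogens in
#'   `donors` are ignored).
#' @param d_max donor-acceptor cutoff (A), default 3.5.
#' @param angle_min angle cutoff (degrees), default 120.
#' @return data.frame with `donor`, `hydrogen`, `acceptor` (atom indices),
#'   `distance` (A), `angle` (degrees).
#' @export
find_hbonds <- function(frame, top, donors, acceptors, d_max = 3.5,
                        angle_min = 120) {
  dh <- .donor_hydrogens(top, donors)
  at <- top$atoms
  acceptors <- acceptors[at$element[acceptors] != "H"]
  hits <- list()
  for (k in seq_len(nrow(dh))) {
    d <- dh[k, 1]; h <- dh[k, 2]
    for (a in acceptors) {
      if (a == d || a == h) next
      dv <- frame[a, ] - frame[d, ]
      dist <- sqrt(sum(dv * dv))
      if (dist >= d_max) next
      u <- frame[d, ] - frame[h, ]
      v <- frame[a, ] - frame[h, ]
      ct <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
      ang <- acos(min(1, max(-1, ct))) * 180 / pi
      if (ang <= angle_min) next
      hits[[length(hits) + 1L]] <- data.frame(donor = d, hydrogen = h,
                                              acceptor = a, distance = dist,
                                              angle = ang)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, hits)
}

.atom_label <- function(top, idx) {
  at <- top$atoms
  rn <- paste0(substr(at$res_name[idx], 1, 1),
               tolower(substring(at$res_name[idx], 2)))
  sprintf("%s%d-%s", rn, at$res_seq[idx], at$name[idx])
}

#' Hydrogen-bond occupancy and mean distance over a trajectory
#'
#' For every donor/acceptor atom pair that passes the geometric criteria in
#' at least one frame: occupancy as the percentage of frames in which the
#' pair passes (via any of the donor's hydrogens), and the mean
#' donor-acceptor distance over those passing frames only. Pairs that never
#' pass are omitted.
#'
#' @inheritParams find_hbonds
#' @param traj a [trajectory()].
#' @param frames frame indices to analyze (default: all).
#' @return data.frame with `donor_label`, `acceptor_label`, `occupancy`
#'   (percent), `mean_distance` (A), sorted by decreasing occupancy.
#' @export
hbond_occupancy <- function(traj, donors, acceptors, frames = NULL,
                            d_max = 3.5, angle_min = 120) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) < 1L) stop("need at least one frame")
  top <- traj$topology
  tally <- new.env(parent = emptyenv())
  for (fi in frames) {
    hb <- find_hbonds(traj$frames[[fi]], top, donors, acceptors, d_max, angle_min)
    if (nrow(hb) == 0L) next
    # one count per donor/acceptor pair per frame, shortest distance kept
    key <- paste(hb$donor, hb$acceptor)
    for (ku in unique(key)) {
      dmin <- min(hb$distance[key == ku])
      prev <- tally[[ku]]
      tally[[ku]] <- if (is.null(prev)) c(1, dmin) else prev + c(1, dmin)
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0L) {
    return(data.frame(donor_label = character(0), acceptor_label = character(0),
                      occupancy = numeric(0), mean_distance = numeric(0)))
  }
  parts <- do.call(rbind, strsplit(keys, " "))
  cnt <- t(vapply(keys, function(k) tally[[k]], numeric(2)))
  out <- data.frame(donor_label = .atom_label(top, as.integer(parts[, 1])),
                    acceptor_label = .atom_label(top, as.integer(parts[, 2])),
                    occupancy = 100 * cnt[, 1] / length(frames),
                    mean_distance = cnt[, 2] / cnt[, 1],
                    stringsAsFactors = FALSE)
  out[order(-out$occupancy, out$donor_label), , drop = FALSE]
}

#' Mean interatomic distance over a frame window
#'
#' @param traj a [trajectory()].
#' @param atom_a,atom_b atom indices.
#' @param window frame indices (default: all); must be non-empty.
#' @return list with `series` (per-frame distances over `window`, A) and
#'   `mean`.
#' @export
distance_series <- function(traj, atom_a, atom_b, window = NULL) {
  n <- n_atoms(traj$topology)
  if (atom_a < 1L || atom_a > n || atom_b < 1L || atom_b > n) {
    stop("atom index out of range")
  }
  if (is.null(window)) window <- seq_len(n_frames(traj))
  if (length(window) == 0L) stop("empty frame window")
  d <- vapply(window, function(k) {
    dv <- traj$frames[[k]][atom_a, ] - traj$frames[[k]][atom_b, ]
    sqrt(sum(dv * dv))
  }, numeric(1))
  list(series = d, mean = mean(d))
}
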