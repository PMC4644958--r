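# Potential of mean force from segmented bidirectional steered-work samples.
#
# The primary estimator is the half-exponential-average ratio of the
# Brownian-dynamics fluctuation-dissipation theorem:
#   dG(A->r) = -kB T ln( <exp(-W_F/(2 kB T))>_F / <exp(-W_R/(2 kB T))>_R )
# where W_F is the work done steering from A to r along a forward path and
# W_R the work done steering from r back to A along a reverse path. On
# Crooks-consistent Gaussian work distributions with equal forward/reverse
# variance the estimator is exact in expectation, which is the regime the
# synthetic work sampler generates. Jarzynski and Bennett-acceptance-ratio
# estimators are provided as cross-checks.

.logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# weighted variant used by the multinomial-weight bootstrap (weights sum to
# the sample size, so this equals .logmeanexp on the resampled vector)
.wlogmeanexp <- function(x, w) {
  m <- max(x)
  m + log(sum(w * exp(x - m)) / sum(w))
}

#' BD-FDT bidirectional free-energy estimate
#'
#' @param forward_works works W_F (kcal/mol) along forward paths A -> r.
#' @param reverse_works works W_R (kcal/mol) along reverse paths r -> A
#'   (recorded in the r -> A direction, used as-is).
#' @param temperature K.
#' @return free-energy difference G(r) - G(A) in kcal/mol, evaluated with
#'   log-sum-exp stabilization.
#' @export
bdfdt <- function(forward_works, reverse_works, temperature = 300) {
  if (length(forward_works) == 0L || length(reverse_works) == 0L) {
    stop("forward and reverse work lists must be non-empty")
  }
  kt <- KB_KCAL * temperature
  -kt * (.logmeanexp(-forward_works / (2 * kt)) -
           .logmeanexp(-reverse_works / (2 * kt)))
}

#' Jarzynski exponential-average estimate
#'
#' @param works works (kcal/mol) along paths in one direction.
#' @param temperature K.
#' @return `-kB T ln <exp(-W/kB T)>` in kcal/mol.
#' @export
jarzynski <- function(works, temperature = 300) {
  if (length(works) == 0L) stop("work list must be non-empty")
  kt <- KB_KCAL * temperature
  -kt * .logmeanexp(-works / kt)
}

#' Bennett acceptance ratio estimate
#'
#' Self-consistent BAR solution for bidirectional work data, with reverse
#' works recorded in the r -> A direction (the Crooks reverse-work variable
#' is their negative). Solved by root bracketing to `tol`.
#'
#' @inheritParams bdfdt
#' @param tol solver tolerance (kcal/mol).
#' @return free-energy difference in kcal/mol.
#' @export
bar <- function(forward_works, reverse_works, temperature = 300, tol = 1e-8) {
  if (length(forward_works) == 0L || length(reverse_works) == 0L) {
    stop("forward and reverse work lists must be non-empty")
  }
  beta <- 1 / (KB_KCAL * temperature)
  .bar_solve(forward_works, reverse_works, beta, tol)
}

# BAR self-consistency solved by safeguarded Newton iteration on the
# monotone residual; optional multinomial weights support the bootstrap
.bar_solve <- function(wf, wr, beta, tol = 1e-8, wgt_f = NULL, wgt_r = NULL) {
  if (is.null(wgt_f)) wgt_f <- rep(1, length(wf))
  if (is.null(wgt_r)) wgt_r <- rep(1, length(wr))
  M <- log(sum(wgt_f) / sum(wgt_r))
  fermi <- function(x) stats::plogis(-x)
  g <- function(dg) {
    ff <- fermi(M + beta * (wf - dg))
    fr <- fermi(-M + beta * (wr + dg))
    list(val = sum(wgt_f * ff) - sum(wgt_r * fr),
         deriv = beta * (sum(wgt_f * ff * (1 - ff)) + sum(wgt_r * fr * (1 - fr))))
  }
  lo <- min(-wr, wf) - 1
  hi <- max(-wr, wf) + 1
  for (k in 1:60) {
    if (g(lo)$val < 0 && g(hi)$val > 0) break
    lo <- lo - 2^k
    hi <- hi + 2^k
  }
  if (!(g(lo)$val < 0 && g(hi)$val > 0)) {
    stop(sprintf("BAR did not converge: no bracketing interval, residual %.3g",
                 g(hi)$val))
  }
  dg <- (lo + hi) / 2
  for (it in 1:100) {
    cur <- g(dg)
    if (cur$val > 0) hi <- dg else lo <- dg
    if (abs(cur$val) < 1e-300 || hi - lo < tol) break
    step <- if (cur$deriv > 0) cur$val / cur$deriv else NA_real_
    cand <- dg - step
    dg <- if (is.finite(cand) && cand > lo && cand < hi) cand else (lo + hi) / 2
    if (abs(step) < tol && is.finite(step)) break
  }
  dg
}

## ---------------------------------------------------------------------------
## Work-sample containers

#' Read/write steered-work samples (TSV)
#'
#' Columns: `segment` (integer), `direction` (`forward`/`reverse`), `path`
#' (integer), `displacement_A`, `work_kcal_mol` (cumulative work along that
#' path; reverse paths start at the segment's far end with zero work).
#'
#' @param path TSV file path.
#' @return data.frame of work samples.
#' @export
read_works <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("segment", "direction", "path", "displacement_A", "work_kcal_mol")
  if (!all(need %in% names(df))) {
    stop("work file lacks column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  names(df)[match(c("displacement_A", "work_kcal_mol"), names(df))] <-
    c("displacement", "work")
  .validate_works(df)
  df
}

#' @rdname read_works
#' @param works work-sample data.frame.
#' @export
write_works <- function(works, path) {
  .validate_works(works)
  out <- data.frame(segment = works$segment, direction = works$direction,
                    path = works$path, displacement_A = works$displacement,
                    work_kcal_mol = works$work)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_works <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(df$direction %in% c("forward", "reverse"))) {
    stop("direction must be 'forward' or 'reverse'")
  }
  if (!all(is.finite(df$work)) || !all(is.finite(df$displacement))) {
    stop("non-finite work or displacement values")
  }
  invisible(df)
}

# organize one segment's samples into forward/reverse work matrices over a
# common displacement grid. Reverse cumulative works (zero at the far end)
# are re-indexed so row r holds W_{r->A} = W_total - W(B->r).
.prepare_segment <- function(seg_df) {
  ref_grid <- sort(unique(seg_df$displacement[
    seg_df$direction == seg_df$direction[1] & seg_df$path == seg_df$path[1]]))
  ng <- length(ref_grid)
  ord <- order(seg_df$direction, seg_df$path, seg_df$displacement)
  consistent <- (nrow(seg_df) %% ng == 0L) &&
    identical(rep(ref_grid, nrow(seg_df) %/% ng), seg_df$displacement[ord])
  if (!consistent) {
    message("inconsistent displacement grids across paths; resampling linearly onto the first path's grid")
  }
  collect <- function(dir) {
    sub <- seg_df[seg_df$direction == dir, , drop = FALSE]
    if (nrow(sub) == 0L) stop("segment needs at least one ", dir, " path")
    if (consistent) {
      ord <- order(sub$path, sub$displacement)
      return(matrix(sub$work[ord], ncol = length(ref_grid), byrow = TRUE))
    }
    paths <- unique(sub$path)
    t(vapply(paths, function(p) {
      pp <- sub[sub$path == p, , drop = FALSE]
      pp <- pp[order(pp$displacement), , drop = FALSE]
      stats::approx(pp$displacement, pp$work, xout = ref_grid, rule = 2)$y
    }, numeric(length(ref_grid))))
  }
  Wf <- collect("forward")
  Wr_cum <- collect("reverse")
  # reverse path cumulative work is stored against displacement with zero at
  # the far end; work from grid point r back to A is total minus work(B->r)
  Wr <- Wr_cum[, 1L] - Wr_cum
  list(grid = ref_grid, forward = Wf, reverse = Wr)
}

#' Within-segment free-energy profile from bidirectional works
#'
#' Applies [bdfdt()] at every grid point r of one pulling segment, using the
#' forward works A -> r and the reverse works r -> A (reverse cumulative
#' work re-indexed from the segment's far end).
#'
#' @param seg_df work samples of a single segment (see [read_works()]).
#' @param temperature K.
#' @return data.frame with `displacement` and `dg` (kcal/mol, zero at the
#'   segment entry), with attributes `segment`, `n_forward`, `n_reverse`.
#' @export
segment_pmf <- function(seg_df, temperature = 300) {
  if (length(unique(seg_df$segment)) != 1L) {
    stop("segment_pmf expects samples of exactly one segment")
  }
  prep <- .prepare_segment(seg_df)
  dg <- vapply(seq_along(prep$grid), function(g) {
    bdfdt(prep$forward[, g], prep$reverse[, g], temperature)
  }, numeric(1))
  out <- data.frame(displacement = prep$grid, dg = dg)
  attr(out, "segment") <- seg_df$segment[1]
  attr(out, "n_forward") <- nrow(prep$forward)
  attr(out, "n_reverse") <- nrow(prep$reverse)
  out
}

#' Stitch contiguous segment profiles into a global PMF
#'
#' Adds each segment's profile onto the accumulated end value of the
#' previous one; segments must tile the displacement axis without gaps or
#' overlaps. The profile is anchored at zero at the first grid point.
#'
#' @param segments list of [segment_pmf()] outputs, any order.
#' @param tol boundary matching tolerance (A).
#' @return data.frame with `displacement`, `dg`.
#' @export
stitch <- function(segments, tol = 1e-6) {
  if (length(segments) == 0L) stop("no segments to stitch")
  starts <- vapply(segments, function(s) s$displacement[1], numeric(1))
  segments <- segments[order(starts)]
  out <- segments[[1]]
  offset <- 0
  if (length(segments) > 1L) {
    for (k in 2:length(segments)) {
      prev_end <- out$displacement[nrow(out)]
      s <- segments[[k]]
      if (abs(s$displacement[1] - prev_end) > tol) {
        stop(sprintf("segments do not tile the displacement axis: %g A then %g A (gap or overlap)",
                     prev_end, s$displacement[1]))
      }
      offset <- out$dg[nrow(out)]
      add <- data.frame(displacement = s$displacement[-1], dg = s$dg[-1] + offset)
      out <- rbind(out, add)
    }
  }
  out$dg <- out$dg - out$dg[1]
  out
}

#' Full PMF estimation with bootstrap uncertainties
#'
#' Splits the work table by segment, estimates each segment profile with
#' [segment_pmf()], stitches, and attaches per-point bootstrap standard
#' errors from resampling whole paths within each segment/direction.
#'
#' @param works work-sample data.frame (see [read_works()]).
#' @param temperature K.
#' @param n_boot bootstrap resamples over paths (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `pmf_profile`: data.frame with `displacement`,
#'   `dg`, `se`; attributes `endpoint`, `endpoint_ci` (2.5/97.5 percentile),
#'   `n_boot`.
#' @export
pmf_profile <- function(works, temperature = 300, n_boot = 200, seed = NULL) {
  .validate_works(works)
  segs <- split(works, works$segment)
  preps <- lapply(segs, .prepare_segment)
  kt <- KB_KCAL * temperature
  # precompute column-stabilized exp(-W/(2kT)) matrices so both the point
  # estimate and every bootstrap replicate are colMeans over resampled rows
  expmats <- lapply(preps, function(prep) {
    mk <- function(W) {
      x <- -W / (2 * kt)
      shift <- apply(x, 2L, max)
      list(E = exp(sweep(x, 2L, shift)), shift = shift)
    }
    list(f = mk(prep$forward), r = mk(prep$reverse), grid = prep$grid)
  })
  seg_dg <- function(em, wf = NULL, wr = NULL) {
    # path resampling enters as multinomial weights (exactly equivalent to
    # index resampling, without copying the work matrices)
    mf <- if (is.null(wf)) colMeans(em$f$E) else
      as.vector(wf %*% em$f$E) / sum(wf)
    mr <- if (is.null(wr)) colMeans(em$r$E) else
      as.vector(wr %*% em$r$E) / sum(wr)
    -kt * ((log(mf) + em$f$shift) - (log(mr) + em$r$shift))
  }
  profiles <- lapply(expmats, function(em) {
    data.frame(displacement = em$grid, dg = seg_dg(em))
  })
  out <- stitch(profiles)
  endpoint <- out$dg[nrow(out)]
  se <- rep(NA_real_, nrow(out))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    boot <- matrix(NA_real_, n_boot, nrow(out))
    for (b in seq_len(n_boot)) {
      bp <- lapply(expmats, function(em) {
        nf <- nrow(em$f$E); nr <- nrow(em$r$E)
        wf <- tabulate(sample.int(nf, nf, replace = TRUE), nf)
        wr <- tabulate(sample.int(nr, nr, replace = TRUE), nr)
        data.frame(displacement = em$grid, dg = seg_dg(em, wf, wr))
      })
      boot[b, ] <- stitch(bp)$dg
    }
    se <- apply(boot, 2L, stats::sd)
    ci <- stats::quantile(boot[, ncol(boot)], c(0.025, 0.975), names = FALSE)
  }
  out$se <- se
  structure(out, class = c("pmf_profile", "data.frame"),
            endpoint = endpoint, endpoint_ci = ci, n_boot = n_boot)
}

#' Compare bidirectional estimators on the same work data
#'
#' Evaluates the BD-FDT and BAR whole-path estimates (sum of per-segment
#' endpoint estimates) with percentile bootstrap confidence intervals from
#' shared path resampling.
#'
#' @inheritParams pmf_profile
#' @return data.frame with rows `bdfdt` and `bar`: `dg`, `ci_lo`, `ci_hi`.
#' @export
compare_estimators <- function(works, temperature = 300, n_boot = 200, seed = NULL) {
  .validate_works(works)
  preps <- lapply(split(works, works$segment), .prepare_segment)
  kt <- KB_KCAL * temperature
  # only the segment-endpoint works enter the whole-path estimates
  endw <- lapply(preps, function(prep) {
    g <- length(prep$grid)
    list(wf = prep$forward[, g], wr = prep$reverse[, g])
  })
  pair_est <- function(ew, wgt_f = NULL, wgt_r = NULL) {
    wf1 <- if (is.null(wgt_f)) rep(1, length(ew$wf)) else wgt_f
    wr1 <- if (is.null(wgt_r)) rep(1, length(ew$wr)) else wgt_r
    c(-kt * (.wlogmeanexp(-ew$wf / (2 * kt), wf1) -
               .wlogmeanexp(-ew$wr / (2 * kt), wr1)),
      .bar_solve(ew$wf, ew$wr, 1 / kt, wgt_f = wf1, wgt_r = wr1))
  }
  point <- rowSums(vapply(endw, pair_est, numeric(2)))
  names(point) <- c("bdfdt", "bar")
  ci <- matrix(NA_real_, 2L, 2L, dimnames = list(c("bdfdt", "bar"), NULL))
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    bmat <- matrix(NA_real_, n_boot, 2L)
    for (b in seq_len(n_boot)) {
      tot <- c(0, 0)
      for (ew in endw) {
        nf <- length(ew$wf); nr <- length(ew$wr)
        tot <- tot + pair_est(ew, tabulate(sample.int(nf, nf, TRUE), nf),
                              tabulate(sample.int(nr, nr, TRUE), nr))
      }
      bmat[b, ] <- tot
    }
    ci[1, ] <- stats::quantile(bmat[, 1], c(0.025, 0.975), names = FALSE)
    ci[2, ] <- stats::quantile(bmat[, 2], c(0.025, 0.975), names = FALSE)
  }
  data.frame(estimator = c("bdfdt", "bar"), dg = as.numeric(point),
             ci_lo = ci[, 1], ci_hi = ci[, 2], stringsAsFactors = FALSE)
}
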