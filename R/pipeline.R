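# Snapshot selection, per-snapshot evaluation, aggregation with the
# sigma = sd/sqrt(N) convention, cross-compound summaries, and correlation
# with experiment.

.COMPONENTS <- c("e_ele", "e_vdw", "g_pol", "g_nonpol",
                 "g_ele_pol", "g_vdw_nonpol", "h")

#' Select evenly spaced snapshots from a trajectory window
#'
#' Frames are taken at `interval_ps` spacing inside the half-open window
#' `(start, end]` nanoseconds (so a (15, 20] ns window at 10 ps yields the
#' 500 snapshots of the standard protocol on a 1 ps-saved trajectory).
#'
#' @param traj a [trajectory()] with times in ps.
#' @param window_ns numeric length-2, `(start, end)` in ns.
#' @param interval_ps snapshot spacing in ps.
#' @param expected_n optional count check; a mismatch is a configuration
#'   error.
#' @return integer frame indices.
#' @export
select_snapshots <- function(traj, window_ns, interval_ps, expected_n = NULL) {
  stopifnot(length(window_ns) == 2L, window_ns[2] > window_ns[1], interval_ps > 0)
  if (window_ns[1] * 1000 + interval_ps > window_ns[2] * 1000 + 1e-9) {
    stop("configuration error: window spans less than one snapshot interval")
  }
  wanted <- seq(window_ns[1] * 1000 + interval_ps, window_ns[2] * 1000,
                by = interval_ps)
  idx <- match(TRUE, abs(traj$times - wanted[1]) < 1e-6)
  hits <- vapply(wanted, function(w) {
    k <- which(abs(traj$times - w) < 1e-6)
    if (length(k) == 1L) k else NA_integer_
  }, integer(1))
  if (anyNA(hits)) {
    stop(sprintf("configuration error: trajectory does not cover the window at %g ps spacing (first missing snapshot at %g ps)",
                 interval_ps, wanted[which(is.na(hits))[1]]))
  }
  if (!is.null(expected_n) && length(hits) != expected_n) {
    stop(sprintf("configuration error: window yields %d snapshots, expected %d",
                 length(hits), expected_n))
  }
  hits
}

#' Aggregate per-snapshot breakdowns into a Table-1-style result
#'
#' Means and standard errors per component with the `sigma = sd / sqrt(N)`
#' convention (sample sd, n - 1 denominator). The binding free energy is the
#' enthalpy mean plus the mean entropy term.
#'
#' @param breakdowns list of [energy_breakdown()] objects (or a data.frame
#'   with the component columns), `n >= 2`.
#' @param entropy_terms optional numeric vector of per-snapshot `-T dS`
#'   values (kcal/mol), `n >= 2` when given.
#' @return object of class `aggregate_result`: list with `mean`, `sem`
#'   (named numeric over components incl. `minus_t_ds`, `g_bind`), `n`,
#'   `n_entropy`.
#' @export
aggregate_breakdowns <- function(breakdowns, entropy_terms = NULL) {
  df <- if (is.data.frame(breakdowns)) breakdowns else {
    as.data.frame(do.call(rbind, lapply(breakdowns, function(b) {
      unlist(b[.COMPONENTS])
    })))
  }
  if (nrow(df) == 0L) stop("no snapshots to aggregate")
  if (nrow(df) < 2L) stop("sem undefined for fewer than 2 snapshots")
  mu <- vapply(df[.COMPONENTS], mean, numeric(1))
  se <- vapply(df[.COMPONENTS], function(x) stats::sd(x) / sqrt(length(x)), numeric(1))
  n_ent <- length(entropy_terms)
  if (!is.null(entropy_terms)) {
    if (n_ent < 2L) stop("sem undefined for fewer than 2 entropy snapshots")
    mu["minus_t_ds"] <- mean(entropy_terms)
    se["minus_t_ds"] <- stats::sd(entropy_terms) / sqrt(n_ent)
    mu["g_bind"] <- mu[["h"]] + mu[["minus_t_ds"]]
    se["g_bind"] <- sqrt(se[["h"]]^2 + se[["minus_t_ds"]]^2)
  }
  aggregate_result(mu, se, n = nrow(df), n_entropy = n_ent)
}

#' Construct an aggregate result directly from means and standard errors
#'
#' Used by [aggregate_breakdowns()] and by the packaged printed-table
#' fixture. Derived components missing from `mean` are filled in from the
#' composite identities.
#'
#' @param mean,sem named numeric vectors over (a subset of) `e_ele`,
#'   `e_vdw`, `g_pol`, `g_nonpol`, `g_ele_pol`, `g_vdw_nonpol`, `h`,
#'   `minus_t_ds`, `g_bind`.
#' @param n,n_entropy snapshot counts behind the enthalpy and entropy
#'   averages.
#' @return object of class `aggregate_result`.
#' @export
aggregate_result <- function(mean, sem, n, n_entropy = 0L) {
  fill <- function(v) {
    if (is.na(v["g_ele_pol"]) && !anyNA(v[c("e_ele", "g_pol")])) {
      v["g_ele_pol"] <- v[["e_ele"]] + v[["g_pol"]]
    }
    if (is.na(v["g_vdw_nonpol"]) && !anyNA(v[c("e_vdw", "g_nonpol")])) {
      v["g_vdw_nonpol"] <- v[["e_vdw"]] + v[["g_nonpol"]]
    }
    if (is.na(v["h"]) && !anyNA(v[c("e_ele", "e_vdw", "g_pol", "g_nonpol")])) {
      v["h"] <- sum(v[c("e_ele", "e_vdw", "g_pol", "g_nonpol")])
    }
    if (is.na(v["g_bind"]) && !anyNA(v[c("h", "minus_t_ds")])) {
      v["g_bind"] <- v[["h"]] + v[["minus_t_ds"]]
    }
    v
  }
  all_comp <- c(.COMPONENTS, "minus_t_ds", "g_bind")
  mu <- stats::setNames(rep(NA_real_, length(all_comp)), all_comp)
  se <- mu
  mu[names(mean)] <- mean
  se[names(sem)] <- sem
  mu <- fill(mu)
  structure(list(mean = mu, sem = se, n = n, n_entropy = n_entropy),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat(sprintf("aggregate over %d snapshots (%d for entropy):\n", x$n, x$n_entropy))
  for (k in names(x$mean)) {
    if (!is.na(x$mean[[k]])) {
      cat(sprintf("  %-13s %9.3f +- %.3f kcal/mol\n", k, x$mean[[k]],
                  if (is.na(x$sem[[k]])) 0 else x$sem[[k]]))
    }
  }
  invisible(x)
}

#' Collect per-compound aggregates into a compound table
#'
#' @param aggregates named list of [aggregate_result()] objects; labels must
#'   be unique.
#' @param experimental optional named numeric of experimental binding free
#'   energies (kcal/mol); `NA` where unmeasured.
#' @return object of class `compound_table`.
#' @export
compound_table <- function(aggregates, experimental = NULL) {
  labels <- names(aggregates)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == "")) {
    stop("compound labels must be unique and non-empty")
  }
  exp_vec <- stats::setNames(rep(NA_real_, length(labels)), labels)
  if (!is.null(experimental)) exp_vec[names(experimental)] <- experimental
  structure(list(compounds = aggregates, experimental = exp_vec),
            class = "compound_table")
}

#' Extract one component across the compounds of a table
#' @param table a [compound_table()].
#' @param component component name, additionally `"exp"` for the
#'   experimental column.
#' @param compounds optional label subset (order respected).
#' @return named numeric vector.
#' @export
table_component <- function(table, component, compounds = NULL) {
  stopifnot(inherits(table, "compound_table"))
  labels <- if (is.null(compounds)) names(table$compounds) else compounds
  if (!all(labels %in% names(table$compounds))) stop("unknown compound label")
  if (component == "exp") return(table$experimental[labels])
  vapply(table$compounds[labels], function(a) a$mean[[component]], numeric(1))
}

#' Cross-compound mean and spread of one energy component
#'
#' The spread is the sample standard deviation (n - 1 denominator), the
#' convention that reproduces the printed cross-compound scatter of the
#' reference table.
#'
#' @inheritParams table_component
#' @return list with `mean`, `sd`, `n`.
#' @export
summarize_across_compounds <- function(table, component, compounds = NULL) {
  x <- table_component(table, component, compounds)
  if (length(x) < 2L) stop("need at least 2 compounds to summarize")
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Pearson correlation between per-compound quantities
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @param mode `"signed"` (default) or `"absolute"` (returns `|r|`).
#' @return Pearson product-moment correlation coefficient.
#' @export
correlate <- function(x, y, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  r <- stats::cor(x, y)
  if (mode == "absolute") abs(r) else r
}

#' Experimental binding free energy from a dissociation constant
#' @param kd dissociation constant (M).
#' @param temperature K.
#' @return `RT ln(Kd)` in kcal/mol.
#' @export
dg_from_kd <- function(kd, temperature = 300) {
  if (any(kd <= 0)) stop("Kd must be > 0")
  R_KCAL * temperature * log(kd)
}

#' Run the MM-GBSA pipeline over trajectory snapshots
#'
#' Evaluates [snapshot_breakdown()] on every selected frame, optionally the
#' normal-mode entropy term on an evenly spaced subset (default 125 frames,
#' the standard protocol's entropy sampling), and aggregates with
#' [aggregate_breakdowns()]. Per-residue decomposition means are returned
#' when requested.
#'
#' @param traj a parameterized [trajectory()].
#' @param partition a [complex_partition()].
#' @param frames frame indices to evaluate (default: all).
#' @param entropy compute the `-T dS` term.
#' @param n_entropy entropy snapshot count (evenly spaced among `frames`).
#' @param entropy_tol minimizer gradient tolerance (kcal/mol/A) for the
#'   pre-NMA minimizations.
#' @param temperature K.
#' @param decompose also average [per_residue_decomposition()] over frames.
#' @param probe,n_points,gamma,beta see [snapshot_breakdown()].
#' @return list with `aggregate` (an [aggregate_result()]), `breakdowns`
#'   (data.frame, one row per frame), `entropy_terms`, and optionally
#'   `decomposition` (data.frame of per-residue means).
#' @export
mmgbsa_run <- function(traj, partition, frames = seq_len(n_frames(traj)),
                       entropy = TRUE, n_entropy = 125, temperature = 300,
                       decompose = FALSE, probe = 1.4, n_points = 960,
                       gamma = 0.005, beta = 0.0, entropy_tol = 1e-6) {
  top <- traj$topology
  rows <- vector("list", length(frames))
  dec_sum <- NULL
  for (k in seq_along(frames)) {
    fr <- traj$frames[[frames[k]]]
    b <- snapshot_breakdown(fr, top, partition, probe, n_points, gamma, beta)
    rows[[k]] <- unlist(b[.COMPONENTS])
    if (decompose) {
      d <- per_residue_decomposition(fr, top, partition, probe, n_points, gamma, beta)
      if (is.null(dec_sum)) {
        dec_sum <- d
      } else {
        dec_sum[, -1] <- dec_sum[, -1] + d[, -1]
      }
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  ent <- NULL
  if (entropy) {
    ei <- frames[unique(round(seq(1, length(frames),
                                  length.out = min(n_entropy, length(frames)))))]
    species <- list(complex = sort(c(partition$receptor, partition$ligand)),
                    receptor = partition$receptor, ligand = partition$ligand)
    tops <- lapply(species, function(ix) subset_topology(top, ix))
    # consecutive snapshots relax into the same (or a nearby) basin, so each
    # species' minimization is warm-started from the previous minimum
    warm <- list(complex = NULL, receptor = NULL, ligand = NULL)
    ent <- vapply(ei, function(fi) {
      fr <- traj$frames[[fi]]
      s <- lapply(names(species), function(nm) {
        start <- if (is.null(warm[[nm]])) fr[species[[nm]], , drop = FALSE] else warm[[nm]]
        mz <- minimize_energy(start, tops[[nm]], tol = entropy_tol)
        warm[[nm]] <<- mz$frame
        nma_entropy(mz$frame, tops[[nm]], temperature, minimize = FALSE)
      })
      binding_entropy_term(s[[1]], s[[2]], s[[3]], temperature)
    }, numeric(1))
  }
  out <- list(aggregate = aggregate_breakdowns(df, ent),
              breakdowns = df, entropy_terms = ent)
  if (decompose) {
    dec_sum[, -1] <- dec_sum[, -1] / length(frames)
    out$decomposition <- dec_sum
  }
  out
}
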