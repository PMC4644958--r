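# Packaged fixture: the published per-compound MM-GBSA component table for
# the nine 14-3-3 sigma inhibitors (R1..R9), means with sigma = sd/sqrt(N)
# standard errors over 500 snapshots (125 for the entropy term), plus the
# experimental binding free energies for R1..R8 (R9 was designed, not
# measured). All values in kcal/mol, stored verbatim as printed.

.TABLE1 <- local({
  compounds <- paste0("R", 1:9)
  mean_rows <- rbind(
    e_ele      = c(214.42, 152.11, 242.33, 246.06, 230.44, 267.29, 276.22, 316.32, 222.79),
    e_vdw      = c(-13.98, -6.73, -15.21, -13.68, -12.73, -14.30, -14.45, -13.73, -11.82),
    g_pol      = c(-247.44, -188.06, -268.85, -272.16, -256.08, -287.10, -295.70, -334.00, -254.20),
    g_nonpol   = c(-2.53, -2.23, -2.53, -2.51, -2.63, -2.48, -2.76, -2.69, -2.59),
    g_ele_pol  = c(-33.02, -35.95, -26.52, -26.10, -25.64, -19.81, -19.48, -17.68, -31.41),
    g_vdw_nonpol = c(-16.51, -8.96, -17.74, -16.19, -15.36, -16.78, -17.21, -16.42, -14.41),
    h          = c(-49.53, -44.91, -44.26, -42.29, -41.00, -36.59, -36.69, -34.10, -45.82),
    minus_t_ds = c(18.99, 19.85, 20.99, 19.90, 20.04, 20.33, 21.04, 21.37, 19.81),
    g_bind     = c(-30.54, -25.06, -23.27, -22.39, -20.96, -16.26, -15.65, -12.73, -26.01))
  sem_rows <- rbind(
    e_ele      = c(1.31, 2.12, 1.36, 1.33, 1.16, 1.29, 1.20, 1.20, 1.35),
    e_vdw      = c(0.23, 0.27, 0.23, 0.24, 0.22, 0.23, 0.23, 0.22, 0.23),
    g_pol      = c(1.12, 1.80, 1.15, 1.15, 1.03, 1.19, 1.10, 1.09, 1.19),
    g_nonpol   = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    g_ele_pol  = c(1.21, 1.96, 1.26, 1.24, 1.09, 1.24, 1.15, 1.15, 1.27),
    g_vdw_nonpol = c(0.12, 0.14, 0.12, 0.12, 0.11, 0.12, 0.12, 0.11, 0.12),
    h          = c(0.32, 0.42, 0.32, 0.31, 0.29, 0.24, 0.23, 0.23, 0.34),
    minus_t_ds = c(0.45, 0.34, 0.37, 0.48, 0.44, 0.45, 0.38, 0.32, 0.46),
    g_bind     = c(0.55, 0.58, 0.44, 0.55, 0.48, 0.48, 0.37, 0.36, 0.57))
  colnames(mean_rows) <- colnames(sem_rows) <- compounds
  exp_dg <- stats::setNames(
    c(-7.28, -6.62, -6.58, -6.27, -6.21, -6.17, -6.10, -5.19, NA), compounds)
  list(mean = mean_rows, sem = sem_rows, exp = exp_dg)
})

#' The packaged published compound table (R1..R9)
#'
#' Means and standard errors of every MM-GBSA component for the nine
#' inhibitor compounds, exactly as printed, plus experimental binding free
#' energies for R1..R8 (none exists for the designed compound R9). Intended
#' as input for [summarize_across_compounds()], [correlate()] and
#' [render_energy_table()].
#'
#' @return a [compound_table()].
#' @export
table1_fixture <- function() {
  t1 <- .TABLE1
  aggs <- lapply(colnames(t1$mean), function(cp) {
    aggregate_result(t1$mean[, cp], t1$sem[, cp], n = 500L, n_entropy = 125L)
  })
  names(aggs) <- colnames(t1$mean)
  compound_table(aggs, t1$exp)
}
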