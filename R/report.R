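# Rendering of compound tables and the command-line entry points.

.ROW_LABELS <- c(e_ele = "ΔE_ele", e_vdw = "ΔE_vdw",
                 g_pol = "ΔG_pol", g_nonpol = "ΔG_nonpol",
                 g_ele_pol = "ΔG_ele+pol",
                 g_vdw_nonpol = "ΔG_vdw+nonpol", h = "ΔH",
                 minus_t_ds = "-TΔS", g_bind = "ΔG_bind",
                 exp = "ΔG_exp")

.fmt2 <- function(x) ifelse(is.na(x), "null", formatC(x, format = "f", digits = 2))

#' Render a compound table as TSV text
#'
#' One row per energy component, two columns (mean, sigma) per compound,
#' 2-decimal fixed formatting (round half to even); missing experimental
#' values render as `null`.
#'
#' @param table a [compound_table()].
#' @return character vector of TSV lines.
#' @export
render_energy_table <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  labels <- names(table$compounds)
  if (length(labels) == 0L) stop("empty compound table")
  header <- c("Item", as.vector(rbind(paste0(labels, "_mean"),
                                      paste0(labels, "_sigma"))))
  lines <- paste(header, collapse = "\t")
  for (comp in names(.ROW_LABELS)) {
    if (comp == "exp") {
      cells <- as.vector(rbind(.fmt2(table$experimental[labels]), ""))
    } else {
      mu <- vapply(table$compounds[labels], function(a) a$mean[[comp]], numeric(1))
      se <- vapply(table$compounds[labels], function(a) a$sem[[comp]], numeric(1))
      cells <- as.vector(rbind(.fmt2(mu), .fmt2(se)))
    }
    lines <- c(lines, paste(c(.ROW_LABELS[[comp]], cells), collapse = "\t"))
  }
  lines
}

#' Parse a rendered compound table back into values
#'
#' Inverse of [render_energy_table()] at the rendered 2-decimal precision.
#'
#' @param lines character vector of TSV lines.
#' @return a [compound_table()].
#' @export
parse_energy_table <- function(lines) {
  cells <- strsplit(lines, "\t")
  header <- cells[[1]]
  labels <- unique(sub("_(mean|sigma)$", "", header[-1]))
  comp_of <- stats::setNames(names(.ROW_LABELS), .ROW_LABELS)
  mu <- matrix(NA_real_, length(.ROW_LABELS), length(labels),
               dimnames = list(names(.ROW_LABELS), labels))
  se <- mu
  n_cells <- 2L * length(labels)
  for (row in cells[-1]) {
    comp <- comp_of[[row[1]]]
    vals <- c(row[-1], rep("", n_cells))[seq_len(n_cells)]  # pad trailing blanks
    m <- suppressWarnings(as.numeric(vals[seq(1, n_cells, by = 2)]))
    s <- suppressWarnings(as.numeric(vals[seq(2, n_cells, by = 2)]))
    mu[comp, ] <- m
    se[comp, ] <- s
  }
  aggs <- lapply(labels, function(cp) {
    keep <- setdiff(rownames(mu), "exp")
    aggregate_result(mu[keep, cp], se[keep, cp], n = NA_integer_)
  })
  names(aggs) <- labels
  compound_table(aggs, stats::setNames(mu["exp", ], labels))
}

## ---------------------------------------------------------------------------
## Command-line interface

.cli_opts <- function(args) {
  opts <- list()
  pos <- character(0)
  k <- 1L
  while (k <= length(args)) {
    a <- args[k]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (k + 1L <= length(args) && !startsWith(args[k + 1L], "--")) {
        opts[[key]] <- args[k + 1L]
        k <- k + 2L
      } else {
        opts[[key]] <- TRUE
        k <- k + 1L
      }
    } else {
      pos <- c(pos, a)
      k <- k + 1L
    }
  }
  list(opts = opts, positional = pos)
}

.cli_need <- function(opts, keys) {
  missing_keys <- setdiff(keys, names(opts))
  if (length(missing_keys) > 0L) {
    stop("missing required option(s): ", paste0("--", missing_keys, collapse = ", "))
  }
}

.cli_manifest <- function(out_path, subcommand, opts) {
  manifest <- list(tool = "bindfe", version = as.character(utils::packageVersion("bindfe")),
                   subcommand = subcommand, options = opts,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paste0(out_path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.cli_load_system <- function(opts, ref_needed = TRUE) {
  traj <- read_pdb(opts$traj)
  traj <- merge_topology(traj, opts$topo)
  top <- traj$topology
  ref <- traj$frames[[1]]
  groups <- list()
  if (!is.null(opts$ligand)) {
    lig <- select_atoms(top, opts$ligand, ref = ref)
    rec <- setdiff(seq_len(n_atoms(top)), lig)
    groups <- list(ligand = lig, receptor = rec)
  }
  list(traj = traj, top = top, ref = ref, groups = groups)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `mmgbsa`, `hbonds`, `rmsd`, `pmf`, `report`.
#' Every option is `--key value`; outputs are TSV, and a JSON run manifest
#' (inputs, parameters, package version) is written next to each output.
#' Invoked by the `inst/cli/bindfe` Rscript wrapper; returns the exit status
#' (0 ok, 2 usage/parse error, 1 runtime error) instead of quitting, so it
#' is testable in-process.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: bindfe <simulate|mmgbsa|hbonds|rmsd|pmf|report> [--key value ...]")
    return(invisible(2L))
  }
  sub <- args[1]
  parsed <- .cli_opts(args[-1])
  opts <- parsed$opts
  status <- tryCatch({
    switch(sub,
      simulate = .cli_simulate(opts),
      mmgbsa = .cli_mmgbsa(opts),
      hbonds = .cli_hbonds(opts),
      rmsd = .cli_rmsd(opts),
      pmf = .cli_pmf(opts),
      report = .cli_report(opts),
      {
        message("unknown subcommand: ", sub)
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("parse error|missing required", conditionMessage(e))) 2L else 1L
  })
  invisible(as.integer(status))
}

.cli_simulate <- function(opts) {
  .cli_need(opts, c("out-prefix"))
  seed <- as.integer(opts$seed %||% 42)
  nfr <- as.integer(opts$frames %||% 500)
  sigma <- as.numeric(opts$sigma %||% 0.004)
  sys <- make_host_guest()
  traj <- jitter_trajectory(sys$frame, sys$topology, n_frames = nfr,
                            sigma = sigma, seed = seed)
  prefix <- opts[["out-prefix"]]
  write_pdb(traj, paste0(prefix, ".pdb"))
  write_topology(sys$topology, paste0(prefix, ".topology.json"))
  if (isTRUE(opts$works) || identical(opts$works, "true")) {
    works <- crooks_work_sampler(seed = seed + 1L)
    write_works(works, paste0(prefix, ".works.tsv"))
  }
  .cli_manifest(prefix, "simulate", opts)
  message(sprintf("wrote %s.pdb (%d frames, sigma %.3g A, seed %d)",
                  prefix, nfr, sigma, seed))
  0L
}

.cli_mmgbsa <- function(opts) {
  .cli_need(opts, c("traj", "topo", "ligand", "out"))
  sys <- .cli_load_system(opts)
  part <- complex_partition(sys$groups$receptor, sys$groups$ligand)
  frames <- seq_len(n_frames(sys$traj))
  if (!is.null(opts$window)) {
    w <- as.numeric(strsplit(opts$window, ":")[[1]])
    frames <- select_snapshots(sys$traj, w, as.numeric(opts$interval %||% 10))
  }
  res <- mmgbsa_run(sys$traj, part, frames = frames,
                    entropy = !isTRUE(opts[["no-entropy"]]),
                    n_entropy = as.integer(opts[["n-entropy"]] %||% 125),
                    temperature = as.numeric(opts$temperature %||% 300))
  ct <- compound_table(list(compound = res$aggregate))
  writeLines(render_energy_table(ct), opts$out)
  .cli_manifest(opts$out, "mmgbsa", opts)
  message("wrote ", opts$out)
  0L
}

.cli_hbonds <- function(opts) {
  .cli_need(opts, c("traj", "topo", "donors", "acceptors", "out"))
  sys <- .cli_load_system(opts)
  don <- select_atoms(sys$top, opts$donors, ref = sys$ref, groups = sys$groups)
  acc <- select_atoms(sys$top, opts$acceptors, ref = sys$ref, groups = sys$groups)
  st <- hbond_occupancy(sys$traj, don, acc,
                        d_max = as.numeric(opts[["d-max"]] %||% 3.5),
                        angle_min = as.numeric(opts[["angle-min"]] %||% 120))
  utils::write.table(st, opts$out, sep = "\t", quote = FALSE, row.names = FALSE)
  .cli_manifest(opts$out, "hbonds", opts)
  message("wrote ", opts$out)
  0L
}

.cli_rmsd <- function(opts) {
  .cli_need(opts, c("traj", "topo", "fit", "out"))
  sys <- .cli_load_system(opts)
  fit <- select_atoms(sys$top, opts$fit, ref = sys$ref, groups = sys$groups)
  measure <- if (is.null(opts$measure)) fit else {
    select_atoms(sys$top, opts$measure, ref = sys$ref, groups = sys$groups)
  }
  rs <- rmsd_series(sys$traj, fit, measure)
  out <- data.frame(time_ps = sys$traj$times, rmsd_A = rs$rmsd)
  utils::write.table(out, opts$out, sep = "\t", quote = FALSE, row.names = FALSE)
  .cli_manifest(opts$out, "rmsd", opts)
  message(sprintf("wrote %s (mean %.3f +- %.3f A)", opts$out, rs$mean, rs$sd))
  0L
}

.cli_pmf <- function(opts) {
  .cli_need(opts, c("work", "out"))
  works <- read_works(opts$work)
  prof <- pmf_profile(works, temperature = as.numeric(opts$temperature %||% 300),
                      seed = as.integer(opts$seed %||% 1))
  utils::write.table(as.data.frame(prof), opts$out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .cli_manifest(opts$out, "pmf", opts)
  message(sprintf("wrote %s (endpoint %.3f kcal/mol)", opts$out, attr(prof, "endpoint")))
  0L
}

.cli_report <- function(opts) {
  if (!identical(opts$fixture, "table1")) {
    stop("missing required option: --fixture table1 is the only packaged fixture")
  }
  ct <- table1_fixture()
  if (!is.null(opts$correlate)) {
    measured <- paste0("R", 1:8)
    r <- correlate(table_component(ct, "g_bind", measured),
                   table_component(ct, opts$correlate, measured))
    cat(sprintf("r = %.2f (signed Pearson, n = %d)\n", r, length(measured)))
  }
  if (!is.null(opts$out)) {
    writeLines(render_energy_table(ct), opts$out)
    .cli_manifest(opts$out, "report", opts)
    message("wrote ", opts$out)
  }
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
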