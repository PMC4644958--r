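# Domain containers: topologies, trajectories, complex partitions, and the
# readers/writers for the file formats the analysis pipeline touches.

.ATOM_PARAM_COLS <- c("charge", "rmin_half", "epsilon", "gb_radius", "gb_screen", "mass")
.ATOM_STRUCT_COLS <- c("serial", "name", "element", "res_name", "res_seq", "chain")

#' Construct a topology
#'
#' A topology holds the ordered atom table of a (toy) system together with
#' the bonded terms and continuum dielectrics needed by the energy and
#' normal-mode machinery. Atom indices in `bonds` and `angles` are 1-based
#' positions into the atom table.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_seq`, `chain` and (optionally, `NA` until a parameter
#'   sidecar is merged) `charge` (e), `rmin_half` (A), `epsilon` (kcal/mol),
#'   `gb_radius` (A), `gb_screen` (dimensionless), `mass` (amu).
#' @param bonds data.frame/matrix with columns `i`, `j`, `k_b`
#'   (kcal/mol/A^2), `r0` (A), or `NULL`.
#' @param angles data.frame/matrix with columns `i`, `j`, `k`, `k_a`
#'   (kcal/mol/rad^2), `theta0` (rad), or `NULL`; `j` is the vertex.
#' @param dielectrics list with elements `interior` and `exterior`.
#' @return object of class `topology`.
#' @export
topology <- function(atoms, bonds = NULL, angles = NULL,
                     dielectrics = list(interior = 1, exterior = 80)) {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(.ATOM_STRUCT_COLS, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in .ATOM_PARAM_COLS) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  n <- nrow(atoms)
  bonds <- .as_term_table(bonds, c("i", "j", "k_b", "r0"))
  angles <- .as_term_table(angles, c("i", "j", "k", "k_a", "theta0"))
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k)
  if (length(idx) > 0L && (any(idx < 1L) || any(idx > n))) {
    stop("bond/angle indices reference non-existing atoms")
  }
  if (nrow(bonds) > 0L) {
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bonds in topology")
  }
  if (!is.numeric(dielectrics$interior) || !is.numeric(dielectrics$exterior) ||
      dielectrics$interior <= 0 || dielectrics$exterior <= 0) {
    stop("dielectrics must be positive")
  }
  if (dielectrics$exterior <= dielectrics$interior) {
    stop("exterior dielectric must exceed interior dielectric")
  }
  ok <- is.na(atoms$rmin_half) | atoms$rmin_half >= 0
  if (!all(ok)) stop("rmin_half must be >= 0")
  ok <- is.na(atoms$epsilon) | atoms$epsilon >= 0
  if (!all(ok)) stop("epsilon must be >= 0")
  ok <- is.na(atoms$mass) | atoms$mass > 0
  if (!all(ok)) stop("mass must be > 0")
  out <- structure(list(atoms = atoms, bonds = bonds, angles = angles,
                        dielectrics = list(interior = as.numeric(dielectrics$interior),
                                           exterior = as.numeric(dielectrics$exterior))),
                   class = "topology")
  # shared scratch environment memoizing the nonbonded pair structure for
  # repeated force-field evaluation (environments survive copies)
  attr(out, "ff_cache") <- new.env(parent = emptyenv())
  out
}

.as_term_table <- function(x, cols) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) ||
      (is.matrix(x) && nrow(x) == 0L) || (is.list(x) && length(x) == 0L)) {
    out <- as.data.frame(matrix(numeric(0), ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is.data.frame(x)) stop("bonded term table must be a data.frame or matrix")
  if (ncol(x) != length(cols)) stop("bonded term table needs columns: ",
                                    paste(cols, collapse = ", "))
  names(x) <- cols
  for (k in c("i", "j", "k")) if (k %in% cols) x[[k]] <- as.integer(x[[k]])
  x
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d bonds, %d angles, dielectrics %g/%g\n",
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
              x$dielectrics$interior, x$dielectrics$exterior))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a [topology()].
#' @return integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Construct a trajectory
#'
#' @param topology a [topology()].
#' @param frames list of N x 3 coordinate matrices (A).
#' @param times numeric vector of frame time stamps (ps), strictly increasing.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, times = seq_along(frames)) {
  stopifnot(inherits(topology, "topology"), is.list(frames))
  n <- n_atoms(topology)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!is.matrix(fr) || ncol(fr) != 3L || nrow(fr) != n) {
      stop(sprintf("frame %d: coordinate count does not match topology (%d atoms)", k, n))
    }
    if (!all(is.finite(fr))) stop(sprintf("frame %d: non-finite coordinates", k))
  }
  times <- as.numeric(times)
  if (length(times) != length(frames)) stop("times length must equal frame count")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = [%g, %g] ps\n",
              length(x$frames), n_atoms(x$topology),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Define a receptor/ligand partition of a complex
#'
#' The two index sets name the receptor and ligand atoms whose difference
#' energies define the single-trajectory binding free energy. They must be
#' disjoint and non-empty.
#'
#' @param receptor,ligand integer atom indices (1-based).
#' @param n_total optional atom count; when given, the union must cover all
#'   `n_total` atoms under analysis.
#' @return object of class `complex_partition`.
#' @export
complex_partition <- function(receptor, ligand, n_total = NULL) {
  receptor <- sort(unique(as.integer(receptor)))
  ligand <- sort(unique(as.integer(ligand)))
  if (length(receptor) == 0L || length(ligand) == 0L) {
    stop("receptor and ligand sets must be non-empty")
  }
  if (length(intersect(receptor, ligand)) > 0L) {
    stop("receptor and ligand sets must be disjoint")
  }
  if (!is.null(n_total) && !setequal(c(receptor, ligand), seq_len(n_total))) {
    stop("receptor and ligand must together cover all atoms under analysis")
  }
  structure(list(receptor = receptor, ligand = ligand), class = "complex_partition")
}

## ---------------------------------------------------------------------------
## PDB input/output (ATOM/HETATM/MODEL/ENDMDL subset)

#' Read a (multi-model) PDB file into a trajectory
#'
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper enforces the
#' pipeline's structural contract: one frame per `MODEL` record (or a single
#' frame), identical atom ordering and counts across models, and finite,
#' well-formed coordinate fields. Force-field parameters are left `NA` until
#' a topology sidecar is merged with [merge_topology()].
#'
#' @param path PDB file path.
#' @param model_policy `"all"` (one frame per MODEL) or `"first"`.
#' @param times optional frame time stamps (ps); defaults to 1, 2, ... ps,
#'   matching a save interval of 1 ps.
#' @return a [trajectory()] whose topology has no parameters or bonded terms.
#' @export
read_pdb <- function(path, model_policy = c("all", "first"), times = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  atom_line_no <- which(is_atom)
  for (ln in atom_line_no) {
    coords <- substring(lines[ln], c(31, 39, 47), c(38, 46, 54))
    vals <- suppressWarnings(as.numeric(coords))
    if (any(is.na(vals))) {
      stop(sprintf("malformed coordinate field at line %d: '%s'", ln, lines[ln]))
    }
  }
  # atom counts per MODEL block
  model_starts <- which(grepl("^MODEL", lines))
  if (length(model_starts) > 1L) {
    block <- findInterval(atom_line_no, model_starts)
    counts <- tabulate(block, nbins = length(model_starts))
    if (length(unique(counts[counts > 0])) > 1L) {
      stop("inconsistent atom counts across MODEL records: ",
           paste(counts, collapse = ", "))
    }
  }
  multi <- length(model_starts) > 1L && model_policy == "all"
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nfr <- nrow(xyz)
  at <- pdb$atom
  atoms <- data.frame(serial = as.integer(at$eleno),
                      name = as.character(at$elety),
                      element = .element_of(at),
                      res_name = as.character(at$resid),
                      res_seq = as.integer(at$resno),
                      chain = ifelse(is.na(at$chain), " ", as.character(at$chain)),
                      stringsAsFactors = FALSE)
  top <- topology(atoms)
  frames <- lapply(seq_len(nfr), function(k) {
    matrix(xyz[k, ], ncol = 3L, byrow = TRUE,
           dimnames = list(NULL, c("x", "y", "z")))
  })
  if (is.null(times)) times <- seq_len(nfr)
  trajectory(top, frames, times)
}

.element_of <- function(at) {
  el <- as.character(at$elesy)
  bad <- is.na(el) | el == ""
  if (any(bad)) {
    # fall back to the first alphabetic character of the atom name
    guess <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", as.character(at$elety)[bad]))
    el[bad] <- guess
  }
  toupper(trimws(el))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written in the fixed-width `%8.3f` PDB fields, so a
#' read/write round trip preserves them to 3 decimal places.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @export
write_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  at <- traj$topology$atoms
  multi <- n_frames(traj) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  name_field <- vapply(at$name, function(nm) {
    if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
  }, character(1))
  for (k in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    fr <- traj$frames[[k]]
    recs <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    at$serial, name_field, substr(at$res_name, 1, 3), at$chain,
                    at$res_seq, fr[, 1], fr[, 2], fr[, 3], 1, 0, at$element)
    writeLines(recs, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## XYZ multi-frame input/output

#' Read a multi-frame XYZ file
#'
#' Plain XYZ: atom count line, comment line (a `t = <ps>` token is honoured
#' as the time stamp), then `element x y z` rows. Atoms get placeholder
#' residue bookkeeping; parameters stay unset until merged.
#'
#' @param path file path.
#' @return a [trajectory()] without parameters.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  frames <- list()
  times <- numeric(0)
  elements <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop(sprintf("malformed atom-count line %d: '%s'", pos, lines[pos]))
    comment <- if (pos + 1L <= length(lines)) lines[pos + 1L] else ""
    tm <- regmatches(comment, regexec("t *= *([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) else length(frames) + 1)
    rows <- lines[pos + 1L + seq_len(n)]
    if (length(rows) < n || any(is.na(rows))) stop("truncated XYZ frame at line ", pos)
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    el <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(xyz))) stop("malformed coordinate in XYZ frame at line ", pos)
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      stop("inconsistent atom counts across XYZ frames")
    }
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  atoms <- data.frame(serial = seq_along(elements), name = elements,
                      element = toupper(elements), res_name = "UNK",
                      res_seq = 1L, chain = "A", stringsAsFactors = FALSE)
  trajectory(topology(atoms), frames, times)
}

#' Write a trajectory as a multi-frame XYZ file
#' @param traj a [trajectory()].
#' @param path output file path.
#' @export
write_xyz <- function(traj, path) {
  at <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("%d", nrow(at)), con)
    writeLines(sprintf("frame %d t = %.6g ps", k, traj$times[k]), con)
    fr <- traj$frames[[k]]
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", at$element, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Topology sidecar JSON

#' Read a topology sidecar (JSON)
#'
#' The sidecar dialect is a flat JSON object:
#' `{"atoms": [{"serial","name","element","res_name","res_seq","chain",
#' "charge","rmin_half","epsilon","gb_radius","gb_screen","mass"}, ...],
#' "bonds": [[i, j, k_b, r0], ...], "angles": [[i, j, k, k_a, theta0], ...],
#' "dielectrics": {"interior": 1, "exterior": 80}}` where `i`, `j`, `k` are
#' 1-based positions into the `atoms` array.
#'
#' @param path JSON file path.
#' @return a fully parameterized [topology()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  atoms <- as.data.frame(obj$atoms, stringsAsFactors = FALSE)
  need <- c(.ATOM_STRUCT_COLS, .ATOM_PARAM_COLS)
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("topology sidecar lacks atom field(s): ", paste(missing_cols, collapse = ", "))
  }
  bonds <- if (!is.null(obj$bonds) && length(obj$bonds)) obj$bonds else NULL
  angles <- if (!is.null(obj$angles) && length(obj$angles)) obj$angles else NULL
  diel <- if (is.null(obj$dielectrics)) list(interior = 1, exterior = 80) else obj$dielectrics
  topology(atoms, bonds, angles, diel)
}

#' Write a topology sidecar (JSON)
#' @param top a [topology()].
#' @param path output file path.
#' @export
write_topology <- function(top, path) {
  stopifnot(inherits(top, "topology"))
  obj <- list(atoms = top$atoms,
              bonds = unname(as.matrix(top$bonds)),
              angles = unname(as.matrix(top$angles)),
              dielectrics = top$dielectrics)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Merge a parameter sidecar into a structure-only trajectory
#'
#' Atoms are matched one-to-one by the key `(res_seq, name)`. Every structure
#' atom must find exactly one sidecar entry; sidecar entries without a
#' structural partner are ignored with a warning. Atom order of the structure
#' is never changed.
#'
#' @param structure a [trajectory()] as returned by [read_pdb()]/[read_xyz()].
#' @param sidecar a [topology()] or path to a sidecar JSON file.
#' @return a fully parameterized [trajectory()].
#' @export
merge_topology <- function(structure, sidecar) {
  stopifnot(inherits(structure, "trajectory"))
  if (is.character(sidecar)) sidecar <- read_topology(sidecar)
  stopifnot(inherits(sidecar, "topology"))
  sa <- structure$topology$atoms
  pa <- sidecar$atoms
  key_s <- paste(sa$res_seq, sa$name)
  key_p <- paste(pa$res_seq, pa$name)
  if (anyDuplicated(key_p)) stop("sidecar atom keys (res_seq, name) are not unique")
  hit <- match(key_s, key_p)
  if (anyNA(hit)) {
    bad <- which(is.na(hit))
    stop("sidecar does not parameterize atom(s): ",
         paste(sprintf("(res_seq %d, name %s)", sa$res_seq[bad], sa$name[bad]),
               collapse = ", "))
  }
  extra <- setdiff(seq_len(nrow(pa)), hit)
  if (length(extra) > 0L) {
    warning(sprintf("sidecar has %d entr%s with no structural counterpart; ignored",
                    length(extra), if (length(extra) == 1L) "y" else "ies"))
  }
  merged <- sa
  for (col in .ATOM_PARAM_COLS) merged[[col]] <- pa[[col]][hit]
  merged$element <- pa$element[hit]
  # bonded indices translate from sidecar order to structure order
  to_struct <- match(seq_len(nrow(pa)), hit)
  remap <- function(tab, cols) {
    if (nrow(tab) == 0L) return(tab)
    for (cc in cols) {
      tab[[cc]] <- to_struct[tab[[cc]]]
    }
    tab[stats::complete.cases(tab[cols]), , drop = FALSE]
  }
  bonds <- remap(sidecar$bonds, c("i", "j"))
  angles <- remap(sidecar$angles, c("i", "j", "k"))
  top <- topology(merged, bonds, angles, sidecar$dielectrics)
  trajectory(top, structure$frames, structure$times)
}

#' Restrict a topology to a subset of atoms
#'
#' Keeps atom order, drops bonded terms that reach outside the subset, and
#' records the original indices in attribute `"index"`.
#'
#' @param top a [topology()].
#' @param idx atom indices to keep (1-based, any order; used sorted).
#' @return a [topology()] over the subset.
#' @export
subset_topology <- function(top, idx) {
  stopifnot(inherits(top, "topology"))
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 1L) || any(idx > n_atoms(top))) stop("subset indices out of range")
  new_of <- rep(NA_integer_, n_atoms(top))
  new_of[idx] <- seq_along(idx)
  remap <- function(tab, cols) {
    if (nrow(tab) == 0L) return(tab)
    for (cc in cols) tab[[cc]] <- new_of[tab[[cc]]]
    tab[stats::complete.cases(tab[cols]), , drop = FALSE]
  }
  out <- topology(top$atoms[idx, , drop = FALSE],
                  remap(top$bonds, c("i", "j")),
                  remap(top$angles, c("i", "j", "k")),
                  top$dielectrics)
  attr(out, "index") <- idx
  out
}
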