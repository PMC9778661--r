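# Trajectory container and structure I/O.
#
# A trajectory is a shared topology (one row per atom) plus an
# n_atoms x 3 x n_frames coordinate array in Angstrom.  Multi-model PDB is
# the on-disk format; parsing and writing are delegated to bio3d.

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.97376,
  S = 32.06, MG = 24.305, "NA" = 22.98977, CL = 35.45, K = 39.0983,
  F = 18.998403, FE = 55.845, ZN = 65.38, CA = 40.078, MN = 54.938
)

#' Look up standard atomic masses from element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @export
atomic_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    stop("no mass known for element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Construct a trajectory object
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `resid`,
#'   `element`; a `mass` column is added from `element` if absent.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)` or an
#'   `n_atoms x 3` matrix for a single frame.  Angstrom.
#' @param dt frame spacing in ps (default 2).
#' @return object of class `"md_trajectory"`.
#' @export
trajectory <- function(atoms, coords, dt = 2) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "resname", "resid", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms missing column(s): ", paste(miss, collapse = ", "))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(atoms)) {
    stop("coordinate array has ", dim(coords)[1], " atoms but topology has ",
         nrow(atoms))
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  if (is.null(atoms$mass)) atoms$mass <- atomic_mass(atoms$element)
  if (any(atoms$mass <= 0)) stop("atom masses must be > 0")
  key <- paste(atoms$resid, atoms$resname, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (resid, name) in topology: ", key[anyDuplicated(key)])
  }
  structure(list(atoms = atoms, coords = coords, dt = dt),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms, %d frame(s), dt = %g ps\n",
              n_atoms(x), n_frames(x), x$dt))
  cat("  residues:", length(unique(paste(x$atoms$resid, x$atoms$resname))),
      " resnames:", paste(unique(x$atoms$resname), collapse = " "), "\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj an `md_trajectory`.
#' @param frame 1-based frame index.
#' @return numeric matrix.
#' @export
frame_coords <- function(traj, frame = 1L) {
  if (frame < 1L || frame > n_frames(traj)) stop("frame index out of range")
  m <- traj$coords[, , frame, drop = FALSE]
  matrix(m, nrow = dim(m)[1], ncol = 3L)
}

#' Keep only selected frames
#' @param traj an `md_trajectory`.
#' @param frames integer frame indices to keep.
#' @return trimmed `md_trajectory` sharing the topology.
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(all(frames >= 1L), all(frames <= n_frames(traj)))
  traj$coords <- traj$coords[, , frames, drop = FALSE]
  traj
}

# light pre-validation of MODEL blocks: bio3d recycles coordinates silently
# when models disagree, so atom counts are checked here first.
.validate_models <- function(lines, path) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
    return(invisible(1L))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records in ", path)
  }
  names_per_model <- lapply(seq_along(model_starts), function(k) {
    block <- lines[model_starts[k]:model_ends[k]]
    block <- block[grepl("^(ATOM  |HETATM)", block)]
    substr(block, 13, 27)  # atom name + resname + chain + resid
  })
  ref <- names_per_model[[1]]
  for (k in seq_along(names_per_model)) {
    if (!identical(names_per_model[[k]], ref)) {
      stop("topology mismatch: MODEL ", k, " in ", path,
           " has different atoms than MODEL 1")
    }
  }
  invisible(length(model_starts))
}

#' Read a structure or multi-model trajectory from PDB
#'
#' Each MODEL block becomes one frame; a file without MODEL records yields a
#' single-frame trajectory.  All MODEL blocks must share the same atoms.
#'
#' @param path PDB file path.
#' @param dt frame spacing in ps assigned to the trajectory (default 2).
#' @return an `md_trajectory`.
#' @export
read_structure <- function(path, dt = 2) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  .validate_models(lines, path)
  bad <- which(grepl("^(ATOM  |HETATM)", lines) & nchar(lines) < 54)
  if (length(bad)) {
    stop("unparseable ATOM/HETATM record at line ", bad[1], " of ", path)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- toupper(trimws(at$elesy))
  noel <- is.na(element) | element == ""
  if (any(noel)) {
    element[noel] <- toupper(substr(trimws(at$elety[noel]), 1, 1))
  }
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), resname = trimws(at$resid),
    resid = at$resno, element = element, stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  trajectory(atoms, coords, dt = dt)
}

#' Write a trajectory as (multi-model) PDB
#'
#' Coordinates are stored at PDB fixed-width precision (3 decimals); a
#' read-back reproduces the topology exactly and coordinates to 1e-3 Angstrom.
#'
#' @param traj an `md_trajectory`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(traj, path) {
  if (!inherits(traj, "md_trajectory") || n_atoms(traj) == 0L) {
    stop("empty or invalid trajectory")
  }
  nf <- n_frames(traj)
  xyz <- t(apply(traj$coords, 3, function(m) as.vector(t(m))))
  if (nf == 1L) xyz <- matrix(xyz, nrow = 1L)
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = traj$atoms$resid, resid = traj$atoms$resname,
    eleno = traj$atoms$serial, elety = traj$atoms$name,
    elesy = traj$atoms$element
  )
  invisible(path)
}

#' Select atoms by a small query grammar
#'
#' Terms are `resid N`, `resname X`, `name Y`, combined with `AND` / `OR`
#' (`AND` binds tighter).  Matching is exact on the token.
#'
#' @param traj an `md_trajectory`.
#' @param query selection string, e.g. `"resid 37 AND name CA"`.
#' @param label optional label stored on the selection.
#' @return object of class `"atom_selection"`: integer indices + label.
#' @export
select_atoms <- function(traj, query, label = query) {
  mask <- .eval_query(traj$atoms, query)
  structure(list(indices = which(mask), label = label),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> '%s': %d atom(s)\n", x$label,
              length(x$indices)))
  invisible(x)
}

.eval_query <- function(atoms, query) {
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query))) {
    stop("selection query must be a single non-empty string")
  }
  ors <- strsplit(query, "\\s+OR\\s+")[[1]]
  mask <- rep(FALSE, nrow(atoms))
  for (clause in ors) {
    ands <- strsplit(clause, "\\s+AND\\s+")[[1]]
    m <- rep(TRUE, nrow(atoms))
    for (term in ands) {
      term <- trimws(term)
      tok <- strsplit(term, "\\s+")[[1]]
      if (length(tok) != 2L) stop("malformed selection term: '", term, "'")
      m <- m & switch(tok[1],
        resid   = atoms$resid == suppressWarnings(as.integer(tok[2])),
        resname = atoms$resname == tok[2],
        name    = atoms$name == tok[2],
        stop("unknown selection keyword: '", tok[1], "'")
      )
      m[is.na(m)] <- FALSE
    }
    mask <- mask | m
  }
  mask
}

#' Trailing analysis window of a trajectory
#'
#' Returns the last `ceiling(fraction * n_frames)` frames, mirroring the
#' convention of analysing the final portion of each production run (e.g. the
#' last 120 ns of a 200 ns trajectory corresponds to `fraction = 0.6`).
#'
#' @param traj an `md_trajectory`.
#' @param fraction fraction of trailing frames to keep, in (0, 1].
#' @return trimmed `md_trajectory`.
#' @export
analysis_window <- function(traj, fraction = 0.6) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  nf <- n_frames(traj)
  keep <- ceiling(fraction * nf)
  subset_frames(traj, seq.int(nf - keep + 1L, nf))
}

#' Idealized placement of backbone amide hydrogens
#'
#' For each residue with a backbone `N` lacking a hydrogen within 1.2 A,
#' places `H` at 1.01 A from `N` along the bisector of the C(prev)->N and
#' CA->N directions (in the C(prev)-N-CA plane).  Residues without a
#' preceding carbonyl carbon (chain starts) are skipped with a warning.
#' Placement uses frame 1 geometry and is applied to every frame by the same
#' local construction.
#'
#' @param traj an `md_trajectory`.
#' @return trajectory with added `H` atoms.
#' @export
add_amide_hydrogens <- function(traj) {
  at <- traj$atoms
  nf <- n_frames(traj)
  prot <- !(at$resname %in% c("HOH", "WAT", "MG", "GTP", "GDP", "NA", "CL"))
  resids <- sort(unique(at$resid[prot]))
  add_at <- list(); add_xyz <- list(); skipped <- integer()
  for (r in resids) {
    iN <- which(at$resid == r & at$name == "N" & prot)
    if (!length(iN)) next
    f1 <- frame_coords(traj, 1L)
    hs <- which(at$element == "H")
    if (length(hs)) {
      dh <- sqrt(colSums((t(f1[hs, , drop = FALSE]) - f1[iN, ])^2))
      if (any(dh <= 1.2)) next  # already protonated
    }
    iCA <- which(at$resid == r & at$name == "CA" & prot)
    iCp <- which(at$resid == (r - 1L) & at$name == "C" & prot)
    if (!length(iCA) || !length(iCp)) { skipped <- c(skipped, r); next }
    xyz <- vapply(seq_len(nf), function(f) {
      fc <- traj$coords[, , f]
      u1 <- fc[iN, ] - fc[iCp, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- fc[iN, ] - fc[iCA, ]; u2 <- u2 / sqrt(sum(u2^2))
      b <- u1 + u2; b <- b / sqrt(sum(b^2))
      fc[iN, ] + 1.01 * b
    }, numeric(3))
    add_at[[length(add_at) + 1L]] <- data.frame(
      serial = NA_integer_, name = "H", resname = at$resname[iN],
      resid = r, element = "H", mass = .atomic_masses[["H"]],
      stringsAsFactors = FALSE
    )
    add_xyz[[length(add_xyz) + 1L]] <- t(xyz)  # nf x 3
  }
  if (length(skipped)) {
    warning("no preceding carbonyl carbon; amide H not placed for residue(s): ",
            paste(skipped, collapse = ", "))
  }
  if (!length(add_at)) return(traj)
  new_at <- rbind(at, do.call(rbind, add_at))
  new_at$serial <- seq_len(nrow(new_at))
  nc <- array(NA_real_, dim = c(nrow(new_at), 3L, nf))
  nc[seq_len(nrow(at)), , ] <- traj$coords
  for (k in seq_along(add_xyz)) {
    nc[nrow(at) + k, , ] <- t(add_xyz[[k]])
  }
  trajectory(new_at, nc, dt = traj$dt)
}
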