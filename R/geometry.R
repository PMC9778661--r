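# Distances, angles, centroids, Kabsch superposition, RMSD/RMSF and
# coordination-shell scans.  Frames are n_atoms x 3 matrices in Angstrom.

#' Euclidean distance between two atoms in a frame
#' @param frame n_atoms x 3 coordinate matrix.
#' @param i,j atom indices.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(frame, i, j) {
  stopifnot(i >= 1, j >= 1, i <= nrow(frame), j <= nrow(frame))
  sqrt(sum((frame[i, ] - frame[j, ])^2))
}

#' Angle at a vertex atom, in degrees
#'
#' Returns the a-h-d angle with the vertex at `h` (for hydrogen bonds this is
#' the acceptor-hydrogen-donor angle).
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param a,h,d atom indices; `h` is the vertex.
#' @return angle in degrees, in [0, 180].
#' @export
atom_angle <- function(frame, a, h, d) {
  stopifnot(h != a, h != d)
  v1 <- frame[a, ] - frame[h, ]
  v2 <- frame[d, ] - frame[h, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("degenerate geometry: coincident atoms")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.backbone_names <- c("N", "CA", "C", "O", "H", "HA", "OXT")

#' Distance between side-chain heavy-atom centroids of two residues
#'
#' Unweighted centroids over heavy atoms beyond the backbone (N, CA, C, O),
#' the standard monitor for hydrophobic side-chain contacts.
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index.
#' @param res_a,res_b residue numbers.
#' @return centroid-centroid distance in Angstrom.
#' @export
sidechain_centroid_distance <- function(traj, frame, res_a, res_b) {
  fc <- frame_coords(traj, frame)
  cen <- function(r) {
    at <- traj$atoms
    idx <- which(at$resid == r & !(at$name %in% .backbone_names) &
                   at$element != "H")
    if (!length(idx)) {
      stop("residue ", r, " has no side-chain heavy atoms (glycine?)")
    }
    colMeans(fc[idx, , drop = FALSE])
  }
  sqrt(sum((cen(res_a) - cen(res_b))^2))
}

# Kabsch least-squares rotation mapping centred P onto centred Q.
# Returns a proper rotation (det = +1) even for reflective cases.
.kabsch <- function(P, Q, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(P))
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc * w) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, center_p = cp, center_q = cq)
}

#' Optimal rigid-body superposition of two frames
#'
#' Least-squares (Kabsch) fit of `mobile` onto `reference` over the atoms in
#' `sel`; the rotation is always proper (determinant +1).  The whole mobile
#' frame is transformed; the reported RMSD is the post-fit value over `sel`.
#'
#' @param mobile,reference n_atoms x 3 coordinate matrices.
#' @param sel an `atom_selection` or integer index vector (>= 3 atoms,
#'   non-collinear).
#' @return list with `coords` (transformed mobile), `rotation`,
#'   `translation` and `rmsd`.
#' @export
superpose <- function(mobile, reference, sel) {
  idx <- if (inherits(sel, "atom_selection")) sel$indices else as.integer(sel)
  if (length(idx) < 3L) stop("superposition needs at least 3 atoms")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2L) {
    stop("degenerate selection: atoms are collinear")
  }
  k <- .kabsch(P, Q)
  out <- sweep(mobile, 2, k$center_p) %*% t(k$R)
  out <- sweep(out, 2, k$center_q, "+")
  dev <- out[idx, , drop = FALSE] - Q
  list(coords = out, rotation = k$R,
       translation = k$center_q - as.vector(k$R %*% k$center_p),
       rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Backbone atom selection (CA, C, N)
#' @param traj an `md_trajectory`.
#' @return an `atom_selection` over backbone CA, C and N atoms.
#' @export
backbone_selection <- function(traj) {
  idx <- which(traj$atoms$name %in% c("CA", "C", "N") &
                 !(traj$atoms$resname %in% c("GTP", "GDP", "HOH", "WAT", "MG")))
  structure(list(indices = idx, label = "backbone CA/C/N"),
            class = "atom_selection")
}

#' Per-frame RMSD to a reference frame
#'
#' Every frame is least-squares fitted on `sel` to the reference frame
#' (frame 1 by default) before the deviation is measured; with
#' `mass_weighted = TRUE` the RMSD is sqrt(sum(m_i d_i^2) / sum(m_i)).
#'
#' @param traj an `md_trajectory`.
#' @param reference reference frame index (default 1).
#' @param sel selection over which to fit and measure; defaults to the
#'   backbone CA/C/N set.
#' @param mass_weighted logical; mass-weight the deviations (default TRUE).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, sel = backbone_selection(traj),
                        mass_weighted = TRUE) {
  idx <- if (inherits(sel, "atom_selection")) sel$indices else as.integer(sel)
  ref <- frame_coords(traj, reference)
  w <- if (mass_weighted) traj$atoms$mass[idx] else rep(1, length(idx))
  w <- w / sum(w)
  vapply(seq_len(n_frames(traj)), function(f) {
    sp <- superpose(frame_coords(traj, f), ref, idx)
    dev <- sp$coords[idx, , drop = FALSE] - ref[idx, , drop = FALSE]
    sqrt(sum(w * rowSums(dev^2)))
  }, numeric(1))
}

# align all frames of traj to frame 1 over idx; returns coords array
.align_to_first <- function(traj, idx) {
  ref <- frame_coords(traj, 1L)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    out[, , f] <- superpose(traj$coords[, , f], ref, idx)$coords
  }
  out
}

#' Root mean square fluctuation profile
#'
#' Frames are first aligned to the initial frame over `align_sel`; the
#' per-atom RMSF is the square root of the time-mean squared deviation from
#' the time-mean position.  With `per_residue = TRUE` atoms of each residue
#' (restricted to `sel`) are combined by mass-weighted averaging of their
#' mean-square fluctuations.
#'
#' @param traj an `md_trajectory` with >= 2 frames.
#' @param sel atoms to report; defaults to the backbone CA/C/N set.
#' @param align_sel atoms used for the alignment (default: same as `sel`).
#' @param per_residue logical; aggregate per residue (default FALSE).
#' @return named numeric vector of RMSF values (Angstrom), per atom index or
#'   per residue number.
#' @export
rmsf <- function(traj, sel = backbone_selection(traj), align_sel = sel,
                 per_residue = FALSE) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  idx <- if (inherits(sel, "atom_selection")) sel$indices else as.integer(sel)
  aidx <- if (inherits(align_sel, "atom_selection")) align_sel$indices else
    as.integer(align_sel)
  co <- .align_to_first(traj, aidx)
  sub <- co[idx, , , drop = FALSE]
  mu <- apply(sub, c(1, 2), mean)
  msf <- rowMeans(apply(sub, 3, function(fr) rowSums((fr - mu)^2)))
  if (!per_residue) {
    names(msf) <- idx
    return(sqrt(msf))
  }
  resid <- traj$atoms$resid[idx]
  mass <- traj$atoms$mass[idx]
  out <- vapply(split(seq_along(idx), resid), function(g) {
    sqrt(sum(mass[g] * msf[g]) / sum(mass[g]))
  }, numeric(1))
  out[order(as.integer(names(out)))]
}

#' Replicate-averaged per-residue RMSF profile
#'
#' Each replicate is aligned and measured independently (per-run alignment);
#' the profile reports the across-replicate mean and standard deviation.
#'
#' @param trajs list of `md_trajectory` replicates.
#' @param ... passed to [rmsf()] (with `per_residue = TRUE`).
#' @return data.frame with columns `resid`, `mean`, `sd`, and one column per
#'   replicate.
#' @export
rmsf_profile <- function(trajs, ...) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  per <- lapply(trajs, rmsf, per_residue = TRUE, ...)
  resid <- as.integer(names(per[[1]]))
  vals <- do.call(cbind, per)
  colnames(vals) <- paste0("rep", seq_along(per))
  data.frame(resid = resid, mean = rowMeans(vals),
             sd = if (ncol(vals) > 1L) apply(vals, 1, stats::sd) else 0,
             vals, row.names = NULL)
}

#' Atoms within a cutoff of a centre atom
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param center atom index of the centre (e.g. the Mg ion).
#' @param candidates an `atom_selection` or integer indices to scan.
#' @param cutoff distance cutoff in Angstrom (> 0); strict `<` comparison.
#' @return data.frame of `(atom, distance)` sorted by distance.
#' @export
coordination_shell <- function(frame, center, candidates, cutoff) {
  stopifnot(cutoff > 0)
  idx <- if (inherits(candidates, "atom_selection")) candidates$indices else
    as.integer(candidates)
  idx <- setdiff(idx, center)
  d <- sqrt(colSums((t(frame[idx, , drop = FALSE]) - frame[center, ])^2))
  keep <- d < cutoff
  out <- data.frame(atom = idx[keep], distance = d[keep])
  out[order(out$distance), , drop = FALSE]
}
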