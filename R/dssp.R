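# Simplified Kabsch-Sander secondary-structure assignment.
#
# Backbone hydrogen bonds are scored with the electrostatic energy
#   E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)  [kcal/mol]
# (distances in Angstrom between the carbonyl C/O of the acceptor residue
# and the amide N/H of the donor residue); a bond is formed iff
# E < -0.5 kcal/mol.  The label alphabet is reduced to
# H (alpha-helix), G (3-10 helix), E (strand), C (coil).

.ks_backbone <- function(traj) {
  at <- traj$atoms
  prot <- !(at$resname %in% c("HOH", "WAT", "MG", "GTP", "GDP", "NA", "CL"))
  resids <- sort(unique(at$resid[prot]))
  idx <- function(r, nm) {
    i <- which(at$resid == r & at$name == nm & prot)
    if (length(i) == 1L) i else NA_integer_
  }
  data.frame(resid = resids,
             N = vapply(resids, idx, integer(1), nm = "N"),
             H = vapply(resids, idx, integer(1), nm = "H"),
             C = vapply(resids, idx, integer(1), nm = "C"),
             O = vapply(resids, idx, integer(1), nm = "O"),
             CA = vapply(resids, idx, integer(1), nm = "CA"))
}

#' Kabsch-Sander hydrogen-bond energy between two residues
#'
#' Energy of the bond donated by the backbone amide (N-H) of `donor_res` to
#' the backbone carbonyl (C=O) of `acceptor_res`.
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index.
#' @param donor_res,acceptor_res residue numbers.
#' @return energy in kcal/mol (bond formed iff < -0.5).
#' @export
ks_energy <- function(traj, frame, donor_res, acceptor_res) {
  bb <- .ks_backbone(traj)
  di <- bb[bb$resid == donor_res, ]
  ai <- bb[bb$resid == acceptor_res, ]
  if (nrow(di) != 1L || nrow(ai) != 1L ||
      anyNA(c(di$N, di$H, ai$C, ai$O))) {
    stop("missing backbone N/H/C/O atoms for residue pair ", donor_res,
         " -> ", acceptor_res)
  }
  fc <- frame_coords(traj, frame)
  d <- function(i, j) sqrt(sum((fc[i, ] - fc[j, ])^2))
  0.084 * 332 * (1 / d(ai$O, di$N) + 1 / d(ai$C, di$H) -
                   1 / d(ai$O, di$H) - 1 / d(ai$C, di$N))
}

# CO(i) -> NH(j) bond matrix for one frame: TRUE iff the amide of residue j
# donates to the carbonyl of residue i with E < -0.5 kcal/mol.
.ks_bond_matrix <- function(traj, frame, bb = .ks_backbone(traj)) {
  fc <- frame_coords(traj, frame)
  n <- nrow(bb)
  ok_d <- !is.na(bb$N) & !is.na(bb$H)
  ok_a <- !is.na(bb$C) & !is.na(bb$O)
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {        # acceptor residue (CO of i)
    if (!ok_a[i]) next
    for (j in seq_len(n)) {      # donor residue (NH of j)
      if (!ok_d[j] || abs(i - j) < 2L) next
      dON <- sqrt(sum((fc[bb$O[i], ] - fc[bb$N[j], ])^2))
      if (dON > 5.2) next        # 1/r terms cannot reach -0.5 beyond this
      dCH <- sqrt(sum((fc[bb$C[i], ] - fc[bb$H[j], ])^2))
      dOH <- sqrt(sum((fc[bb$O[i], ] - fc[bb$H[j], ])^2))
      dCN <- sqrt(sum((fc[bb$C[i], ] - fc[bb$N[j], ])^2))
      e <- 0.084 * 332 * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
      hb[i, j] <- e < -0.5
    }
  }
  hb
}

#' Assign secondary structure for one frame
#'
#' Simplified Kabsch-Sander rules on the backbone hydrogen-bond pattern:
#' two consecutive i -> i+4 turns make an alpha-helix run (H), two
#' consecutive i -> i+3 turns a 3-10 helix run (G), parallel/antiparallel
#' bridge rules mark strands (E), everything else is coil (C).  Precedence
#' H > G > E > C.
#'
#' @param traj an `md_trajectory` with >= 5 protein residues carrying
#'   backbone N, H, C, O.
#' @param frame frame index.
#' @return named character vector of labels, one per residue.
#' @export
ss_assign <- function(traj, frame = 1L) {
  bb <- .ks_backbone(traj)
  n <- nrow(bb)
  if (n < 5L) stop("secondary-structure assignment needs >= 5 residues")
  hb <- .ks_bond_matrix(traj, frame, bb)
  turn <- function(k) {
    # turn_k(i): CO(i) -> NH(i+k)
    vapply(seq_len(n), function(i) {
      i + k <= n && hb[i, i + k]
    }, logical(1))
  }
  t4 <- turn(4L); t3 <- turn(3L)
  lab <- rep("C", n)
  # bridges (strands), applied first so helices take precedence by overwrite
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 3L) next
    par <- (i > 1L && i < n && hb[i - 1L, j] && hb[j, i + 1L]) ||
      (j > 1L && j < n && hb[j - 1L, i] && hb[i, j + 1L])
    anti <- (hb[i, j] && hb[j, i]) ||
      (i > 1L && i < n && j > 1L && j < n && hb[i - 1L, j + 1L] &&
         hb[j - 1L, i + 1L])
    if (isTRUE(par) || isTRUE(anti)) lab[c(i, j)] <- "E"
  }
  for (i in seq_len(n - 1L)) {
    if (i > 1L && t3[i - 1L] && t3[i]) lab[i:(i + 2L)] <- "G"
  }
  for (i in seq_len(n - 1L)) {
    if (i > 1L && t4[i - 1L] && t4[i]) lab[i:(i + 3L)] <- "H"
  }
  names(lab) <- bb$resid
  lab
}

#' Per-residue secondary-structure propensities over trajectories
#'
#' Fraction of frames each residue spends in each label, pooled over all
#' frames of all given trajectories; rows sum to 1.
#'
#' @param trajs an `md_trajectory` or list of replicates.
#' @return data.frame with `resid` and columns `H`, `G`, `E`, `C`.
#' @export
ss_propensity <- function(trajs) {
  if (inherits(trajs, "md_trajectory")) trajs <- list(trajs)
  counts <- NULL
  total <- 0L
  resid <- NULL
  for (tr in trajs) {
    for (f in seq_len(n_frames(tr))) {
      lab <- ss_assign(tr, f)
      if (is.null(resid)) resid <- as.integer(names(lab))
      m <- vapply(c("H", "G", "E", "C"), function(s) as.integer(lab == s),
                  integer(length(lab)))
      counts <- if (is.null(counts)) m else counts + m
      total <- total + 1L
    }
  }
  out <- data.frame(resid = resid, counts / total)
  rownames(out) <- NULL
  out
}
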