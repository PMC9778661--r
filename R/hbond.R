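# Geometric hydrogen-bond detection and occupancy statistics.
#
# A bond between acceptor heavy atom A, donor hydrogen H and donor heavy
# atom D is formed iff d(A, D) < d_max AND the A-H-D angle (vertex at the
# hydrogen) > angle_min; both inequalities strict.

#' Hydrogen-bond geometric criterion
#' @param d_max maximum acceptor-donor heavy-atom distance, Angstrom
#'   (default 3.5).
#' @param angle_min minimum acceptor-hydrogen-donor angle at the hydrogen,
#'   degrees (default 120).
#' @return object of class `"hbond_criterion"`.
#' @export
hbond_criterion <- function(d_max = 3.5, angle_min = 120) {
  stopifnot(d_max > 0, angle_min >= 0, angle_min <= 180)
  structure(list(d_max = d_max, angle_min = angle_min),
            class = "hbond_criterion")
}

#' Enumerate hydrogen-bond donor and acceptor candidates
#'
#' Donors are N/O heavy atoms with at least one bonded hydrogen (an H within
#' 1.2 A in frame 1); each donor-hydrogen pairing is one candidate row.
#' Acceptors are all N/O heavy atoms.  Polar heavy atoms without an explicit
#' hydrogen are simply not donors; use [add_amide_hydrogens()] for backbone
#' amides of structures stored without hydrogens.
#'
#' @param traj an `md_trajectory`.
#' @return list with `donors` (data.frame `heavy`, `h`) and `acceptors`
#'   (integer indices).
#' @export
hbond_candidates <- function(traj) {
  at <- traj$atoms
  heavy <- which(at$element %in% c("N", "O"))
  hs <- which(at$element == "H")
  if (!length(hs)) {
    stop("no hydrogens in topology; add them (see add_amide_hydrogens) ",
         "before hydrogen-bond analysis")
  }
  f1 <- frame_coords(traj, 1L)
  don <- do.call(rbind, lapply(heavy, function(i) {
    d <- sqrt(colSums((t(f1[hs, , drop = FALSE]) - f1[i, ])^2))
    b <- hs[d <= 1.2]
    if (!length(b)) return(NULL)
    data.frame(heavy = i, h = b)
  }))
  if (is.null(don)) don <- data.frame(heavy = integer(), h = integer())
  list(donors = don, acceptors = heavy)
}

#' Detect hydrogen bonds in one frame
#'
#' Exhaustive test of every donor(-hydrogen) x acceptor combination against
#' the geometric criterion.  When a donor heavy atom carries several
#' hydrogens, each is tested and each satisfying (donor, H, acceptor) triple
#' is reported.
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index.
#' @param criterion an [hbond_criterion()].
#' @param candidates optional precomputed [hbond_candidates()] result.
#' @return data.frame with columns `donor`, `h`, `acceptor`, `distance`,
#'   `angle`.
#' @export
hbond_detect <- function(traj, frame = 1L, criterion = hbond_criterion(),
                         candidates = NULL) {
  if (is.null(candidates)) candidates <- hbond_candidates(traj)
  fc <- frame_coords(traj, frame)
  don <- candidates$donors
  acc <- candidates$acceptors
  rows <- list()
  for (k in seq_len(nrow(don))) {
    D <- don$heavy[k]; H <- don$h[k]
    a_ok <- setdiff(acc, D)
    dDA <- sqrt(colSums((t(fc[a_ok, , drop = FALSE]) - fc[D, ])^2))
    near <- a_ok[dDA < criterion$d_max]
    if (!length(near)) next
    for (A in near) {
      ang <- atom_angle(fc, A, H, D)
      if (ang > criterion$angle_min) {
        rows[[length(rows) + 1L]] <- data.frame(
          donor = D, h = H, acceptor = A,
          distance = atom_distance(fc, A, D), angle = ang)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      distance = numeric(), angle = numeric()))
  }
  do.call(rbind, rows)
}

# Vectorized per-frame bonded flag for one donor (heavy + its hydrogens)
# against a set of acceptor atoms: TRUE if any (H, acceptor) combination
# satisfies the criterion in that frame.
.pair_bonded_series <- function(traj, donor_heavy, donor_hs, acceptors,
                                criterion = hbond_criterion()) {
  co <- traj$coords
  nf <- n_frames(traj)
  bonded <- rep(FALSE, nf)
  xyz <- function(i) matrix(co[i, , , drop = FALSE], nrow = 3L)  # 3 x nf
  Dxyz <- xyz(donor_heavy)
  cosmin <- cos(criterion$angle_min * pi / 180)
  for (A in acceptors) {
    Axyz <- xyz(A)
    dAD <- sqrt(colSums((Axyz - Dxyz)^2))
    close <- dAD < criterion$d_max
    if (!any(close)) next
    for (H in donor_hs) {
      Hxyz <- xyz(H)
      v1 <- Axyz - Hxyz
      v2 <- Dxyz - Hxyz
      cosang <- colSums(v1 * v2) /
        (sqrt(colSums(v1^2)) * sqrt(colSums(v2^2)))
      # angle > angle_min <=> cos(angle) < cos(angle_min)
      bonded <- bonded | (close & (cosang < cosmin))
    }
  }
  bonded
}

#' Per-frame bonded series for one donor/acceptor pair
#'
#' @param traj an `md_trajectory`.
#' @param donor index of the donor heavy atom (its bonded hydrogens are found
#'   from frame 1, or can be given explicitly via `hydrogens`).
#' @param acceptors integer indices of acceptor heavy atoms; the pair counts
#'   as bonded in a frame if any (hydrogen, acceptor) combination satisfies
#'   the criterion.
#' @param criterion an [hbond_criterion()].
#' @param hydrogens optional explicit hydrogen indices for the donor.
#' @return logical vector, one flag per frame.
#' @export
hbond_series <- function(traj, donor, acceptors,
                         criterion = hbond_criterion(), hydrogens = NULL) {
  if (is.null(hydrogens)) {
    f1 <- frame_coords(traj, 1L)
    hs <- which(traj$atoms$element == "H")
    d <- sqrt(colSums((t(f1[hs, , drop = FALSE]) - f1[donor, ])^2))
    hydrogens <- hs[d <= 1.2]
  }
  if (!length(hydrogens)) stop("donor atom ", donor, " has no bonded hydrogen")
  .pair_bonded_series(traj, donor, hydrogens, acceptors, criterion)
}

#' Hydrogen-bond occupancy across replicate trajectories
#'
#' Occupancy is the fraction of analysis-window frames in which the pair is
#' bonded; the reported mean is the arithmetic mean of the per-replicate
#' fractions.
#'
#' @param trajs list of `md_trajectory` replicates (shared topology).
#' @param donor donor heavy-atom index (in the shared topology).
#' @param acceptors acceptor heavy-atom indices.
#' @param window trailing window fraction in (0, 1] (default 0.6).
#' @param criterion an [hbond_criterion()].
#' @param label optional pair label.
#' @return one-row data.frame: `pair`, `rep1..repK`, `mean`.
#' @export
hbond_occupancy <- function(trajs, donor, acceptors, window = 0.6,
                            criterion = hbond_criterion(), label = NULL) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  fr <- vapply(trajs, function(tr) {
    wt <- analysis_window(tr, window)
    if (n_frames(wt) == 0L) stop("empty analysis window")
    mean(hbond_series(wt, donor, acceptors, criterion))
  }, numeric(1))
  if (is.null(label)) {
    at <- trajs[[1]]$atoms
    label <- paste0(at$resname[donor], at$resid[donor], ".", at$name[donor],
                    "-", paste(unique(at$name[acceptors]), collapse = "/"))
  }
  out <- data.frame(pair = label, t(fr), mean = mean(fr),
                    stringsAsFactors = FALSE)
  names(out)[1L + seq_along(fr)] <- paste0("rep", seq_along(fr))
  out
}

#' Filter an occupancy table to high-occupancy bonds
#'
#' Keeps a pair if its mean occupancy exceeds `threshold` in ANY of the
#' analysed systems (strict `>`).  The table may carry a `system` column
#' (one mean per system per pair) or be a single-system table.
#'
#' @param table data.frame with columns `pair`, `mean` and optionally
#'   `system`.
#' @param threshold occupancy threshold (default 0.75).
#' @return filtered data.frame (all rows of every pair that passes).
#' @export
high_occupancy <- function(table, threshold = 0.75) {
  stopifnot(is.data.frame(table), "mean" %in% names(table))
  if ("system" %in% names(table)) {
    mx <- tapply(table$mean, table$pair, max)
    keep <- names(mx)[mx > threshold]
    table[table$pair %in% keep, , drop = FALSE]
  } else {
    table[table$mean > threshold, , drop = FALSE]
  }
}
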