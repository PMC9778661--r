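# Conformational-state classification of GTPase frames.
#
# The active state carries both characteristic hydrogen bonds from the GTP
# gamma-phosphate oxygens to the backbone amides of T37 (switch I) and G62
# (switch II); the three inactive substates are defined by which of the two
# bonds is lost.  The d1/d2 atom-pair distances (Calpha(T37)-Pbeta and
# Calpha(G62)-Pbeta) are descriptive observables carried alongside.

#' Conformational state labels
#'
#' The four per-frame labels of the switch-region state scheme, in canonical
#' order.
#' @format character vector of length 4.
#' @export
state_levels <- c("ACTIVE", "INACTIVE_1", "INACTIVE_2", "INACTIVE_3")

#' Classify frames from the two characteristic bond flags
#'
#' Truth table: (TRUE, TRUE) -> ACTIVE; (FALSE, FALSE) -> INACTIVE_1 (both
#' gamma-phosphate interactions lost); (FALSE, TRUE) -> INACTIVE_2 (T37
#' interaction lost only); (TRUE, FALSE) -> INACTIVE_3 (G62 interaction lost
#' only).
#'
#' @param t37_bonded,g62_bonded logical vectors (recycled to equal length).
#' @return factor with levels `ACTIVE`, `INACTIVE_1`, `INACTIVE_2`,
#'   `INACTIVE_3`.
#' @export
classify_state <- function(t37_bonded, g62_bonded) {
  n <- max(length(t37_bonded), length(g62_bonded))
  t37 <- rep_len(as.logical(t37_bonded), n)
  g62 <- rep_len(as.logical(g62_bonded), n)
  lab <- ifelse(t37 & g62, "ACTIVE",
         ifelse(!t37 & !g62, "INACTIVE_1",
         ifelse(!t37 & g62, "INACTIVE_2", "INACTIVE_3")))
  factor(lab, levels = state_levels)
}

.gamma_oxygens <- c("O1G", "O2G", "O3G")

#' Compute the d1/d2 observables and per-frame state labels
#'
#' d1 = distance from the Calpha of the switch I threonine (default residue
#' 37) to the GTP Pbeta atom; d2 = the same from the Calpha of the switch II
#' glycine (default residue 62).  The characteristic bonds are tested with
#' the backbone amide N-H of each residue as donor against any of the
#' gamma-phosphate oxygens O1G/O2G/O3G as acceptor.
#'
#' @param traj an `md_trajectory` containing the protein and a GTP residue.
#' @param resid_t37,resid_g62 residue numbers of the two marker residues.
#' @param gtp_resname residue name of the nucleotide (default "GTP").
#' @param criterion an [hbond_criterion()].
#' @return data.frame of class `"state_series"` with per-frame columns
#'   `frame`, `d1`, `d2`, `t37_bonded`, `g62_bonded`, `state`.
#' @export
state_series <- function(traj, resid_t37 = 37L, resid_g62 = 62L,
                         gtp_resname = "GTP",
                         criterion = hbond_criterion()) {
  at <- traj$atoms
  need <- function(resid, name, what) {
    i <- which(at$resid == resid & at$name == name)
    if (length(i) != 1L) stop("selection error: need exactly one ", what)
    i
  }
  iPB <- which(at$resname == gtp_resname & at$name == "PB")
  if (length(iPB) != 1L) stop("selection error: need exactly one ",
                              gtp_resname, " PB atom")
  iCA1 <- need(resid_t37, "CA", paste0("CA of residue ", resid_t37))
  iCA2 <- need(resid_g62, "CA", paste0("CA of residue ", resid_g62))
  iN1 <- need(resid_t37, "N", paste0("N of residue ", resid_t37))
  iN2 <- need(resid_g62, "N", paste0("N of residue ", resid_g62))
  accs <- which(at$resname == gtp_resname & at$name %in% .gamma_oxygens)
  if (!length(accs)) stop("selection error: no gamma-phosphate oxygens")

  co <- traj$coords
  dist_series <- function(i, j) {
    d <- co[i, , , drop = FALSE] - co[j, , , drop = FALSE]
    sqrt(colSums(matrix(d, nrow = 3L)^2))
  }
  d1 <- dist_series(iCA1, iPB)
  d2 <- dist_series(iCA2, iPB)
  t37 <- hbond_series(traj, iN1, accs, criterion)
  g62 <- hbond_series(traj, iN2, accs, criterion)
  out <- data.frame(frame = seq_len(n_frames(traj)), d1 = d1, d2 = d2,
                    t37_bonded = t37, g62_bonded = g62,
                    state = classify_state(t37, g62))
  class(out) <- c("state_series", "data.frame")
  out
}

#' State populations over an analysis window
#'
#' @param series a `state_series` (or list of them, one per replicate; the
#'   pooled populations are then reported together with per-replicate ones).
#' @param window trailing fraction of frames to analyse, in (0, 1]
#'   (default 1).
#' @return for a single series, a named numeric vector over the four states
#'   summing to 1; for a list, a matrix with one row per replicate plus a
#'   `"pooled"` row.
#' @export
state_populations <- function(series, window = 1) {
  one <- function(s) {
    stopifnot(inherits(s, "state_series") || is.data.frame(s))
    nf <- nrow(s)
    keep <- ceiling(window * nf)
    if (window <= 0 || window > 1 || keep == 0L) {
      stop("empty analysis window")
    }
    st <- factor(s$state[seq.int(nf - keep + 1L, nf)], levels = state_levels)
    as.vector(table(st)) / keep
  }
  if (is.data.frame(series)) {
    p <- one(series)
    names(p) <- state_levels
    return(p)
  }
  per <- t(vapply(series, one, numeric(4)))
  colnames(per) <- state_levels
  nfr <- vapply(series, function(s) ceiling(window * nrow(s)), numeric(1))
  pooled <- colSums(per * nfr) / sum(nfr)
  rbind(per, pooled = pooled)
}

#' Probability histogram of a distance observable
#'
#' Half-open bins `[lo, hi)` of constant width; bin probabilities sum to 1.
#'
#' @param series a `state_series` (or any data.frame with the column).
#' @param which `"d1"` or `"d2"`.
#' @param bin_width bin width in Angstrom (default 0.2).
#' @return data.frame with `lo`, `hi`, `mid`, `prob`.
#' @export
distance_histogram <- function(series, which = c("d1", "d2"),
                               bin_width = 0.2) {
  which <- match.arg(which)
  stopifnot(bin_width > 0)
  x <- series[[which]]
  lo0 <- floor(min(x) / bin_width) * bin_width
  breaks <- seq(lo0, max(x) + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(x, breaks), nbins = length(breaks) - 1L)
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1L],
             mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             prob = cnt / length(x))
}
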