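# Solvent-accessible surface area and catalytic-site water counting.
#
# Two SASA algorithms: a numerical Shrake-Rupley quadrature (deterministic
# golden-spiral point set; serves as the exact oracle) and the analytical
# LCPO approximation (linear combination of pairwise overlaps).

#' Bondi van der Waals radii
#' @return named numeric vector, Angstrom, keyed by element symbol.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
    MG = 1.73, "NA" = 2.27, CL = 1.75, K = 2.75, F = 1.47)
}

#' Radii used by the LCPO parameterization
#'
#' The radius set the LCPO parameters were fitted with (hydrogens are
#' excluded from the LCPO model and carry radius 0).
#' @return named numeric vector, Angstrom.
#' @export
lcpo_radii <- function() {
  c(C = 1.70, N = 1.65, O = 1.60, S = 1.90, P = 1.90, MG = 1.18, H = 0)
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral construction; the same `n` always yields the same points.
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * k
  cbind(r * cos(phi), r * sin(phi), z)
}

.radius_for <- function(elements, radii) {
  r <- radii[elements]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Shrake-Rupley numerical SASA
#'
#' Per-atom accessible area = (exposed points / n_points) * 4 pi (r+probe)^2,
#' with test points from the deterministic golden-spiral construction and
#' occlusion tested against every other atom of the frame (atoms with radius
#' 0 never occlude).
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index.
#' @param sel an `atom_selection` or integer indices of atoms to report
#'   (default: all atoms).  Occluders are always all atoms.
#' @param n_points points per sphere (>= 32; default 960).
#' @param radii named radius vector by element (default [bondi_radii()]).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param points optional explicit unit-sphere point matrix replacing the
#'   golden-spiral set (the quadrature is exactly rotation-invariant only
#'   when the point set is rotated together with the frame).
#' @return list of class `"sasa_result"`: `atom_area` (named by atom index),
#'   `total`, `method`.
#' @export
shrake_rupley <- function(traj, frame = 1L, sel = NULL, n_points = 960L,
                          radii = bondi_radii(), probe = 1.4,
                          points = NULL) {
  fc <- frame_coords(traj, frame)
  r <- .radius_for(traj$atoms$element, radii)
  idx <- if (is.null(sel)) seq_len(nrow(fc)) else
    if (inherits(sel, "atom_selection")) sel$indices else as.integer(sel)
  if (is.null(points)) {
    stopifnot(n_points >= 32L)
    points <- golden_spiral_points(n_points)
  }
  pts <- points
  n_points <- nrow(pts)
  occl <- which(r > 0)
  areas <- vapply(idx, function(i) {
    ri <- r[i] + probe
    if (r[i] <= 0) return(0)
    p <- sweep(pts * ri, 2, fc[i, ], "+")
    nb <- occl[occl != i]
    d2 <- colSums((t(fc[nb, , drop = FALSE]) - fc[i, ])^2)
    nb <- nb[d2 < (ri + r[nb] + probe)^2]
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      rj <- r[j] + probe
      dj2 <- (p[, 1] - fc[j, 1])^2 + (p[, 2] - fc[j, 2])^2 +
        (p[, 3] - fc[j, 3])^2
      exposed <- exposed & (dj2 >= rj^2)
      if (!any(exposed)) break
    }
    sum(exposed) / n_points * 4 * pi * ri^2
  }, numeric(1))
  names(areas) <- idx
  structure(list(atom_area = areas, total = sum(areas),
                 method = "shrake_rupley"), class = "sasa_result")
}

# LCPO parameter table (element + bonded heavy-neighbour count).
# P1..P4 are the linear-combination weights; radius from lcpo_radii().
# An atom with zero bonded heavy neighbours has no published row; the exact
# isolated-sphere limit (P1 = 1) is used for it.
.lcpo_table <- local({
  tab <- rbind(
    c("C", 1, 0.77887, -0.28063, -0.0012968, 0.00039328),   # sp3 C, 1 nb
    c("C", 2, 0.56482, -0.19608, -0.0010219, 0.0002658),    # sp3 C, 2 nb
    c("C", 3, 0.23348, -0.072627, -0.00020079, 0.00007967), # sp3/sp2 C, 3 nb
    c("C", 4, 0.00000, 0.00000, 0.00000, 0.00000),          # quaternary C
    c("N", 1, 0.73511, -0.22116, -0.00089148, 0.0002523),   # amide-like N
    c("N", 2, 0.41102, -0.12254, -0.000075448, 0.00011804), # ring N
    c("N", 3, 0.062577, -0.017874, -0.00008312, 0.000019849),
    c("O", 1, 0.77914, -0.25262, -0.0016056, 0.00035071),   # hydroxyl O
    c("O", 2, 0.49392, -0.16038, -0.00015512, 0.00016453),  # ester/ether O
    c("OC", 1, 0.68563, -0.1868, -0.00135573, 0.00023743),  # carbonyl O
    c("OX", 1, 0.88857, -0.33421, -0.0018683, 0.00049372),  # charged O (P/carboxylate)
    c("S", 1, 0.7722, -0.26393, 0.0010629, 0.0002179),
    c("S", 2, 0.54581, -0.19477, -0.0012873, 0.00029247),
    c("P", 3, 0.3865, -0.18249, -0.0036598, 0.0004264),
    c("P", 4, 0.03873, -0.0089339, 0.0000083582, 0.0000030381)
  )
  data.frame(element = tab[, 1], nb = as.integer(tab[, 2]),
             P1 = as.numeric(tab[, 3]), P2 = as.numeric(tab[, 4]),
             P3 = as.numeric(tab[, 5]), P4 = as.numeric(tab[, 6]),
             stringsAsFactors = FALSE)
})

#' Assign LCPO parameters to atoms
#'
#' Heavy-atom bonds are inferred from frame-1 geometry (neighbour within
#' 1.9 A; 2.0 A when either atom is P or S); parameters are keyed on element
#' and bonded heavy-neighbour count.  Hydrogens are excluded from the LCPO
#' model.  Atoms with zero bonded heavy neighbours get the exact
#' isolated-sphere parameters (P1 = 1).
#'
#' @param traj an `md_trajectory`.
#' @param frame frame used to infer bonds (default 1).
#' @return data.frame with one row per atom: `element`, `nb`, `P1..P4`,
#'   `radius` (LCPO radius + 0 for H).
#' @export
lcpo_assign <- function(traj, frame = 1L) {
  at <- traj$atoms
  fc <- frame_coords(traj, frame)
  rl <- lcpo_radii()
  heavy <- which(at$element != "H")
  n <- nrow(at)
  nb <- integer(n)
  for (i in heavy) {
    cut <- ifelse(at$element[i] %in% c("P", "S") |
                    at$element[heavy] %in% c("P", "S"), 2.0, 1.9)
    d <- sqrt(colSums((t(fc[heavy, , drop = FALSE]) - fc[i, ])^2))
    nb[i] <- sum(d > 1e-6 & d < cut)
  }
  # neighbour lists for type refinement (oxygen sub-types)
  nbl <- lapply(seq_len(n), function(i) {
    if (at$element[i] == "H") return(integer())
    cut <- ifelse(at$element[i] %in% c("P", "S") |
                    at$element[heavy] %in% c("P", "S"), 2.0, 1.9)
    d <- sqrt(colSums((t(fc[heavy, , drop = FALSE]) - fc[i, ])^2))
    heavy[d > 1e-6 & d < cut]
  })
  out <- data.frame(element = at$element, nb = nb, P1 = NA_real_,
                    P2 = 0, P3 = 0, P4 = 0, radius = 0)
  for (i in heavy) {
    el <- at$element[i]
    if (is.na(rl[el])) {
      stop("no LCPO parameters for atom ", at$name[i], " (element ", el,
           ", residue ", at$resid[i], ")")
    }
    out$radius[i] <- rl[[el]]
    if (nb[i] == 0L) { out$P1[i] <- 1; next }
    key <- el
    if (el == "O" && nb[i] == 1L) {
      j <- nbl[[i]][1]
      key <- if (at$element[j] == "P") "OX"                 # phosphate O
      else if (at$element[j] == "C" && nb[j] >= 3L) "OC"    # carbonyl O
      else "O"
    }
    if (!key %in% .lcpo_table$element) {
      # element outside the parameterized organic set (e.g. an ion):
      # isolated-sphere limit regardless of contact count
      out$P1[i] <- 1
      next
    }
    avail <- .lcpo_table$nb[.lcpo_table$element == key]
    use_nb <- avail[which.min(abs(avail - nb[i]))]  # nearest parameterized
    row <- .lcpo_table[.lcpo_table$element == key &
                         .lcpo_table$nb == use_nb, ]
    if (nrow(row) != 1L) {
      stop("no LCPO parameters for atom ", at$name[i], " (element ", el,
           ", ", nb[i], " bonded neighbours, residue ", at$resid[i], ")")
    }
    out$P1[i] <- row$P1; out$P2[i] <- row$P2
    out$P3[i] <- row$P3; out$P4[i] <- row$P4
  }
  out$P1[at$element == "H"] <- 0
  out
}

# pairwise buried area of sphere i by sphere j (both radii include probe)
.aij <- function(ri, rj, d) {
  2 * pi * ri * (ri - d / 2 - (ri^2 - rj^2) / (2 * d))
}

#' LCPO analytical SASA
#'
#' Linear combination of pairwise overlaps:
#' A_i = P1 S1 + P2 sum_j A_ij + P3 sum_(j,k) A_jk + P4 sum_j A_ij sum_k A_jk,
#' where S1 = 4 pi (r_i + probe)^2, A_ij is the area of sphere i buried by
#' neighbour j, and the P3/P4 sums run over neighbour pairs (j, k) of atom i
#' that are themselves neighbours.  Negative per-atom estimates are clamped
#' to 0.  Hydrogens carry zero area and never occlude.
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index.
#' @param sel atoms to report (default: all).  Occluders are all heavy atoms.
#' @param params optional [lcpo_assign()] table (recomputed otherwise).
#' @param probe probe radius, Angstrom (default 1.4).
#' @return list of class `"sasa_result"`: `atom_area`, `total`, `method`.
#' @export
lcpo <- function(traj, frame = 1L, sel = NULL, params = NULL, probe = 1.4) {
  if (is.null(params)) params <- lcpo_assign(traj)
  fc <- frame_coords(traj, frame)
  idx <- if (is.null(sel)) seq_len(nrow(fc)) else
    if (inherits(sel, "atom_selection")) sel$indices else as.integer(sel)
  r <- ifelse(params$element == "H", 0, params$radius + probe)
  heavy <- which(r > 0)
  # overlap neighbour lists among heavy atoms (distance < ri + rj)
  nbl <- vector("list", nrow(fc))
  aij <- vector("list", nrow(fc))
  for (i in heavy) {
    others <- heavy[heavy != i]
    d <- sqrt(colSums((t(fc[others, , drop = FALSE]) - fc[i, ])^2))
    keep <- d < (r[i] + r[others]) & d > 1e-9
    nbl[[i]] <- others[keep]
    a <- .aij(r[i], r[others][keep], d[keep])
    names(a) <- others[keep]
    aij[[i]] <- a
  }
  areas <- vapply(idx, function(i) {
    if (r[i] <= 0) return(0)
    S1 <- 4 * pi * r[i]^2
    js <- nbl[[i]]
    if (!length(js)) return(params$P1[i] * S1)
    sum_aij <- sum(aij[[i]])
    s3 <- 0; s4 <- 0
    for (j in js) {
      ks <- intersect(nbl[[j]], js)
      if (!length(ks)) next
      ajk <- sum(aij[[j]][as.character(ks)])
      s3 <- s3 + ajk
      s4 <- s4 + aij[[i]][[as.character(j)]] * ajk
    }
    max(0, params$P1[i] * S1 + params$P2[i] * sum_aij +
          params$P3[i] * s3 + params$P4[i] * s4)
  }, numeric(1))
  names(areas) <- idx
  structure(list(atom_area = areas, total = sum(areas), method = "lcpo"),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %s: %d atoms, total %.2f A^2\n", x$method,
              length(x$atom_area), x$total))
  invisible(x)
}

#' Windowed SASA series over replicates
#'
#' Per-frame selection totals over the trailing analysis window of each
#' replicate; reports the pooled mean (frame-count weighted across
#' replicates), per-replicate means, and the SD across replicate means.
#'
#' @param trajs list of `md_trajectory` replicates.
#' @param sel_query selection query string (default `"resname GTP"`).
#' @param window trailing window fraction (default 0.6).
#' @param method `"lcpo"` (default) or `"shrake_rupley"`.
#' @param ... passed to the SASA backend.
#' @return list: `per_frame` (list of numeric vectors), `replicate_means`,
#'   `mean` (pooled), `sd` (across replicate means).
#' @export
selection_sasa_series <- function(trajs, sel_query = "resname GTP",
                                  window = 0.6,
                                  method = c("lcpo", "shrake_rupley"), ...) {
  method <- match.arg(method)
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  per_frame <- lapply(trajs, function(tr) {
    wt <- analysis_window(tr, window)
    sel <- select_atoms(wt, sel_query)
    if (!length(sel$indices)) stop("empty selection: ", sel_query)
    params <- if (method == "lcpo") lcpo_assign(wt) else NULL
    vapply(seq_len(n_frames(wt)), function(f) {
      if (method == "lcpo") lcpo(wt, f, sel, params = params, ...)$total
      else shrake_rupley(wt, f, sel, ...)$total
    }, numeric(1))
  })
  rmeans <- vapply(per_frame, mean, numeric(1))
  nfr <- lengths(per_frame)
  list(per_frame = per_frame, replicate_means = rmeans,
       mean = sum(rmeans * nfr) / sum(nfr),
       sd = if (length(rmeans) > 1L) stats::sd(rmeans) else 0)
}

#' Percent decrease between two means
#'
#' `100 * (reference - value) / reference`; the arithmetic used to compare
#' e.g. mutant vs wild-type mean GTP SASA.
#' @param reference,value numeric scalars.
#' @return percent decrease (positive when `value < reference`).
#' @export
percent_decrease <- function(reference, value) {
  100 * (reference - value) / reference
}

#' Count water molecules around a site
#'
#' Number of distinct water molecules (resname HOH/WAT) whose oxygen lies
#' strictly within `cutoff` of ANY site atom; each molecule counts once.
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index.
#' @param site an `atom_selection` or integer indices of the site atoms
#'   (canonically the gamma-phosphate group PG, O1G, O2G, O3G).
#' @param cutoff distance cutoff, Angstrom (default 3.0).
#' @param water_resnames residue names identifying waters.
#' @return integer count.
#' @export
count_waters <- function(traj, frame = 1L, site, cutoff = 3.0,
                         water_resnames = c("HOH", "WAT")) {
  stopifnot(cutoff > 0)
  sidx <- if (inherits(site, "atom_selection")) site$indices else
    as.integer(site)
  at <- traj$atoms
  wo <- which(at$resname %in% water_resnames & at$element == "O")
  if (!length(wo)) {
    warning("no water molecules in topology")
    return(0L)
  }
  fc <- frame_coords(traj, frame)
  near <- logical(length(wo))
  for (s in sidx) {
    d2 <- colSums((t(fc[wo, , drop = FALSE]) - fc[s, ])^2)
    near <- near | (d2 < cutoff^2)
  }
  length(unique(at$resid[wo][near]))
}

#' Windowed water-count summary over replicates
#'
#' @param trajs list of `md_trajectory` replicates.
#' @param site_query selection query for the site (default the
#'   gamma-phosphate group).
#' @param window trailing window fraction (default 0.6).
#' @param cutoff distance cutoff, Angstrom (default 3.0).
#' @return list: `counts` (list of per-frame integer vectors), `mean`
#'   (over all window frames of all replicates), `histogram` (normalized
#'   count distribution).
#' @export
water_count_summary <- function(trajs,
                                site_query =
                                  "name PG OR name O1G OR name O2G OR name O3G",
                                window = 0.6, cutoff = 3.0) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  counts <- lapply(trajs, function(tr) {
    wt <- analysis_window(tr, window)
    if (n_frames(wt) == 0L) stop("empty analysis window")
    site <- select_atoms(wt, site_query)
    vapply(seq_len(n_frames(wt)), function(f) count_waters(wt, f, site, cutoff),
           integer(1))
  })
  all <- unlist(counts)
  h <- table(factor(all, levels = seq.int(0L, max(all))))
  list(counts = counts, mean = mean(all),
       histogram = as.numeric(h) / length(all),
       levels = as.integer(names(h)))
}
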