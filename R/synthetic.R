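# Synthetic GTPase-like reference structures and stochastic trajectories
# with planted ground truth: Markov conformational-state sequences, the two
# characteristic gamma-phosphate hydrogen-bond geometries, per-region
# fluctuation amplitudes, and a gamma-phosphate water shell.
#
# The toy system is a reduced pseudo-complex (P-loop, switch I and switch II
# fragments, GTP, Mg, a water bath), not a stereochemically consistent
# protein: only the geometry the analyses touch is controlled.

# ---- small vector helpers ----------------------------------------------

.unit <- function(v) v / sqrt(sum(v^2))
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# NeRF placement: position of atom D given A-B-C, bond r (C-D), angle theta
# (B-C-D, degrees) and torsion phi (A-B-C-D, degrees).
.nerf <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# points at distance r1 from c1 and r2 from c2 lie on a circle; pick the
# circle point maximizing `score` (scanned at 1-degree steps, deterministic)
.two_sphere_point <- function(c1, r1, c2, r2, score) {
  d <- sqrt(sum((c2 - c1)^2))
  stopifnot(d > abs(r1 - r2), d < r1 + r2)
  u <- .unit(c2 - c1)
  x <- (d^2 + r1^2 - r2^2) / (2 * d)
  rho <- sqrt(r1^2 - x^2)
  center <- c1 + x * u
  w <- .cross(u, c(0, 0, 1))
  if (sqrt(sum(w^2)) < 1e-9) w <- .cross(u, c(0, 1, 0))
  w <- .unit(w)
  v <- .cross(u, w)
  best <- NULL; best_s <- -Inf
  for (th in seq(0, 2 * pi, length.out = 361L)[-361L]) {
    p <- center + rho * (cos(th) * w + sin(th) * v)
    s <- score(p)
    if (s > best_s) { best_s <- s; best <- p }
  }
  best
}

# the two remaining tetrahedral bond directions at `center` given two
# existing bonded neighbours
.tetra_complete <- function(center, b1, b2) {
  n1 <- .unit(b1 - center); n2 <- .unit(b2 - center)
  bis <- -.unit(n1 + n2)
  perp <- .unit(.cross(n1, n2))
  phi <- 54.735 * pi / 180
  list(d1 = .unit(bis * cos(phi) + perp * sin(phi)),
       d2 = .unit(bis * cos(phi) - perp * sin(phi)))
}

# ---- backbone / peptide construction -----------------------------------

#' Build an idealized poly-peptide backbone
#'
#' Ideal bond geometry with the given backbone dihedrals; atoms N, H, CA, C,
#' O per residue (no H on the first residue) plus a CB for non-glycine
#' residues.  Used for synthetic fragments and as a generator of ideal
#' helices/strands.
#'
#' @param resnames character vector of 3-letter residue names.
#' @param phi,psi backbone dihedrals in degrees (recycled); defaults are the
#'   ideal alpha-helix values.
#' @param resid_start first residue number (default 1).
#' @param dt frame spacing for the returned single-frame trajectory.
#' @return an `md_trajectory` with one frame.
#' @export
build_peptide <- function(resnames, phi = -57, psi = -47, resid_start = 1L,
                          dt = 2) {
  n <- length(resnames)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  # seed triad
  N <- list(); CA <- list(); C <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(1.458, 0, 0)
  C[[1]] <- .nerf(c(-1, 1, 0), N[[1]], CA[[1]], 1.525, 111.2, psi[1] + 120)
  for (i in seq_len(n)[-1]) {
    N[[i]] <- .nerf(N[[i - 1]], CA[[i - 1]], C[[i - 1]], 1.329, 116.2,
                    psi[i - 1])
    CA[[i]] <- .nerf(CA[[i - 1]], C[[i - 1]], N[[i]], 1.458, 121.7, 180)
    C[[i]] <- .nerf(C[[i - 1]], N[[i]], CA[[i]], 1.525, 111.2, phi[i])
  }
  rows <- list(); xyz <- list()
  put <- function(name, el, resid, resname, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = NA_integer_, name = name, resname = resname, resid = resid,
      element = el, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- p
  }
  for (i in seq_len(n)) {
    r <- resid_start + i - 1L
    put("N", "N", r, resnames[i], N[[i]])
    if (i > 1L) {
      u1 <- .unit(N[[i]] - C[[i - 1]]); u2 <- .unit(N[[i]] - CA[[i]])
      put("H", "H", r, resnames[i], N[[i]] + 1.01 * .unit(u1 + u2))
    }
    put("CA", "C", r, resnames[i], CA[[i]])
    put("C", "C", r, resnames[i], C[[i]])
    o <- if (i < n) {
      .nerf(N[[i]], CA[[i]], C[[i]], 1.231, 120.5, psi[i] + 180)
    } else {
      .nerf(N[[i]], CA[[i]], C[[i]], 1.231, 120.5, psi[i] + 180)
    }
    put("O", "O", r, resnames[i], o)
    if (resnames[i] != "GLY") {
      put("CB", "C", r, resnames[i],
          .nerf(C[[i]], N[[i]], CA[[i]], 1.53, 110.5, -122))
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  trajectory(atoms, do.call(rbind, xyz), dt = dt)
}

# append simple toy side-chain heavy atoms beyond CB for selected residues;
# the extension direction is chosen deterministically to maximize clearance
# from `obstacles` (all atoms placed so far)
.extend_sidechain <- function(atoms, xyz, resid, names_els,
                              obstacles = NULL) {
  iCA <- which(atoms$resid == resid & atoms$name == "CA")
  iCB <- which(atoms$resid == resid & atoms$name == "CB")
  u0 <- .unit(xyz[iCB, ] - xyz[iCA, ])
  obst <- rbind(obstacles, xyz[atoms$resid != resid, , drop = FALSE])
  cands <- golden_spiral_points(40L)
  cands <- cands[cands %*% u0 > 0.25, , drop = FALSE]
  score <- vapply(seq_len(nrow(cands)), function(k) {
    tip <- xyz[iCB, ] + 3.2 * cands[k, ]
    midp <- xyz[iCB, ] + 1.8 * cands[k, ]
    min(colSums((t(obst) - tip)^2), colSums((t(obst) - midp)^2))
  }, numeric(1))
  u <- cands[which.max(score), ]
  perp <- .unit(.cross(u, c(0, 0, 1)))
  if (!all(is.finite(perp))) perp <- .unit(.cross(u, c(0, 1, 0)))
  perp2 <- .cross(u, perp)
  k <- 0
  for (ne in names_els) {
    k <- k + 1
    p <- xyz[iCB, ] + (0.8 + 0.75 * k) * u +
      1.1 * ifelse(k %% 2 == 0, 1, -1) * perp + 0.3 * k * perp2
    atoms <- rbind(atoms, data.frame(
      serial = NA_integer_, name = ne[[1]], resname = atoms$resname[iCA],
      resid = resid, element = ne[[2]], stringsAsFactors = FALSE))
    xyz <- rbind(xyz, p)
  }
  list(atoms = atoms, xyz = xyz)
}

# ---- specification ------------------------------------------------------

#' Transition matrix with a prescribed stationary distribution
#'
#' `P = persistence * I + (1 - persistence) * 1 pi^T`: every row mixes a
#' self-loop with independent redraws from `stationary`, so `stationary` is
#' the exact stationary law and `persistence` the one-step autocorrelation.
#'
#' @param stationary length-4 probability vector over
#'   (ACTIVE, INACTIVE_1, INACTIVE_2, INACTIVE_3).
#' @param persistence self-loop weight in [0, 1) (default 0.2).
#' @return 4 x 4 row-stochastic matrix.
#' @export
default_transition_matrix <- function(stationary = c(0.70, 0.20, 0.10, 0.00),
                                      persistence = 0.2) {
  stopifnot(length(stationary) == 4L, abs(sum(stationary) - 1) < 1e-12,
            all(stationary >= 0), persistence >= 0, persistence < 1)
  P <- persistence * diag(4) +
    (1 - persistence) * matrix(stationary, 4, 4, byrow = TRUE)
  dimnames(P) <- list(state_levels, state_levels)
  P
}

#' Specification of a synthetic GTPase trajectory
#'
#' @param n_frames number of frames (>= 1).
#' @param dt frame spacing, ps (default 2).
#' @param transition_matrix 4 x 4 row-stochastic matrix over the state
#'   labels (default: [default_transition_matrix()]).
#' @param bonded_geometry list `mean`, `sd`, `max` (A) for the donor-acceptor
#'   heavy-atom distance of a formed bond (normal truncated above at `max`,
#'   which must stay < 3.5) and `angle_range` (degrees at the hydrogen).
#' @param unbonded_geometry list `mean`, `sd`, `min` (A) for a broken bond
#'   (truncated below at `min` >= 3.7).
#' @param fluct_sigma isotropic positional noise SD, A: a scalar or a named
#'   vector over regions `ploop`, `switch1`, `switch2`, `nucleotide`,
#'   `other` (waters are placed explicitly each frame and carry no noise
#'   term).
#' @param water_lambda named per-state Poisson mean of the number of waters
#'   within 3.0 A of the gamma-phosphate group.
#' @param res63 residue type at position 63: `"GLN"` (wild-type-like) or
#'   `"LEU"` (Q63L-like).
#' @param n_waters size of the water bath (>= 20).
#' @param seed integer RNG seed.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_frames = 500L, dt = 2,
                           transition_matrix = default_transition_matrix(),
                           bonded_geometry = list(mean = 2.9, sd = 0.1,
                                                  max = 3.4,
                                                  angle_range = c(150, 180)),
                           unbonded_geometry = list(mean = 4.5, sd = 0.3,
                                                    min = 3.7),
                           fluct_sigma = 0.35,
                           water_lambda = c(ACTIVE = 2, INACTIVE_1 = 5,
                                            INACTIVE_2 = 3, INACTIVE_3 = 3),
                           res63 = c("GLN", "LEU"),
                           n_waters = 24L, seed = 42L) {
  res63 <- match.arg(res63)
  stopifnot(n_frames >= 1L, dt > 0, n_waters >= 20L)
  P <- transition_matrix
  if (!is.matrix(P) || any(dim(P) != 4L) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("transition_matrix must be 4 x 4 row-stochastic")
  }
  stopifnot(bonded_geometry$sd > 0, unbonded_geometry$sd > 0,
            bonded_geometry$mean < 3.5, bonded_geometry$max < 3.5,
            unbonded_geometry$min >= 3.7)
  regions <- c("ploop", "switch1", "switch2", "nucleotide", "other")
  if (length(fluct_sigma) == 1L && is.null(names(fluct_sigma))) {
    fluct_sigma <- stats::setNames(rep(fluct_sigma, 5L), regions)
  } else {
    miss <- setdiff(regions, names(fluct_sigma))
    if (length(miss)) stop("fluct_sigma missing region(s): ",
                           paste(miss, collapse = ", "))
  }
  stopifnot(all(fluct_sigma > 0))
  stopifnot(all(state_levels %in% names(water_lambda)),
            all(water_lambda >= 0))
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 transition_matrix = P, bonded_geometry = bonded_geometry,
                 unbonded_geometry = unbonded_geometry,
                 fluct_sigma = fluct_sigma,
                 water_lambda = water_lambda[state_levels], res63 = res63,
                 n_waters = as.integer(n_waters), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Preset synthetic specifications for the three RhoA-like systems
#'
#' Qualitative ensembles: `wt` is INACTIVE_1-dominant with flexible
#' switches, `g14v` is ACTIVE-dominant with rigid switches, `q63l` is
#' INACTIVE_3-dominant with a rigid switch I.
#'
#' @param system one of `"wt"`, `"g14v"`, `"q63l"`.
#' @param ... overrides passed on to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
preset_spec <- function(system = c("wt", "g14v", "q63l"), ...) {
  system <- match.arg(system)
  args <- switch(system,
    wt = list(
      transition_matrix = default_transition_matrix(c(0.01, 0.85, 0.00, 0.14)),
      fluct_sigma = c(ploop = 0.25, switch1 = 0.55, switch2 = 0.55,
                      nucleotide = 0.20, other = 0.35)),
    g14v = list(
      transition_matrix = default_transition_matrix(c(0.95, 0.01, 0.00, 0.04)),
      fluct_sigma = c(ploop = 0.20, switch1 = 0.30, switch2 = 0.30,
                      nucleotide = 0.18, other = 0.30)),
    q63l = list(
      transition_matrix = default_transition_matrix(c(0.05, 0.17, 0.00, 0.78)),
      fluct_sigma = c(ploop = 0.22, switch1 = 0.32, switch2 = 0.50,
                      nucleotide = 0.20, other = 0.32),
      res63 = "LEU"))
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left fixed vector of the chain; fails when the stationary law is not
#' unique (more than one recurrent class, e.g. the identity matrix).
#'
#' @param P row-stochastic square matrix.
#' @return probability vector (entries >= 0, sums to 1).
#' @export
stationary_distribution <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < -1e-12) ||
      any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("P must be row-stochastic")
  }
  e <- eigen(t(P))
  one <- which(abs(e$values - 1) < 1e-8)
  if (length(one) != 1L) {
    stop("stationary distribution is not unique (reducible chain)")
  }
  v <- Re(e$vectors[, one])
  v <- v / sum(v)
  if (any(v < -1e-9)) stop("invalid stationary vector")
  pmax(v, 0) / sum(pmax(v, 0))
}

# ---- reference structure ------------------------------------------------

.region_of <- function(atoms) {
  out <- rep("other", nrow(atoms))
  out[atoms$resid >= 12 & atoms$resid <= 20 &
        !(atoms$resname %in% c("GTP", "MG", "WAT"))] <- "ploop"
  out[atoms$resid >= 32 & atoms$resid <= 42 &
        !(atoms$resname %in% c("GTP", "MG", "WAT"))] <- "switch1"
  out[atoms$resid >= 60 & atoms$resid <= 78 &
        !(atoms$resname %in% c("GTP", "MG", "WAT"))] <- "switch2"
  out[atoms$resname %in% c("GTP", "MG")] <- "nucleotide"
  out[atoms$resname == "WAT"] <- "water"
  out
}

#' Build the synthetic reference complex
#'
#' A reduced GTPase-GTP-Mg pseudo-complex: P-loop fragment (residues 12-20),
#' switch I fragment (32-42, including Y34, V35, P36, T37, V38, F39),
#' switch II fragment (60-70, including G62, residue 63, Y66, L69), a full
#' heavy-atom GTP, one Mg ion, and a bath of water oxygens.  The template is
#' the ACTIVE conformation: both characteristic amide-to-gamma-phosphate
#' hydrogen bonds are formed and the Mg ion carries its six-ligand
#' (hexahedral) coordination shell at 2.0-2.2 A (one oxygen from each
#' phosphate, T19 OG1, T37 OG1, V35 backbone O).
#'
#' @param spec a [synthetic_spec()] (only `res63`, `n_waters`, `dt` are
#'   used here).
#' @return single-frame `md_trajectory`.
#' @export
build_reference <- function(spec = synthetic_spec()) {
  mg <- c(0, 0, 0)
  # hexahedral coordination sites
  O1B <- c(2.05, 0, 0)
  O2G <- c(0, 2.08, 0)
  O2A <- c(0, 0, -2.06)
  OG1_19 <- c(-2.10, 0, 0)
  OG1_37 <- c(0, -2.10, 0)
  O_35 <- c(0, 0, 2.15)
  # beta and gamma phosphorus via the six-ring Mg-O1B-PB-O3B-PG-O2G
  PB <- c(2.05 + 1.50 * cos(50 * pi / 180), 1.50 * sin(50 * pi / 180), 0)
  PG <- c(1.50 * sin(50 * pi / 180), 2.08 + 1.50 * cos(50 * pi / 180), 0)
  mid <- (PB + PG) / 2
  h <- sqrt(max(0, 1.60^2 - sum((PB - mid)^2)))
  O3B <- mid + c(0, 0, h)
  # remaining tetrahedral oxygens on PG and PB
  tg <- .tetra_complete(PG, O2G, O3B)
  O1G <- PG + 1.48 * tg$d1
  O3G <- PG + 1.48 * tg$d2
  tb <- .tetra_complete(PB, O1B, O3B)
  # alpha bridge: O3A at 1.60 from PB near one free tetra direction,
  # positioned so PA can bond both O3A and the Mg-site oxygen O2A;
  # O2B takes the other free tetra direction
  clear <- function(p, pts, target) {
    min(vapply(pts, function(q) sqrt(sum((p - q)^2)), numeric(1)) - target, 0)
  }
  O3A <- .two_sphere_point(PB, 1.60, O2A, 2.90, function(p) {
    clear(p, list(O1B, O3B, O2G, O1G, O3G), 2.2) +
      clear(p, list(mg), 2.5) + 0.01 * sqrt(sum((p - mg)^2))
  })
  O2B <- PB + 1.48 *
    (if (sum((PB + tb$d1 - O3A)^2) > sum((PB + tb$d2 - O3A)^2)) tb$d1
     else tb$d2)
  PA <- .two_sphere_point(O2A, 1.50, O3A, 1.60, function(p) {
    clear(p, list(O1B, O2B, O3B, O2G), 2.6) + clear(p, list(mg), 2.6) +
      0.01 * sqrt(sum((p - mg)^2))
  })
  ta <- .tetra_complete(PA, O2A, O3A)
  O1A <- PA + 1.48 * ta$d1
  O5p <- PA + 1.60 * ta$d2
  # ribose: planar pentagon C4'-O4'-C1'-C2'-C3' hung off C5'
  C5p <- O5p + 1.43 * .unit(O5p - PA + c(0.3, 0.3, 0.6))
  ring_u <- .unit(C5p - O5p)
  ring_v <- .unit(.cross(ring_u, c(0, 0, 1)))
  r5 <- 1.45 / (2 * sin(36 * pi / 180))
  cen5 <- C5p + 1.52 * ring_u + r5 * ring_v
  pent <- lapply(0:4, function(k) {
    th <- pi + (2 * pi * k) / 5
    cen5 + r5 * (cos(th) * ring_v + sin(th) * .cross(ring_u, ring_v)) * 1 +
      r5 * 0 * ring_u
  })
  C4p <- pent[[1]]; O4p <- pent[[2]]; C1p <- pent[[3]]
  C2p <- pent[[4]]; C3p <- pent[[5]]
  O3p <- C3p + 1.42 * .unit(C3p - cen5)
  O2p <- C2p + 1.42 * .unit(C2p - cen5)
  # guanine: planar fused 6+5 ring attached at N9 = C1' + 1.47
  g_u <- .unit(C1p - cen5)
  g_w <- .unit(.cross(g_u, ring_v))
  N9 <- C1p + 1.47 * g_u
  hexc <- N9 + 2.6 * g_u
  hex_at <- function(deg) {
    th <- deg * pi / 180
    hexc + 1.39 * (cos(th) * g_u + sin(th) * g_w)
  }
  C4g <- hex_at(180); N3 <- hex_at(240); C2g <- hex_at(300)
  N1 <- hex_at(0); C6 <- hex_at(60); C5g <- hex_at(120)
  # pentagon fused on edge C4-C5
  m45 <- (C4g + C5g) / 2
  out5 <- .unit(m45 - hexc)
  r5g <- 1.39 / (2 * sin(36 * pi / 180))
  cen5g <- m45 + r5g * cos(36 * pi / 180) * out5
  ang0 <- atan2(sum((C4g - cen5g) * g_w), sum((C4g - cen5g) * g_u))
  pent_at <- function(k) {
    th <- ang0 + k * 2 * pi / 5
    cen5g + r5g * (cos(th) * g_u + sin(th) * g_w)
  }
  # walk from C4 away from C5: determine direction by checking k = 1 vs -1
  cand1 <- pent_at(1); cand2 <- pent_at(-1)
  step <- if (sum((cand1 - C5g)^2) > sum((cand2 - C5g)^2)) 1 else -1
  N9g <- pent_at(3 * step)   # should coincide with N9 region
  N7 <- pent_at(2 * step); C8 <- pent_at(3 * step)
  # realign: ring order around pentagon is C4, N9, C8, N7, C5
  N9 <- pent_at(1 * step); C8 <- pent_at(2 * step); N7 <- pent_at(3 * step)
  C1p_adj <- N9 + 1.47 * .unit(C1p - N9)  # keep C1'-N9 bond exact
  C1p <- C1p_adj
  O6 <- C6 + 1.23 * .unit(C6 - hexc)
  N2 <- C2g + 1.34 * .unit(C2g - hexc)

  rows <- list(); xyz <- list()
  put <- function(name, el, resid, resname, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = NA_integer_, name = name, resname = resname, resid = resid,
      element = el, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- p
  }
  gtp <- list(
    PA = list("P", PA), O1A = list("O", O1A), O2A = list("O", O2A),
    O3A = list("O", O3A), PB = list("P", PB), O1B = list("O", O1B),
    O2B = list("O", O2B), O3B = list("O", O3B), PG = list("P", PG),
    O1G = list("O", O1G), O2G = list("O", O2G), O3G = list("O", O3G),
    "O5'" = list("O", O5p), "C5'" = list("C", C5p), "C4'" = list("C", C4p),
    "O4'" = list("O", O4p), "C3'" = list("C", C3p), "O3'" = list("O", O3p),
    "C2'" = list("C", C2p), "O2'" = list("O", O2p), "C1'" = list("C", C1p),
    N9 = list("N", N9), C8 = list("C", C8), N7 = list("N", N7),
    C5 = list("C", C5g), C6 = list("C", C6), O6 = list("O", O6),
    N1 = list("N", N1), C2 = list("C", C2g), N2 = list("N", N2),
    N3 = list("N", N3), C4 = list("C", C4g)
  )
  for (nm in names(gtp)) put(nm, gtp[[nm]][[1]], 201L, "GTP", gtp[[nm]][[2]])
  put("MG", "MG", 202L, "MG", mg)

  # --- protein fragments -------------------------------------------------
  gtp_mg <- do.call(rbind, xyz)
  rodrigues <- function(axis, th) {
    a <- .unit(axis)
    vx <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(th) * vx + (1 - cos(th)) * vx %*% vx
  }
  # rotation mapping unit vector a onto unit vector b
  align_rot <- function(a, b) {
    v <- .cross(a, b)
    s <- sqrt(sum(v^2)); cth <- sum(a * b)
    if (s < 1e-9) {
      if (cth > 0) return(diag(3))
      p <- .unit(.cross(a, c(1, 0, 0)))
      if (!all(is.finite(p))) p <- .unit(.cross(a, c(0, 1, 0)))
      return(rodrigues(p, pi))
    }
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  # Place an extended-strand fragment: orient so a chosen local direction at
  # the anchor atom maps onto `orient_to`, translate the anchor to `target`,
  # then roll about the orientation axis to the clearance-optimal azimuth
  # (deterministic 5-degree scan against everything placed so far).
  frag <- function(resnames, resid_start, anchor_resid, anchor_name,
                   target, orient_to, obstacles, orient = c("nh", "chain")) {
    orient <- match.arg(orient)
    bp <- build_peptide(resnames, phi = -139, psi = 135,
                        resid_start = resid_start)
    at <- bp$atoms; at$mass <- NULL
    co <- frame_coords(bp, 1L)
    ia <- which(at$resid == anchor_resid & at$name == anchor_name)
    cur <- if (orient == "nh") {
      ih <- which(at$resid == anchor_resid & at$name == "H")
      .unit(co[ih, ] - co[ia, ])
    } else {
      cas <- which(at$name == "CA")
      .unit(co[cas[length(cas)], ] - co[cas[1], ])
    }
    R <- align_rot(cur, .unit(orient_to))
    co <- co %*% t(R)
    co <- sweep(co, 2, co[ia, ] - target, "-")
    keep <- !(at$resid == anchor_resid & at$name %in% c("N", "H"))
    best <- co; best_s <- -Inf
    for (th in seq(0, 2 * pi, by = 5 * pi / 180)) {
      Rr <- rodrigues(orient_to, th)
      cand <- sweep(sweep(co, 2, target) %*% t(Rr), 2, target, "+")
      sub <- cand[keep, , drop = FALSE]
      dmin <- min(vapply(seq_len(nrow(obstacles)), function(k) {
        min(colSums((t(sub) - obstacles[k, ])^2))
      }, numeric(1)))
      if (dmin > best_s) { best_s <- dmin; best <- cand }
    }
    list(atoms = at, xyz = best)
  }

  # switch I: residues 32..42, T37 amide anchored to O1G
  u37 <- .unit(O1G - PG)
  t1 <- O1G + 2.9 * u37
  sw1 <- frag(c("GLY", "ASP", "TYR", "VAL", "PRO", "THR", "VAL", "PHE",
                "ASP", "GLU", "TYR"), 32L, 37L, "N", t1, -u37,
              obstacles = gtp_mg, orient = "nh")
  sw1 <- .extend_sidechain(sw1$atoms, sw1$xyz, 34L,
                           list(c("CG", "C"), c("OH", "O")), gtp_mg)
  sw1 <- .extend_sidechain(sw1$atoms, sw1$xyz, 38L,
                           list(c("CG1", "C"), c("CG2", "C")), gtp_mg)
  sw1 <- .extend_sidechain(sw1$atoms, sw1$xyz, 39L, list(c("CG", "C")),
                           gtp_mg)
  # T37 side chain: OG1 pinned at the Mg site, CG2 near it
  iCB37 <- which(sw1$atoms$resid == 37L & sw1$atoms$name == "CB")
  sw1$atoms <- rbind(sw1$atoms,
    data.frame(serial = NA_integer_, name = "OG1", resname = "THR",
               resid = 37L, element = "O", stringsAsFactors = FALSE),
    data.frame(serial = NA_integer_, name = "CG2", resname = "THR",
               resid = 37L, element = "C", stringsAsFactors = FALSE))
  sw1$xyz <- rbind(sw1$xyz, OG1_37, OG1_37 + c(-1.0, -1.0, 0.5))
  # override T37 amide H to point at O1G
  iN37 <- which(sw1$atoms$resid == 37L & sw1$atoms$name == "N")
  iH37 <- which(sw1$atoms$resid == 37L & sw1$atoms$name == "H")
  sw1$xyz[iH37, ] <- sw1$xyz[iN37, ] + 1.01 * .unit(O1G - sw1$xyz[iN37, ])
  # V35 backbone O pinned at the Mg +z site
  iO35 <- which(sw1$atoms$resid == 35L & sw1$atoms$name == "O")
  sw1$xyz[iO35, ] <- O_35

  # switch II: residues 60..70, G62 amide anchored to O3G
  u62 <- .unit(O3G - PG)
  t2 <- O3G + 2.9 * u62
  res63name <- if (spec$res63 == "LEU") "LEU" else "GLN"
  sw2 <- frag(c("THR", "ALA", "GLY", res63name, "GLU", "ASP", "TYR", "ASP",
                "ARG", "LEU", "ARG"), 60L, 62L, "N", t2, -u62,
              obstacles = rbind(gtp_mg, sw1$xyz), orient = "nh")
  if (res63name == "GLN") {
    sw2 <- .extend_sidechain(sw2$atoms, sw2$xyz, 63L,
                             list(c("CG", "C"), c("CD", "C"),
                                  c("OE1", "O"), c("NE2", "N")),
                             rbind(gtp_mg, sw1$xyz))
  } else {
    sw2 <- .extend_sidechain(sw2$atoms, sw2$xyz, 63L,
                             list(c("CG", "C"), c("CD1", "C"),
                                  c("CD2", "C")), rbind(gtp_mg, sw1$xyz))
  }
  sw2 <- .extend_sidechain(sw2$atoms, sw2$xyz, 66L,
                           list(c("CG", "C"), c("OH", "O")),
                           rbind(gtp_mg, sw1$xyz))
  sw2 <- .extend_sidechain(sw2$atoms, sw2$xyz, 69L,
                           list(c("CG", "C"), c("CD1", "C"), c("CD2", "C")),
                           rbind(gtp_mg, sw1$xyz))
  iN62 <- which(sw2$atoms$resid == 62L & sw2$atoms$name == "N")
  iH62 <- which(sw2$atoms$resid == 62L & sw2$atoms$name == "H")
  sw2$xyz[iH62, ] <- sw2$xyz[iN62, ] + 1.01 * .unit(O3G - sw2$xyz[iN62, ])

  # P-loop: residues 12..20, anchored by T19 CA near its OG1 Mg site
  g14 <- "GLY"
  pl <- frag(c("VAL", "GLY", g14, "ALA", "CYS", "GLY", "LYS", "THR", "CYS"),
             12L, 19L, "CA", OG1_19 + c(-2.2, 0.8, 0.6), c(0, 1, 1),
             obstacles = rbind(gtp_mg, sw1$xyz, sw2$xyz), orient = "chain")
  iCB19 <- which(pl$atoms$resid == 19L & pl$atoms$name == "CB")
  pl$atoms <- rbind(pl$atoms,
    data.frame(serial = NA_integer_, name = "OG1", resname = "THR",
               resid = 19L, element = "O", stringsAsFactors = FALSE),
    data.frame(serial = NA_integer_, name = "CG2", resname = "THR",
               resid = 19L, element = "C", stringsAsFactors = FALSE))
  pl$xyz <- rbind(pl$xyz, OG1_19, OG1_19 + c(-0.8, 1.2, 0.4))

  for (fragment in list(pl, sw1, sw2)) {
    for (k in seq_len(nrow(fragment$atoms))) {
      put(fragment$atoms$name[k], fragment$atoms$element[k],
          fragment$atoms$resid[k], fragment$atoms$resname[k],
          fragment$xyz[k, ])
    }
  }

  # --- water bath ---------------------------------------------------------
  existing <- do.call(rbind, xyz)
  dirs <- golden_spiral_points(spec$n_waters)
  wres <- 300L
  for (k in seq_len(spec$n_waters)) {
    r <- if (k %% 2 == 0) 7.5 else 10.5
    p <- PG + r * dirs[k, ]
    tries <- 0
    while (min(sqrt(colSums((t(existing) - p)^2))) < 3.2 && tries < 20) {
      r <- r + 0.8
      p <- PG + r * dirs[k, ]
      tries <- tries + 1
    }
    put("O", "O", wres, "WAT", p)
    existing <- rbind(existing, p)
    wres <- wres + 1L
  }

  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  trajectory(atoms, do.call(rbind, xyz), dt = spec$dt)
}

# ---- trajectory simulation ----------------------------------------------

# inverse-CDF truncated normal draws from uniform deviates
.trunc_norm <- function(u, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Simulate a synthetic trajectory with planted ground truth
#'
#' Draws a Markov state sequence from `spec$transition_matrix`, then builds
#' every frame from the reference template: all atoms receive isotropic
#' Gaussian jitter with the per-region `fluct_sigma`; the T37 and G62 amides
#' are then re-placed so that their donor-acceptor distance to the planted
#' gamma-phosphate acceptor follows the bonded or unbonded geometry
#' distribution prescribed by the state (the whole residue shifts rigidly
#' with its amide, and the amide hydrogen is laid at a planted
#' acceptor-H-donor angle); finally the planted number of water oxygens is
#' placed strictly inside the 3.0 A gamma-phosphate shell and the remainder
#' of the bath well outside it.  The single RNG stream is consumed in the
#' fixed order states, bond geometries, positional noise, waters, so equal
#' seeds give bitwise-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `trajectory` (an `md_trajectory`) and `truth` (list:
#'   `state_sequence`, `stationary`, `hbond_truth` data.frame with `t37`,
#'   `g62`, `water_counts`, `d1`, `d2`, `fluct_sigma`).
#' @export
simulate_trajectory <- function(spec = synthetic_spec()) {
  ref <- build_reference(spec)
  at <- ref$atoms
  base <- frame_coords(ref, 1L)
  n <- spec$n_frames
  set.seed(spec$seed)

  P <- spec$transition_matrix
  stationary <- stationary_distribution(P)
  # 1) states
  states <- integer(n)
  states[1] <- sample.int(4L, 1L, prob = stationary)
  for (f in seq_len(n)[-1]) {
    states[f] <- sample.int(4L, 1L, prob = P[states[f - 1], ])
  }
  t37_b <- states %in% c(1L, 4L)   # ACTIVE or INACTIVE_3
  g62_b <- states %in% c(1L, 3L)   # ACTIVE or INACTIVE_2

  # 2) bond geometry draws (one set per frame and bond, used as needed)
  bg <- spec$bonded_geometry; ug <- spec$unbonded_geometry
  draw_geom <- function(bonded) {
    u <- stats::runif(n)
    d <- ifelse(bonded,
                .trunc_norm(u, bg$mean, bg$sd, upper = bg$max),
                .trunc_norm(u, ug$mean, ug$sd, lower = ug$min))
    theta <- stats::runif(n, bg$angle_range[1], bg$angle_range[2])
    psi <- stats::runif(n, 0, 2 * pi)
    list(d = d, theta = theta, psi = psi)
  }
  g37 <- draw_geom(t37_b)
  g62 <- draw_geom(g62_b)

  # 3) positional noise
  region <- .region_of(at)
  sig <- ifelse(region == "water", 0, spec$fluct_sigma[region])
  sig[is.na(sig)] <- 0
  idx37 <- which(at$resid == 37L & !(at$resname %in% c("GTP", "MG", "WAT")))
  idx62 <- which(at$resid == 62L & !(at$resname %in% c("GTP", "MG", "WAT")))
  iN37 <- which(at$resid == 37L & at$name == "N")
  iH37 <- which(at$resid == 37L & at$name == "H")
  iN62 <- which(at$resid == 62L & at$name == "N")
  iH62 <- which(at$resid == 62L & at$name == "H")
  gtp_name <- function(nm) which(at$resname == "GTP" & at$name == nm)
  iO1G <- gtp_name("O1G"); iO3G <- gtp_name("O3G"); iPG <- gtp_name("PG")
  gammaO <- c(gtp_name("O1G"), gtp_name("O2G"), gtp_name("O3G"))
  site <- c(iPG, gammaO)
  wat_o <- which(at$resname == "WAT")
  noise <- array(stats::rnorm(length(base) * n, sd = sig),
                 dim = c(nrow(base), 3L, n))

  # 4) water draws
  lam <- spec$water_lambda[states]
  kc <- stats::rpois(n, lam)
  kc <- pmin(kc, length(wat_o))
  wdir <- array(stats::rnorm(3L * length(wat_o) * n),
                dim = c(length(wat_o), 3L, n))
  wrad_in <- matrix(stats::runif(length(wat_o) * n, 2.2, 2.8),
                    length(wat_o), n)
  wrad_out <- matrix(stats::runif(length(wat_o) * n, 6.0, 12.0),
                     length(wat_o), n)

  # template donor directions (fixed unit vectors, acceptor -> donor N)
  u37dir <- .unit(base[iN37, ] - base[iO1G, ])
  u62dir <- .unit(base[iN62, ] - base[iO3G, ])

  place_amide <- function(fc, iN, iH, iRes, iAcc, udir, d, theta, psi) {
    acc <- fc[iAcc, ]
    targetN <- acc + d * udir
    # keep the unbonded donor clear of all three gamma oxygens
    if (d >= 3.5) {
      for (it in 1:5) {
        dmin <- min(sqrt(colSums((t(fc[gammaO, , drop = FALSE]) - targetN)^2)))
        if (dmin >= 3.7) break
        d <- d + (3.7 - dmin) + 0.05
        targetN <- acc + d * udir
      }
    }
    shift <- targetN - fc[iN, ]
    fc[iRes, ] <- sweep(fc[iRes, , drop = FALSE], 2, shift, "+")
    # hydrogen at planted acceptor-H-donor angle theta (deg)
    dAD <- sqrt(sum((fc[iN, ] - acc)^2))
    uNA <- .unit(acc - fc[iN, ])
    th <- theta * pi / 180
    phi_at_n <- pi - th - asin(min(1, (1.01 / dAD) * sin(th)))
    perp <- .unit(.cross(uNA, c(0.1, 0.9, 0.42)))
    if (!all(is.finite(perp))) perp <- .unit(.cross(uNA, c(1, 0, 0)))
    perp <- cos(psi) * perp + sin(psi) * .cross(uNA, perp)
    hdir <- cos(phi_at_n) * uNA + sin(phi_at_n) * perp
    fc[iH, ] <- fc[iN, ] + 1.01 * hdir
    fc
  }

  coords <- array(NA_real_, dim = c(nrow(base), 3L, n))
  for (f in seq_len(n)) {
    fc <- base + noise[, , f]
    fc <- place_amide(fc, iN37, iH37, idx37, iO1G, u37dir,
                      g37$d[f], g37$theta[f], g37$psi[f])
    fc <- place_amide(fc, iN62, iH62, idx62, iO3G, u62dir,
                      g62$d[f], g62$theta[f], g62$psi[f])
    # waters: planted count strictly inside the shell, rest outside
    pg <- fc[iPG, ]
    k <- kc[f]
    for (w in seq_along(wat_o)) {
      dir <- .unit(wdir[w, , f])
      r <- if (w <= k) wrad_in[w, f] else wrad_out[w, f]
      fc[wat_o[w], ] <- pg + r * dir
    }
    coords[, , f] <- fc
  }

  traj <- trajectory(at, coords, dt = spec$dt)
  dser <- function(i, j) {
    d <- coords[i, , , drop = FALSE] - coords[j, , , drop = FALSE]
    sqrt(colSums(matrix(d, nrow = 3L)^2))
  }
  iCA37 <- which(at$resid == 37L & at$name == "CA")
  iCA62 <- which(at$resid == 62L & at$name == "CA")
  iPB <- gtp_name("PB")
  truth <- list(
    state_sequence = factor(state_levels[states], levels = state_levels),
    stationary = stats::setNames(stationary, state_levels),
    hbond_truth = data.frame(frame = seq_len(n), t37 = t37_b, g62 = g62_b),
    water_counts = kc,
    d1 = dser(iCA37, iPB), d2 = dser(iCA62, iPB),
    fluct_sigma = spec$fluct_sigma
  )
  list(trajectory = traj, truth = truth)
}

#' Write a ground-truth table alongside a simulated trajectory
#'
#' Delimited table with one row per frame: `frame`, `state`, `d1`, `d2`,
#' `water_count`.
#'
#' @param truth the `truth` element of [simulate_trajectory()].
#' @param path output file path (tab-delimited).
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  df <- data.frame(frame = seq_along(truth$state_sequence),
                   state = as.character(truth$state_sequence),
                   d1 = truth$d1, d2 = truth$d2,
                   water_count = truth$water_counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
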