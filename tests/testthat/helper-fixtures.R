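# Fixtures built in code: tiny topologies, cached synthetic trajectories and
# brute-force oracles shared across test files.

# minimal topology helper: one atom per row of `coords`
toy_traj <- function(coords, element = "C", name = NULL, resname = "LIG",
                     resid = NULL, dt = 2) {
  n <- nrow(coords)
  atoms <- data.frame(
    serial = seq_len(n),
    name = if (is.null(name)) paste0(element, seq_len(n)) else name,
    resname = rep_len(resname, n),
    resid = if (is.null(resid)) rep(1L, n) else resid,
    element = rep_len(element, n), stringsAsFactors = FALSE
  )
  trajectory(atoms, coords, dt = dt)
}

# deterministic cached simulations (built once per test run)
.sim_cache <- new.env()
cached_sim <- function(key, spec) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_trajectory(spec)
  }
  .sim_cache[[key]]
}

default_sim <- function(n_frames = 2000L, seed = 7L) {
  cached_sim(paste0("default", n_frames, "_", seed),
             synthetic_spec(n_frames = n_frames, seed = seed))
}

# brute-force hydrogen-bond oracle: O(donors x acceptors) triple loop over
# explicit per-atom distances and angles
brute_hbond <- function(traj, frame, criterion = hbond_criterion()) {
  cand <- hbond_candidates(traj)
  fc <- frame_coords(traj, frame)
  hits <- list()
  for (k in seq_len(nrow(cand$donors))) {
    D <- cand$donors$heavy[k]; H <- cand$donors$h[k]
    for (A in cand$acceptors) {
      if (A == D) next
      d <- sqrt(sum((fc[A, ] - fc[D, ])^2))
      v1 <- fc[A, ] - fc[H, ]; v2 <- fc[D, ] - fc[H, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (d < criterion$d_max && ang > criterion$angle_min) {
        hits[[length(hits) + 1L]] <- c(D, H, A)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), ncol = 3))
  do.call(rbind, hits)
}

# exhaustive average-linkage oracle for small distance matrices
brute_average_linkage <- function(m, k) {
  n <- nrow(m)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        d <- mean(m[clusters[[i]], clusters[[j]]])
        if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (c_i in seq_along(clusters)) labels[clusters[[c_i]]] <- c_i
  labels
}

# normalize a partition to a canonical label vector for comparison
canon_partition <- function(labels) {
  match(labels, unique(labels))
}

# antiparallel two-strand fixture: strand 2 is strand 1 rotated 180 degrees
# about z and translated so its residue-23 carbonyl O sits 1.9 A along the
# N-H direction of strand-1 residue 3 (an ideal mutual bridge geometry)
sheet_fixture <- function() {
  s1 <- build_peptide(rep("ALA", 8), phi = -139, psi = 135)
  co <- frame_coords(s1, 1)
  at <- s1$atoms
  idx <- function(r, nm) which(at$resid == r & at$name == nm)
  nh <- co[idx(3, "H"), ] - co[idx(3, "N"), ]
  nh <- nh / sqrt(sum(nh^2))
  target_o <- co[idx(3, "H"), ] + 1.9 * nh
  co2 <- co %*% diag(c(-1, -1, 1))
  co2 <- sweep(co2, 2, target_o - co2[idx(3, "O"), ], "+")
  at2 <- at; at2$resid <- at2$resid + 20L
  allat <- rbind(at, at2); allat$serial <- seq_len(nrow(allat))
  trajectory(allat, rbind(co, co2))
}
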