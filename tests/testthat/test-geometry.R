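test_that("distances match the naive formula on random pairs", {
  expect_equal(atom_distance(rbind(c(0, 0, 0), c(3, 4, 0)), 1, 2), 5)
  expect_equal(atom_distance(rbind(c(1, 2, 3)), 1, 1), 0)
  set.seed(1)
  fc <- matrix(rnorm(300), 100, 3)
  for (k in 1:100) {
    ij <- sample(100, 2)
    expect_equal(atom_distance(fc, ij[1], ij[2]),
                 sqrt(sum((fc[ij[1], ] - fc[ij[2], ])^2)), tolerance = 1e-12)
  }
})

test_that("angles have the vertex at the middle atom and span [0, 180]", {
  fc <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(atom_angle(fc, 1, 2, 3), 180)
  expect_equal(atom_angle(fc, 1, 2, 4), 90)
  set.seed(2)
  for (k in 1:50) {
    fc <- matrix(rnorm(9), 3, 3)
    v1 <- fc[1, ] - fc[2, ]; v2 <- fc[3, ] - fc[2, ]
    expected <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(atom_angle(fc, 1, 2, 3), expected, tolerance = 1e-10)
  }
  fc <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(atom_angle(fc, 1, 2, 3), "degenerate")
})

test_that("side-chain centroid distances use heavy atoms beyond the backbone", {
  at <- data.frame(
    serial = 1:6,
    name = c("N", "CA", "CB", "N", "CA", "CB"),
    resname = "ALA", resid = c(1L, 1L, 1L, 2L, 2L, 2L), element =
      c("N", "C", "C", "N", "C", "C"))
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
              c(0, 5, 0), c(1, 5, 0), c(2, 5.5, 0))
  tr <- trajectory(at, co)
  expect_equal(sidechain_centroid_distance(tr, 1, 1, 2),
               sqrt(0 + 5.5^2), tolerance = 1e-12)
  expect_equal(sidechain_centroid_distance(tr, 1, 1, 1), 0)
  # multi-atom centroid against a hand computation
  ref <- build_reference(synthetic_spec(res63 = "LEU"))
  fc <- frame_coords(ref, 1)
  at <- ref$atoms
  cen <- function(r) {
    idx <- which(at$resid == r & !(at$name %in% c("N", "CA", "C", "O", "H",
                                                  "HA", "OXT")) &
                   at$element != "H")
    colMeans(fc[idx, , drop = FALSE])
  }
  expect_equal(sidechain_centroid_distance(ref, 1, 63, 38),
               sqrt(sum((cen(63) - cen(38))^2)), tolerance = 1e-12)
  # glycine has no side-chain heavy atoms
  expect_error(sidechain_centroid_distance(ref, 1, 62, 38), "side-chain")
})

test_that("superposition is optimal, proper and exact for rigid copies", {
  set.seed(3)
  ref <- matrix(rnorm(30), 10, 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mob <- ref %*% t(R) + matrix(c(5, -2, 1), 10, 3, byrow = TRUE)
  sp <- superpose(mob, ref, 1:10)
  expect_lt(sp$rmsd, 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  # reflected copy: rotation stays proper, rmsd > 0
  refl <- ref %*% diag(c(-1, 1, 1))
  sp2 <- superpose(refl, ref, 1:10)
  expect_gt(sp2$rmsd, 0.1)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-9)

  # optimality vs 1000 random rigid transforms
  mob2 <- matrix(rnorm(30), 10, 3)
  sp3 <- superpose(mob2, ref, 1:10)
  set.seed(4)
  for (k in 1:1000) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    Rq <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
      2 * (q[2] * q[4] + q[3] * q[1]),
      2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[2] * q[1]),
      2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    cand <- mob2 %*% t(Rq)
    cand <- sweep(cand, 2, colMeans(cand) - colMeans(ref))
    rmsd_cand <- sqrt(mean(rowSums((cand - ref)^2)))
    expect_gte(rmsd_cand, sp3$rmsd - 1e-9)
  }
  expect_error(superpose(mob[1:2, ], ref[1:2, ], 1:2), "3 atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line, 1:5), "collinear")
})

test_that("superposition agrees with the bio3d fitting routine", {
  set.seed(5)
  ref <- matrix(rnorm(24), 8, 3)
  mob <- matrix(rnorm(24), 8, 3)
  sp <- superpose(mob, ref, 1:8)
  fit <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mob)),
                        fixed.inds = 1:24, mobile.inds = 1:24)
  expect_equal(sp$coords, matrix(fit, ncol = 3, byrow = TRUE),
               tolerance = 1e-6)
})

test_that("rmsd series reduces to unweighted for equal masses and matches the mass-weighted formula", {
  sim <- cached_sim("geo50", synthetic_spec(n_frames = 5L, seed = 21L))
  tr <- sim$trajectory
  # static trajectory: all zeros
  stat <- tr
  for (f in seq_len(n_frames(stat))) stat$coords[, , f] <- stat$coords[, , 1]
  expect_equal(max(rmsd_series(stat)), 0, tolerance = 1e-10)

  sel <- backbone_selection(tr)
  idx <- sel$indices
  equal_mass <- tr
  equal_mass$atoms$mass <- 1
  expect_equal(rmsd_series(equal_mass, sel = sel, mass_weighted = TRUE),
               rmsd_series(tr, sel = sel, mass_weighted = FALSE),
               tolerance = 1e-12)

  # explicit sum(m d^2)/sum(m) oracle on frame 3
  rs <- rmsd_series(tr, sel = sel, mass_weighted = TRUE)
  ref <- frame_coords(tr, 1)
  sp <- superpose(frame_coords(tr, 3), ref, idx)
  m <- tr$atoms$mass[idx]
  dev2 <- rowSums((sp$coords[idx, ] - ref[idx, ])^2)
  expect_equal(rs[3], sqrt(sum(m * dev2) / sum(m)), tolerance = 1e-10)
})

test_that("rmsf recovers the closed form sigma*sqrt(3) for isotropic noise", {
  sp <- synthetic_spec(
    n_frames = 10000L, fluct_sigma = 0.5, seed = 3L,
    transition_matrix = matrix(rep(c(1, 0, 0, 0), 4), 4, 4, byrow = TRUE))
  tr <- cached_sim("rmsf10k", sp)$trajectory
  sel <- backbone_selection(tr)
  # exclude the two residues whose amides are re-placed by the bond planting
  keep <- sel$indices[!(tr$atoms$resid[sel$indices] %in% c(37L, 62L))]
  rf <- rmsf(tr, sel = keep, align_sel = keep)
  expect_equal(mean(rf), 0.5 * sqrt(3), tolerance = 0.02)
  expect_error(rmsf(subset_frames(tr, 1L)), "2 frames")
})

test_that("rmsf is zero for a static trajectory and invariant under rigid motion", {
  sim <- cached_sim("geo50", synthetic_spec(n_frames = 5L, seed = 21L))
  tr <- sim$trajectory
  stat <- tr
  for (f in seq_len(n_frames(stat))) stat$coords[, , f] <- stat$coords[, , 1]
  expect_equal(max(rmsf(stat)), 0, tolerance = 1e-10)

  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rot <- tr
  for (f in seq_len(n_frames(rot))) {
    rot$coords[, , f] <- frame_coords(tr, f) %*% t(R) +
      matrix(c(3, 4, 5), n_atoms(tr), 3, byrow = TRUE)
  }
  expect_equal(rmsf(rot), rmsf(tr), tolerance = 1e-8)
})

test_that("replicate rmsf profiles report across-run mean and sd", {
  s1 <- cached_sim("geoA", synthetic_spec(n_frames = 150L, seed = 31L,
                                          fluct_sigma = 0.3))$trajectory
  s2 <- cached_sim("geoB", synthetic_spec(n_frames = 150L, seed = 32L,
                                          fluct_sigma = 0.6))$trajectory
  prof <- rmsf_profile(list(s1, s2))
  expect_equal(prof$mean, (prof$rep1 + prof$rep2) / 2, tolerance = 1e-12)
  expect_equal(prof$sd, abs(prof$rep1 - prof$rep2) / sqrt(2),
               tolerance = 1e-10)
  expect_true(all(prof$mean >= 0))
})

test_that("coordination shell finds the hexahedral Mg sphere and matches brute force", {
  ref <- build_reference(synthetic_spec())
  fc <- frame_coords(ref, 1)
  at <- ref$atoms
  iMG <- which(at$name == "MG")
  cands <- setdiff(seq_len(nrow(fc)), iMG)
  shell <- coordination_shell(fc, iMG, cands, 2.4)
  expect_equal(nrow(shell), 6L)
  expect_true(all(at$element[shell$atom] == "O"))
  expect_setequal(
    paste(at$resid[shell$atom], at$name[shell$atom]),
    c("201 O2A", "201 O1B", "201 O2G", "19 OG1", "37 OG1", "35 O"))
  expect_equal(nrow(coordination_shell(fc, iMG, cands, 0.1)), 0L)
  # brute-force scan oracle
  d <- sqrt(colSums((t(fc[cands, ]) - fc[iMG, ])^2))
  expect_equal(sort(shell$atom), sort(cands[d < 2.4]))
  expect_false(is.unsorted(shell$distance))
  expect_error(coordination_shell(fc, iMG, cands, -1))
})
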