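test_that("Shrake-Rupley reproduces the analytic isolated-sphere area", {
  tr <- toy_traj(matrix(0, 1, 3))
  sr <- shrake_rupley(tr, n_points = 960)
  expect_equal(sr$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.005)
  expect_error(shrake_rupley(tr, n_points = 16), "n_points")
})

test_that("Shrake-Rupley matches the two-sphere spherical-cap closed form", {
  d <- 2.0
  tr <- toy_traj(rbind(c(0, 0, 0), c(d, 0, 0)))
  sr <- shrake_rupley(tr, n_points = 3840)
  r <- 1.7 + 1.4
  # equal radii: each sphere loses the cap of height (r - d/2)
  analytic <- 4 * pi * r^2 - 2 * pi * r * (r - d / 2)
  expect_equal(unname(sr$atom_area[1]), analytic, tolerance = 0.01 * analytic)
  expect_equal(unname(sr$atom_area[2]), analytic, tolerance = 0.01 * analytic)
})

test_that("Shrake-Rupley quadrature converges and never exceeds the bare sphere", {
  ref <- build_reference(synthetic_spec())
  sel <- select_atoms(ref, "resname GTP")
  a <- shrake_rupley(ref, 1, sel, n_points = 480)
  b <- shrake_rupley(ref, 1, sel, n_points = 960)
  expect_lt(abs(b$total - a$total) / b$total, 0.01)
  r <- bondi_radii()[ref$atoms$element[sel$indices]]
  expect_true(all(a$atom_area <= 4 * pi * (r + 1.4)^2 + 1e-9))
  expect_true(all(a$atom_area >= 0))
})

test_that("SASA is invariant under rigid motions of the frame", {
  ref <- build_reference(synthetic_spec())
  sel <- select_atoms(ref, "resname GTP")
  pts <- golden_spiral_points(480)
  a <- shrake_rupley(ref, 1, sel, points = pts)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- ref
  rot$coords[, , 1] <- frame_coords(ref, 1) %*% t(R) +
    matrix(c(10, -3, 2), n_atoms(ref), 3, byrow = TRUE)
  # exact invariance when the quadrature points co-rotate with the frame
  b <- shrake_rupley(rot, 1, sel, points = pts %*% t(R))
  expect_equal(a$atom_area, b$atom_area, tolerance = 1e-9)
  # with the fixed laboratory-frame point set only discretization error moves
  b2 <- shrake_rupley(rot, 1, sel, points = pts)
  expect_equal(b2$total, a$total, tolerance = 0.02)
  l1 <- lcpo(ref, 1, sel)
  l2 <- lcpo(rot, 1, sel)
  expect_equal(l1$atom_area, l2$atom_area, tolerance = 1e-9)
})

test_that("LCPO hits the isolated-sphere limit and clamps buried atoms", {
  tr <- toy_traj(matrix(0, 1, 3))
  expect_equal(lcpo(tr)$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
  # an atom caged by 12 close neighbours is fully buried
  pts <- golden_spiral_points(12) * 1.8
  cage <- toy_traj(rbind(c(0, 0, 0), pts))
  lc <- lcpo(cage)
  expect_equal(unname(lc$atom_area[1]), 0)
  # missing parameters are reported with the atom identity
  bad <- toy_traj(matrix(0, 1, 3), element = "FE")
  expect_error(lcpo(bad), "FE")
})

test_that("LCPO stays within 10% of the Shrake-Rupley oracle on the GTP-like molecule", {
  ref <- build_reference(synthetic_spec())
  sel <- select_atoms(ref, "resname GTP")
  gtp <- trajectory(ref$atoms[sel$indices, ],
                    frame_coords(ref, 1)[sel$indices, ])
  sr <- shrake_rupley(gtp, n_points = 960, radii = lcpo_radii())
  lc <- lcpo(gtp)
  expect_lt(abs(lc$total - sr$total) / sr$total, 0.10)
})

test_that("windowed SASA series pools replicates frame-count weighted", {
  s1 <- cached_sim("sasaA", synthetic_spec(n_frames = 20L, seed = 41L))
  s2 <- cached_sim("sasaB", synthetic_spec(n_frames = 40L, seed = 42L))
  res <- selection_sasa_series(list(s1$trajectory, s2$trajectory),
                               window = 0.5)
  expect_length(res$per_frame[[1]], 10L)
  expect_length(res$per_frame[[2]], 20L)
  expect_equal(res$mean,
               sum(c(10, 20) * res$replicate_means) / 30, tolerance = 1e-12)
  expect_equal(res$sd, sd(res$replicate_means))
  # static repetition has zero spread
  tr <- s1$trajectory
  for (f in seq_len(n_frames(tr))) tr$coords[, , f] <- tr$coords[, , 1]
  res2 <- selection_sasa_series(list(tr), window = 1)
  expect_equal(sd(res2$per_frame[[1]]), 0, tolerance = 1e-10)
})

test_that("percent decrease reproduces reported mutant-vs-wild-type arithmetic", {
  expect_equal(percent_decrease(100, 75), 25)
  expect_equal(percent_decrease(100, 100), 0)
  vals <- read.delim(system.file("extdata", "rhoa_reference_values.tsv",
                                 package = "rhotraj"))
  sasa <- vals[vals$quantity == "mean_gtp_sasa", ]
  wt <- sasa$value[sasa$system == "wt"]
  expect_equal(round(percent_decrease(wt, sasa$value[sasa$system == "g14v"])),
               32)
  expect_equal(round(percent_decrease(wt, sasa$value[sasa$system == "q63l"])),
               24)
})

test_that("water counting is strict, per-molecule and matches brute force", {
  at <- data.frame(
    serial = 1:5,
    name = c("PG", "O1G", "O", "O", "O"),
    resname = c("GTP", "GTP", "WAT", "WAT", "WAT"),
    resid = c(201L, 201L, 301L, 302L, 303L),
    element = c("P", "O", "O", "O", "O"))
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0),
              c(1.5 + 2.5, 0, 0),   # 2.5 from O1G -> counted
              c(0, 3.2, 0),         # 3.2 from both -> out
              c(0, 0, 2.99))        # 2.99 from PG -> counted
  tr <- trajectory(at, co)
  site <- select_atoms(tr, "name PG OR name O1G")
  expect_equal(count_waters(tr, 1, site), 2L)
  # boundary: exactly at the cutoff is excluded
  co[5, ] <- c(0, 0, 3.0)
  tr2 <- trajectory(at, co)
  expect_equal(count_waters(tr2, 1, site), 1L)
  # no waters
  tr3 <- trajectory(at[1:2, ], co[1:2, , drop = FALSE])
  expect_warning(n <- count_waters(tr3, 1, select_atoms(tr3, "name PG")),
                 "no water")
  expect_equal(n, 0L)
  # random configurations vs brute-force double loop
  set.seed(12)
  for (k in 1:20) {
    nw <- 15L
    wat <- matrix(rnorm(nw * 3, sd = 3), nw, 3)
    at4 <- data.frame(serial = seq_len(nw + 2),
                      name = c("PG", "O1G", rep("O", nw)),
                      resname = c("GTP", "GTP", rep("WAT", nw)),
                      resid = c(201L, 201L, 300L + seq_len(nw)),
                      element = c("P", "O", rep("O", nw)))
    co4 <- rbind(c(0, 0, 0), c(1.5, 0, 0), wat)
    tr4 <- trajectory(at4, co4)
    brute <- sum(vapply(seq_len(nw), function(w) {
      any(sqrt(colSums((t(co4[1:2, ]) - wat[w, ])^2)) < 3.0)
    }, logical(1)))
    expect_equal(count_waters(tr4, 1, select_atoms(tr4, "name PG OR name O1G")),
                 brute)
  }
})

test_that("water summaries recover the planted per-state Poisson means", {
  sim <- default_sim(2000L)
  w <- water_count_summary(list(sim$trajectory), window = 1)
  expect_equal(sum(w$histogram), 1, tolerance = 1e-12)
  expect_equal(w$mean, mean(sim$truth$water_counts), tolerance = 1e-12)
  # planted mean: mixture of per-state lambdas under the stationary law
  lam <- synthetic_spec()$water_lambda
  st <- sim$truth$state_sequence
  expect_equal(w$mean, mean(lam[as.character(st)]), tolerance = 0.15)
})
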