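test_that("donor/acceptor enumeration follows element and bonded-H rules", {
  at <- data.frame(
    serial = 1:5,
    name = c("N", "H", "O", "C", "O1G"),
    resname = c("ALA", "ALA", "ALA", "ALA", "GTP"),
    resid = c(1L, 1L, 1L, 1L, 2L),
    element = c("N", "H", "O", "C", "O"))
  co <- rbind(c(0, 0, 0), c(1.01, 0, 0), c(3, 0, 0), c(5, 0, 0),
              c(2.9, 0.5, 0))
  tr <- trajectory(at, co)
  cand <- hbond_candidates(tr)
  expect_equal(cand$donors$heavy, 1L)      # N with H at 1.01
  expect_equal(cand$donors$h, 2L)
  expect_setequal(cand$acceptors, c(1L, 3L, 5L))  # N/O only, no carbon
  # no hydrogens at all
  tr2 <- trajectory(at[-2, ], co[-2, , drop = FALSE])
  expect_error(hbond_candidates(tr2), "add_amide_hydrogens")
})

test_that("detection applies strict distance and angle thresholds", {
  mk <- function(d, ang) {
    # donor N at origin, H on x-axis, acceptor placed at distance d from N
    # with the A-H-D angle = ang at the hydrogen
    at <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                     resname = c("A", "A", "B"), resid = c(1L, 1L, 2L),
                     element = c("N", "H", "O"))
    r <- 1.01
    th <- ang * pi / 180
    phi <- pi - th - asin(r / d * sin(th))
    acc <- c(d * cos(phi), d * sin(phi), 0)
    trajectory(at, rbind(c(0, 0, 0), c(r, 0, 0), acc))
  }
  crit <- hbond_criterion()
  planted <- mk(2.9, 160)
  det <- hbond_detect(planted, 1, crit)
  expect_equal(nrow(det), 1L)
  expect_equal(det$distance, 2.9, tolerance = 1e-9)
  expect_equal(det$angle, 160, tolerance = 1e-6)
  expect_equal(nrow(hbond_detect(mk(3.6, 170), 1, crit)), 0L)  # too far
  expect_equal(nrow(hbond_detect(mk(3.0, 110), 1, crit)), 0L)  # too bent
  # boundary values are excluded (strict inequalities): set the criterion
  # thresholds to the exact measured geometry of a formed bond
  fc <- frame_coords(planted, 1)
  d_obs <- atom_distance(fc, 3, 1)
  a_obs <- atom_angle(fc, 3, 2, 1)
  expect_equal(nrow(hbond_detect(planted, 1,
                                 hbond_criterion(d_max = d_obs))), 0L)
  expect_equal(nrow(hbond_detect(planted, 1,
                                 hbond_criterion(angle_min = a_obs))), 0L)
})

test_that("detection matches the brute-force oracle on synthetic frames", {
  sim <- default_sim(200L)
  tr <- sim$trajectory
  cand <- hbond_candidates(tr)
  for (f in c(1L, 7L, 33L, 120L, 200L)) {
    det <- hbond_detect(tr, f, candidates = cand)
    oracle <- brute_hbond(tr, f)
    expect_equal(nrow(det), nrow(oracle))
    if (nrow(det)) {
      expect_setequal(paste(det$donor, det$h, det$acceptor),
                      paste(oracle[, 1], oracle[, 2], oracle[, 3]))
    }
  }
})

test_that("per-frame bond series agrees with planted truth on every frame", {
  sim <- default_sim(2000L)
  tr <- sim$trajectory
  at <- tr$atoms
  gammaO <- which(at$resname == "GTP" & at$name %in% c("O1G", "O2G", "O3G"))
  t37 <- hbond_series(tr, which(at$resid == 37 & at$name == "N"), gammaO)
  g62 <- hbond_series(tr, which(at$resid == 62 & at$name == "N"), gammaO)
  expect_identical(t37, sim$truth$hbond_truth$t37)
  expect_identical(g62, sim$truth$hbond_truth$g62)
})

test_that("occupancy is the window fraction and the replicate mean is arithmetic", {
  sim <- default_sim(2000L)
  tr <- sim$trajectory
  at <- tr$atoms
  gammaO <- which(at$resname == "GTP" & at$name %in% c("O1G", "O2G", "O3G"))
  iN <- which(at$resid == 37 & at$name == "N")
  occ <- hbond_occupancy(list(tr), iN, gammaO, window = 0.6)
  wt <- analysis_window(tr, 0.6)
  expect_equal(occ$rep1, mean(hbond_series(wt, iN, gammaO)))
  expect_equal(occ$mean, occ$rep1)
  # three replicates with known fractions average arithmetically
  occ3 <- data.frame(pair = "x", rep1 = 0.9, rep2 = 1.0, rep3 = 0.8,
                     mean = mean(c(0.9, 1.0, 0.8)))
  expect_equal(occ3$mean, 0.9)
})

test_that("occupancy is monotone in both criterion thresholds", {
  sim <- default_sim(2000L)
  tr <- analysis_window(sim$trajectory, 0.3)
  at <- tr$atoms
  gammaO <- which(at$resname == "GTP" & at$name %in% c("O1G", "O2G", "O3G"))
  iN <- which(at$resid == 37 & at$name == "N")
  frac <- function(dmax, amin) {
    mean(hbond_series(tr, iN, gammaO, hbond_criterion(dmax, amin)))
  }
  d_grid <- c(2.5, 3.0, 3.5, 4.0, 4.5)
  occ_d <- vapply(d_grid, frac, numeric(1), amin = 120)
  expect_true(all(diff(occ_d) >= 0))
  a_grid <- c(100, 120, 140, 160, 175)
  occ_a <- vapply(a_grid, frac, numeric(1), dmax = 3.5)
  expect_true(all(diff(occ_a) <= 0))
})

test_that("high-occupancy filter keeps a pair formed in ANY system", {
  tab <- data.frame(
    pair = rep(c("a", "b"), each = 3),
    system = rep(c("wt", "g14v", "q63l"), 2),
    mean = c(0.78, 0.10, 0.10, 0.5, 0.5, 0.5))
  hi <- high_occupancy(tab, 0.75)
  expect_setequal(unique(hi$pair), "a")
  expect_equal(nrow(hi), 3L)  # all rows of the passing pair are kept
  expect_equal(nrow(high_occupancy(tab, 0)), 6L)
  all_low <- data.frame(pair = c("a", "b"), mean = c(0.5, 0.5))
  expect_equal(nrow(high_occupancy(all_low, 0.75)), 0L)
})
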