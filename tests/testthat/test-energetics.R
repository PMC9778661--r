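energy_fixture <- function(n = 100L, seed = 71L, resnames = c("G14", "K18",
                                                              "MG")) {
  set.seed(seed)
  tab <- data.frame(
    frame = seq_len(n),
    dE_int = rnorm(n, 0, 0.5),
    dE_ele = rnorm(n, -150, 2),
    dE_vdw = rnorm(n, -40, 1),
    dG_pol = rnorm(n, -40, 2),
    dG_nonpol = rnorm(n, -5, 0.2))
  for (r in resnames) tab[[paste0("res_", r)]] <- rnorm(n, -10, 0.5)
  tab
}

test_that("the nonpolar term is linear in the SASA difference", {
  expect_equal(nonpolar_term(100, gamma = 0.0072, b = 0), 0.72)
  expect_equal(nonpolar_term(0, b = 1.5), 1.5)
  expect_equal(nonpolar_term(200, b = 2) - 2,
               2 * (nonpolar_term(100, b = 2) - 2))
})

test_that("combine obeys the energy-equation chain to 1e-9", {
  tabs <- lapply(1:3, function(r) energy_fixture(seed = 70L + r))
  b <- bfe_combine(tabs, window = 0.6)
  cmp <- b$components
  expect_equal(unname(cmp["dE_MM"]),
               unname(cmp["dE_int"] + cmp["dE_ele"] + cmp["dE_vdw"]),
               tolerance = 1e-9)
  expect_equal(unname(cmp["dG_sol"]), unname(cmp["dG_pol"] + cmp["dG_nonpol"]),
               tolerance = 1e-9)
  expect_equal(b$total, unname(cmp["dE_MM"] + cmp["dG_sol"]) + b$entropy,
               tolerance = 1e-9)
  # entropy 0 means dG = dH exactly
  expect_equal(b$entropy, 0)
  # single-frame arithmetic
  one <- data.frame(frame = 1, dE_int = -10, dE_ele = -20, dE_vdw = -5,
                    dG_pol = 3, dG_nonpol = -1)
  expect_equal(bfe_combine(one, window = 1)$total, -33)
  # the recorded -TdS term shifts the total one-for-one
  expect_equal(bfe_combine(one, window = 1, entropy = 5)$total, -28)
})

test_that("replicate statistics equal brute-force recomputation", {
  tabs <- lapply(1:3, function(r) energy_fixture(seed = 80L + r))
  b <- bfe_combine(tabs, window = 0.6)
  brute <- vapply(tabs, function(tab) {
    w <- tab[41:100, ]
    mean(w$dE_int + w$dE_ele + w$dE_vdw + w$dG_pol + w$dG_nonpol)
  }, numeric(1))
  expect_equal(b$replicate_means, brute, tolerance = 1e-12)
  expect_equal(b$total, mean(brute), tolerance = 1e-12)
  expect_equal(b$sd, sd(brute), tolerance = 1e-12)
  # pooled-frame SD mode
  bp <- bfe_combine(tabs, window = 0.6, pooled_sd = TRUE)
  pooled <- unlist(lapply(tabs, function(tab) {
    w <- tab[41:100, ]
    w$dE_int + w$dE_ele + w$dE_vdw + w$dG_pol + w$dG_nonpol
  }))
  expect_equal(bp$sd, sd(pooled), tolerance = 1e-12)
  # replicate means like the reported triple-run style
  stub <- function(v) data.frame(frame = 1, dE_int = v, dE_ele = 0,
                                 dE_vdw = 0, dG_pol = 0, dG_nonpol = 0)
  b3 <- bfe_combine(lapply(c(-227, -228, -226), stub), window = 1)
  expect_equal(b3$total, -227)
  expect_equal(b3$sd, 1)
})

test_that("missing required columns are reported by name", {
  tab <- energy_fixture()
  tab$dG_pol <- NULL
  expect_error(bfe_combine(tab), "dG_pol")
  tab2 <- energy_fixture()
  tab2$dG_nonpol <- NULL
  expect_error(bfe_combine(tab2), "dG_nonpol")
  # the SASA triple substitutes for dG_nonpol via the linear model
  tab3 <- energy_fixture()
  tab3$dG_nonpol <- NULL
  tab3$sasa_complex <- 9000; tab3$sasa_receptor <- 8000
  tab3$sasa_ligand <- 1400
  b <- bfe_combine(tab3, window = 1, gamma = 0.0072, b = 0)
  expect_equal(unname(b$components["dG_nonpol"]), 0.0072 * (-400),
               tolerance = 1e-12)
})

test_that("per-residue decomposition reports sorted means with MG last", {
  tabs <- lapply(1:3, function(r) energy_fixture(seed = 90L + r))
  pr <- bfe_per_residue(tabs, window = 0.6)
  expect_equal(pr$residue, c("G14", "K18", "MG"))
  brute <- vapply(tabs, function(tab) mean(tab$res_G14[41:100]), numeric(1))
  expect_equal(pr$mean[pr$residue == "G14"], mean(brute), tolerance = 1e-12)
  expect_equal(pr$sd[pr$residue == "G14"], sd(brute), tolerance = 1e-12)
  # constant planted contribution
  const <- energy_fixture()
  const$res_G14 <- -5.43
  prc <- bfe_per_residue(const, window = 1)
  expect_equal(prc$mean[prc$residue == "G14"], -5.43)
  expect_equal(prc$sd[prc$residue == "G14"], 0)
  # ragged columns across replicates
  bad <- tabs
  bad[[2]]$res_K18 <- NULL
  expect_error(bfe_per_residue(bad), "ragged")
  expect_error(bfe_per_residue(energy_fixture(resnames = character())),
               "decomposition")
})

test_that("complete per-residue rows partition the total", {
  n <- 50L
  set.seed(101)
  parts <- matrix(rnorm(n * 4, -10, 1), n, 4)
  tab <- data.frame(frame = seq_len(n),
                    dE_int = parts[, 1], dE_ele = parts[, 2],
                    dE_vdw = parts[, 3], dG_pol = parts[, 4], dG_nonpol = 0,
                    res_A1 = parts[, 1] + parts[, 2],
                    res_B2 = parts[, 3] + parts[, 4])
  b <- bfe_combine(tab, window = 1)
  pr <- bfe_per_residue(tab, window = 1)
  expect_equal(sum(pr$mean), b$total, tolerance = 1e-9)
})

test_that("binding-energy differences are symmetric absolute gaps", {
  expect_equal(bfe_difference(-227.08, -262.51), 35.43, tolerance = 1e-9)
  expect_equal(bfe_difference(-5, -5), 0)
  expect_equal(bfe_difference(-5, 3), bfe_difference(3, -5))
  one <- data.frame(frame = 1, dE_int = -10, dE_ele = -20, dE_vdw = -5,
                    dG_pol = 3, dG_nonpol = -1)
  expect_equal(bfe_difference(bfe_combine(one, window = 1), -30), 3)
})

test_that("energy tables round-trip through the reader", {
  tab <- energy_fixture(n = 10L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_energy_table(tf)
  expect_equal(back, tab, tolerance = 1e-12)
  dup <- tab; dup$frame[2] <- 1
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(dup, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_energy_table(tf2), "duplicate")
})
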