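toy_circuit <- function(n) {
  list(name = "toy", type = "toy",
       atoms = seq_len(n), bonds = cbind(seq_len(n), c(seq_len(n)[-1], 1)))
}

test_that("a circuit with all bonds at R_opt scores exactly (1, 0, 0)", {
  p <- homa_params()
  n <- 6
  ang <- 2 * pi * (0:5) / 6
  r <- 1.388 / (2 * sin(pi / 6))
  xyz <- cbind(r * cos(ang), r * sin(ang), 0)
  out <- homa(toy_circuit(6), xyz, p, elements = rep("C", 6))
  expect_equal(out$homa, 1, tolerance = 1e-12)
  expect_equal(out$en, 0, tolerance = 1e-12)
  expect_equal(out$geo, 0, tolerance = 1e-12)
})

test_that("two-bond toy circuit at R_opt +/- 0.05 gives EN 0, GEO 0.644", {
  # hand oracle: Rbar = R_opt so EN = 0; GEO = 257.7 / 2 * 2 * 0.05^2 = 0.644250
  p <- homa_params()
  circ <- list(name = "toy", type = "toy", atoms = 1:3,
               bonds = rbind(c(1, 2), c(2, 3)))
  xyz <- rbind(c(0, 0, 0), c(1.388 + 0.05, 0, 0),
               c(1.388 + 0.05 + 1.388 - 0.05, 0, 0))
  out <- homa(circ, xyz, p, elements = rep("C", 3))
  expect_equal(out$en, 0, tolerance = 1e-12)
  expect_equal(out$geo, 257.7 * 0.05^2, tolerance = 1e-12)
  expect_equal(out$homa, 1 - 257.7 * 0.05^2, tolerance = 1e-12)
})

test_that("calibration scores the reference inner circuit at exactly 1", {
  p <- calibrate()
  ref <- reference_geometry()
  tpl <- make_template("Zn")
  sc <- homa_all_circuits(tpl$structure, tpl$map, p)
  expect_equal(sc$homa[sc$type == "inner"], 1, tolerance = 1e-12)
  # determinism: calibrating twice yields identical parameters
  p2 <- calibrate()
  expect_identical(p$r_opt, p2$r_opt)
  # the rescale mechanism also scores the reference at 1, for all circuits
  pr <- calibrate(mechanism = "rescale")
  sc2 <- homa_all_circuits(tpl$structure, tpl$map, pr)
  expect_equal(sc2$homa, rep(1, 5), tolerance = 1e-10)
})

test_that("a strongly bond-alternated circuit scores below 1 after calibration", {
  p <- calibrate()
  circ <- toy_circuit(6)
  circ$type <- "inner"
  ang <- 2 * pi * (0:5) / 6
  xyz0 <- cbind(1.4 * cos(ang) / (2 * sin(pi / 6)), 1.4 * sin(ang) / (2 * sin(pi / 6)), 0)
  # alternate bond lengths by radial breathing of alternate vertices
  xyz <- xyz0 * rep(c(1.05, 0.95), 3)
  out <- homa(circ, xyz, p, elements = rep("C", 6))
  expect_lt(out$homa, 1)
  expect_gt(out$geo, 0)
})

test_that("HOMA + EN + GEO = 1 and component zeros hold on random circuits", {
  p <- homa_params()
  set.seed(42)
  for (k in 1:25) {
    n <- sample(3:8, 1)
    xyz <- matrix(rnorm(3 * n, sd = 2), ncol = 3)
    # keep bonds away from zero length
    xyz <- xyz + 3 * diag(nrow = n, ncol = 3)[, 1] %o% c(1, 0, 0)
    xyz[, 1] <- xyz[, 1] + 3 * seq_len(n)
    el <- rep("C", n); el[2] <- "N"   # one heteroatom, no N-N bonds
    out <- homa(toy_circuit(n), xyz, p, elements = el)
    expect_equal(out$homa + out$en + out$geo, 1, tolerance = 1e-10)
    expect_gte(out$en, 0)
    expect_gte(out$geo, 0)
    # rigid-motion invariance
    out2 <- homa(toy_circuit(n), rigid_move(xyz), p, elements = el)
    expect_equal(out2$homa, out$homa, tolerance = 1e-9)
  }
})

test_that("EN vanishes iff the mean matches R_opt; GEO iff bonds are equal", {
  p <- homa_params()
  circ <- list(name = "t", type = "t", atoms = 1:3,
               bonds = rbind(c(1, 2), c(2, 3)))
  xyz_eq <- rbind(c(0, 0, 0), c(1.45, 0, 0), c(2.90, 0, 0))
  out <- homa(circ, xyz_eq, p, elements = rep("C", 3))
  expect_equal(out$geo, 0, tolerance = 1e-12)
  expect_gt(out$en, 0)
})

test_that("C-N bonds map onto the CC scale by Pauling bond number", {
  # a pyridine-like C-N bond of 1.338 A has an effective CC length near
  # the aromatic optimum; verify against a direct evaluation of the
  # conversion formulas (independent arithmetic oracle)
  k <- porphgeom:::pauling_constants()
  n_bond <- exp((1.465 - 1.338) / ((1.465 - 1.269) / log(2)))
  expected <- 1.467 - (1.467 - 1.349) / log(2) * log(n_bond)
  expect_equal(porphgeom:::cc_equivalent_of_cn(1.338), expected, tolerance = 1e-12)
  expect_lt(abs(expected - 1.388), 0.01)
  # inverse consistency
  expect_equal(porphgeom:::cc_equivalent_of_cn(
    porphgeom:::cn_equivalent_of_cc(1.40)), 1.40, tolerance = 1e-12)
})

test_that("degenerate inputs raise errors", {
  p <- homa_params()
  empty <- list(name = "e", type = "e", atoms = 1:2,
                bonds = matrix(numeric(0), 0, 2))
  xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0))
  expect_error(homa(empty, xyz, p, elements = c("C", "C")), "empty circuit")
  off <- list(name = "o", type = "o", atoms = 1:2, bonds = rbind(c(1, 5)))
  expect_error(homa(off, xyz, p, elements = c("C", "C")), "outside geometry")
})
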