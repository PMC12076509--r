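test_that("templates pass curation and carry the requested substitution", {
  tpp <- make_template("Zn", meso = "Ph")
  rep <- apply_filters(tpp$structure)
  expect_true(rep$pass)
  det <- find_porphyrin_macrocycle(tpp$structure)
  expect_equal(det$n_macrocycles, 1)

  ni <- make_template("Ni")
  fv <- build_feature_vector(ni$structure, ni$map, "cone_angles")
  expect_equal(fv$coordination_number, 4)

  full <- make_template("Zn", meso = "Me", beta = "Me")
  ring_subs <- full$map$substituents
  expect_equal(sum(ring_subs$position %in% c("meso", "beta")), 12)
  expect_error(make_template("Zn", meso = "nosuch"), "unknown substituent")
})

test_that("generated structures round-trip through XYZ and detection", {
  tpl <- make_template("Ru", meso = "Ph", axial = "py")
  s <- distort_template(tpl, c(sad = 1.1, ruf = -0.6))
  lines <- write_xyz(s)
  s2 <- parse_structure(lines, format = "xyz")
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-6)
  s2 <- perceive_bonds(s2)
  det <- find_porphyrin_macrocycle(s2)
  expect_equal(det$n_macrocycles, 1)
})

test_that("the ruffling scan starts at the calibrated score and crosses over", {
  scan <- distortion_scan("ruffling")
  expect_equal(scan$homa_inner[scan$amplitude == 0], 1, tolerance = 1e-10)
  hp <- scan$homa_pyrrole_mean
  imax <- which.max(hp)
  expect_gt(imax, 1)                      # an initial increasing region
  expect_lt(imax, nrow(scan))             # followed by a decrease
  expect_true(all(diff(hp[1:imax]) > 0))
  expect_true(all(diff(hp[imax:length(hp)]) < 0))
})

test_that("the saddling scan decreases pyrrole aromaticity monotonically", {
  scan <- distortion_scan("saddling")
  expect_true(all(diff(scan$homa_pyrrole_mean) < 0))
  expect_true(all(diff(scan$homa_inner) < 0))
})

test_that("scan results are invariant to grid order and rigid motion", {
  grid <- c(0, 0.5, 1.0, 2.0)
  s1 <- distortion_scan("ruffling", amplitudes = grid)
  s2 <- distortion_scan("ruffling", amplitudes = rev(grid))
  expect_equal(dplyr::arrange(s2, amplitude), s1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a noiseless population reproduces the planted law exactly", {
  spec <- population_spec(n = 25, sigma = 0, seed = 77)
  pop <- generate_population(spec)
  fn <- feature_names("cone_angles")
  Z <- scale(as.matrix(pop$data[, fn]))
  want_sad <- spec$intercept_sad + drop(Z %*% spec$beta_sad[fn])
  expect_lt(max(abs(pop$data$sad - want_sad)), 1e-8)
  expect_lt(max(abs(pop$data$total_oop -
                    sqrt(pop$data$sad^2 + pop$data$ruf^2))), 1e-8)
})

test_that("population generation is deterministic for a fixed seed", {
  p1 <- generate_population(population_spec(n = 15, seed = 5))
  p2 <- generate_population(population_spec(n = 15, seed = 5))
  expect_identical(p1$data, p2$data)
  p3 <- generate_population(population_spec(n = 15, seed = 6))
  expect_false(identical(p3$data$sad, p1$data$sad))
})

test_that("negative noise levels are rejected", {
  expect_error(population_spec(n = 10, sigma = -0.1, seed = 1))
  expect_error(population_spec(n = 10, seed = ), "mandatory")
})

test_that("the filter fixture set has one pass and targeted failures", {
  fx <- make_filter_fixtures()
  expect_length(fx, 8)
  rep <- apply_filters(fx)
  expect_equal(sum(rep$pass), 1)
  fn <- filter_names()
  for (k in 2:8) {
    fails <- fn[!unlist(rep[k, fn])]
    expect_identical(fails, names(fx)[k])
  }
})
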