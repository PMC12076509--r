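test_that("the mode basis is orthonormal, mean-free and tilt-free", {
  b <- nsd_basis()
  expect_equal(colnames(b$B), mode_names)
  G <- t(b$B) %*% b$B
  expect_lt(max(abs(G - diag(6))), 1e-10)
  expect_lt(max(abs(colSums(b$B))), 1e-10)
  # orthogonal to rigid tilts about x and y
  expect_lt(max(abs(t(b$B) %*% b$ref_xyz[, 1])), 1e-9)
  expect_lt(max(abs(t(b$B) %*% b$ref_xyz[, 2])), 1e-9)
  # label sanity: ruffling lives on meso/alpha/beta with N in plane,
  # saddling has meso and N in plane
  ref <- b$reference
  expect_lt(max(abs(b$B[ref$n_idx, "ruf"])), 1e-12)
  expect_lt(max(abs(b$B[ref$n_idx, "sad"])), 1e-12)
  expect_lt(max(abs(b$B[ref$cm_idx, "sad"])), 1e-12)
  expect_equal(which.max(abs(b$B[, "ruf"])) %in% ref$cm_idx, TRUE)
})

test_that("a planar macrocycle decomposes to zero", {
  b <- default_nsd_basis()
  r <- nsd_decompose(b$ref_xyz, ref_map24(), b)
  expect_lt(max(abs(as.numeric(r[1, mode_names]))), 1e-12)
  expect_equal(r$total_oop, 0, tolerance = 1e-12)
})

test_that("imposed single and paired modes are recovered independently", {
  b <- default_nsd_basis()
  m <- ref_map24()
  g <- impose_distortion(b, c(ruf = 1.0))
  r <- nsd_decompose(g, m, b)
  expect_equal(r$ruf, 1.0, tolerance = 1e-10)
  expect_lt(max(abs(as.numeric(r[1, setdiff(mode_names, "ruf")]))), 1e-10)
  expect_lt(r$residual, 1e-10)

  g2 <- impose_distortion(b, c(ruf = 1.3, sad = -0.8))
  r2 <- nsd_decompose(g2, m, b)
  expect_equal(r2$ruf, 1.3, tolerance = 1e-10)
  expect_equal(r2$sad, -0.8, tolerance = 1e-10)

  g3 <- impose_distortion(b, c(sad = 0.5, dom = 0.2))
  r3 <- nsd_decompose(g3, m, b)
  expect_equal(r3$total_oop, sqrt(0.5^2 + 0.2^2), tolerance = 1e-10)
})

test_that("impose -> decompose recovers random amplitude vectors to 1e-8", {
  b <- default_nsd_basis()
  m <- ref_map24()
  set.seed(2024)
  for (k in 1:200) {
    a <- runif(6, -3, 3)
    g <- impose_distortion(b, stats::setNames(a, mode_names))
    r <- nsd_decompose(g, m, b)
    expect_lt(max(abs(as.numeric(r[1, mode_names]) - a)), 1e-8)
  }
})

test_that("energy partition holds on arbitrary geometries", {
  b <- default_nsd_basis()
  m <- ref_map24()
  set.seed(5)
  for (k in 1:20) {
    g <- b$ref_xyz + matrix(rnorm(72, sd = 0.15), 24, 3)
    r <- nsd_decompose(g, m, b)
    a <- as.numeric(r[1, mode_names])
    expect_equal(sum(a^2) + r$residual^2, r$total_oop^2, tolerance = 1e-8)
  }
})

test_that("decomposition is invariant under rigid-body motion", {
  b <- default_nsd_basis()
  m <- ref_map24()
  set.seed(6)
  a <- runif(6, -2, 2)
  g <- impose_distortion(b, stats::setNames(a, mode_names))
  g2 <- rigid_move(g, axis = c(2, -1, 3), angle = 1.2, shift = c(-4, 2, 7))
  r2 <- nsd_decompose(g2, m, b)
  expect_lt(max(abs(as.numeric(r2[1, mode_names]) - a)), 1e-8)
})

test_that("the mirror image of a ruffled geometry flips the ruffling sign", {
  b <- default_nsd_basis()
  m <- ref_map24()
  g <- impose_distortion(b, c(ruf = 0.9))
  g_mirror <- g %*% diag(c(1, 1, -1))
  r <- nsd_decompose(g_mirror, m, b)
  expect_equal(r$ruf, -0.9, tolerance = 1e-8)
})

test_that("zero amplitudes return the reference geometry exactly", {
  b <- default_nsd_basis()
  expect_identical(impose_distortion(b, numeric(0)), b$ref_xyz)
  expect_error(impose_distortion(b, c(bogus = 1)), "unknown mode")
})

test_that("plane fitting matches closed-form least squares", {
  tpl <- make_template("Zn")
  pl <- fit_reference_plane(tpl$structure, tpl$map)
  expect_lt(max(abs(pl$residuals)), 1e-12)

  # 4 N at z = (+a, -a, +a, -a) on symmetric x, y: LS plane is z = 0
  b <- default_nsd_basis()
  g <- b$ref_xyz
  a <- 0.4
  g[1:4, 3] <- c(a, -a, a, -a)
  pl2 <- fit_reference_plane(g, ref_map24())
  expect_equal(abs(pl2$normal[3]), 1, tolerance = 1e-10)
  expect_equal(pl2$center[3], 0, tolerance = 1e-10)
  expect_equal(sort(pl2$residuals), sort(c(a, -a, a, -a)), tolerance = 1e-10)

  # rotating the input rotates the fitted plane identically
  R <- rotation_matrix(c(1, 1, 0), 0.8)
  pl3 <- fit_reference_plane(g %*% t(R), ref_map24())
  expect_equal(abs(sum(pl3$normal * (R %*% pl2$normal))), 1, tolerance = 1e-9)
  expect_equal(pl3$rmsd, pl2$rmsd, tolerance = 1e-10)
  expect_error(fit_reference_plane(matrix(c(1:24 * 0.1, rep(0, 48)), 24, 3),
                                   ref_map24()), "degenerate")
})

test_that("per-atom deviation follows the total / 24 convention", {
  expect_equal(mean_per_atom_deviation(0.6), 0.025)
  expect_equal(mean_per_atom_deviation(0), 0)
  expect_equal(mean_per_atom_deviation(2.4), 0.1)
  b <- default_nsd_basis()
  r <- nsd_decompose(impose_distortion(b, c(sad = 1.2)), ref_map24(), b)
  expect_equal(mean_per_atom_deviation(r), 0.05, tolerance = 1e-10)
})

test_that("distorted full templates keep substituent bonds rigid", {
  tpl <- make_template("Zn", meso = "Ph", axial = "py")
  s2 <- distort_template(tpl, c(ruf = 1.5, sad = 0.7))
  blen <- function(s) {
    xyz <- coords(s)
    sqrt(rowSums((xyz[s$bonds$i, ] - xyz[s$bonds$j, ])^2))
  }
  subs <- tpl$map$substituents
  ph <- subs$atoms[[which(subs$position == "meso")[1]]]
  inb <- tpl$structure$bonds$i %in% ph & tpl$structure$bonds$j %in% ph
  expect_equal(blen(s2)[inb], blen(tpl$structure)[inb], tolerance = 1e-12)
  # and the NSD of the distorted structure matches what was imposed
  r <- nsd_decompose(s2, tpl$map)
  expect_equal(r$ruf, 1.5, tolerance = 1e-8)
  expect_equal(r$sad, 0.7, tolerance = 1e-8)
})
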