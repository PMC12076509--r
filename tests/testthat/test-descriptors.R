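test_that("single-atom cones match the closed form", {
  expect_equal(cone_angle(c(0, 0, 0), c(2, 0, 0), 1.0), 60, tolerance = 1e-9)
  expect_equal(cone_angle(c(1, 1, 1), c(1, 1, 4), 1.5),
               2 * asin(0.5) * 180 / pi, tolerance = 1e-9)
  expect_equal(cone_angle(c(0, 0, 0), c(0, 3, 0), 0), 0)
  expect_error(cone_angle(c(0, 0, 0), c(1, 0, 0), 1.2), "vdW sphere")
  expect_error(cone_angle(c(0, 0, 0), c(0, 0, 0), 0), "coincides")
})

test_that("two point atoms at +/- 30 degrees give a 60 degree cone", {
  pos <- rbind(2 * c(cos(pi / 6), sin(pi / 6), 0),
               2 * c(cos(pi / 6), -sin(pi / 6), 0))
  got <- cone_angle(c(0, 0, 0), pos, 0, use_vdw = FALSE)
  expect_equal(got, 60, tolerance = 1e-6)
  expect_equal(grid_cone_angle(c(0, 0, 0), pos), 60, tolerance = 0.5)
})

test_that("the optimizer matches dense grid search within 0.5 degrees", {
  set.seed(99)
  for (k in 1:12) {
    n <- sample(2:5, 1)
    pos <- matrix(rnorm(3 * n, sd = 1.5), ncol = 3)
    pos <- sweep(pos, 1, pmax(sqrt(rowSums(pos^2)), 0.8), "/") *
      runif(n, 1.5, 4)
    r <- runif(n, 0, 0.9)
    got <- cone_angle(c(0, 0, 0), pos, r)
    want <- grid_cone_angle(c(0, 0, 0), pos, r)
    expect_lt(abs(got - want), 0.5)
  }
})

test_that("cone angle is rigid-motion invariant and radius-monotone", {
  set.seed(4)
  pos <- matrix(rnorm(9, sd = 2), 3, 3)
  pos <- pos + 4
  r <- c(0.5, 0.8, 0.3)
  a1 <- cone_angle(c(0, 0, 0), pos, r)
  moved <- rigid_move(rbind(c(0, 0, 0), pos))
  a2 <- cone_angle(moved[1, ], moved[-1, ], r)
  expect_equal(a1, a2, tolerance = 1e-6)
  a3 <- cone_angle(c(0, 0, 0), pos, r + c(0, 0.3, 0))
  expect_gte(a3, a1)
})

test_that("surrogate distances reproduce coordinate arithmetic for points", {
  tpl <- make_template("Zn")   # H at every site
  subs <- tpl$map$substituents
  pick <- function(site) subs[subs$site == site, ]
  d_bb <- surrogate_distance(tpl$structure, tpl$map,
                             pick(13), pick(14), "beta_beta")
  # oracle: both H transplant to site_pos + 1.09 * site_dir
  fr <- surrogate_frame("beta_beta")
  p1 <- fr[[1]]$pos + 1.09 * fr[[1]]$dir
  p2 <- fr[[2]]$pos + 1.09 * fr[[2]]$dir
  expect_equal(d_bb, sqrt(sum((p1 - p2)^2)), tolerance = 1e-9)
  # symmetry under swapping A and B
  expect_equal(surrogate_distance(tpl$structure, tpl$map, pick(14), pick(13),
                                  "beta_beta"), d_bb, tolerance = 1e-12)
  d_mb <- surrogate_distance(tpl$structure, tpl$map, pick(21), pick(15),
                             "meso_beta")
  expect_gt(d_mb, 0)
})

test_that("bulkier substituents reduce the surrogate crowding distance", {
  d_for <- function(meso_key) {
    tpl <- make_template("Zn", meso = meso_key)
    subs <- tpl$map$substituents
    pick <- function(site) subs[subs$site == site, ]
    surrogate_distance(tpl$structure, tpl$map, pick(21), pick(15), "meso_beta")
  }
  d_H <- d_for("H"); d_Me <- d_for("Me"); d_Et <- d_for("Et")
  expect_lt(d_Me, d_H)
  expect_lt(d_Et, d_H)
})

test_that("metal radius lookup is the packaged covalent table", {
  expect_identical(metal_radius("Zn"), covalent_radius("Zn"))
  expect_identical(metal_radius("Ru"), metal_radius("Ru"))
  expect_false(metal_radius("Zn") == metal_radius("Ru"))
  expect_error(metal_radius("Qq"), "unknown element")
})

test_that("feature vectors follow the coordination-number conventions", {
  ni <- make_template("Ni")
  fv <- build_feature_vector(ni$structure, ni$map, "cone_angles")
  expect_equal(fv$coordination_number, 4)
  expect_equal(fv$mean_axial_cone, -1)

  ax2 <- make_template("Zn", axial = c("probe1.20", "probe1.20"))
  fv2 <- build_feature_vector(ax2$structure, ax2$map, "cone_angles")
  expect_equal(fv2$coordination_number, 6)
  expect_equal(fv2$mean_axial_cone, 2 * asin(1.2 / 2.3) * 180 / pi,
               tolerance = 1e-9)

  tpp <- make_template("Zn", meso = "Ph")
  fv3 <- build_feature_vector(tpp$structure, tpp$map, "cone_angles")
  ph_row <- tpp$map$substituents[tpp$map$substituents$position == "meso", ][1, ]
  expect_equal(fv3$mean_meso_cone,
               substituent_cone_angle(tpp$structure, tpp$map, ph_row),
               tolerance = 1e-9)
  expect_equal(fv3$mean_beta_cone, 0)  # atom-center cone of H
})

test_that("feature vectors are identical across the 8 symmetry images", {
  tpl <- make_template("Zn", meso = c("Ph", "H", "Me", "H"),
                       beta = c("H", "H", "Me", "H", "H", "H", "H", "H"))
  fvs <- lapply(porphgeom:::macrocycle_images(tpl$map), function(im) {
    im$metal_idx <- tpl$map$metal_idx
    im$axial_idx <- tpl$map$axial_idx
    im$substituents <- tpl$map$substituents
    class(im) <- "porph_macrocycle_map"
    im <- canonical_atom_ordering(im)
    build_feature_vector(tpl$structure, im, "distances")
  })
  for (k in 2:8) expect_equal(fvs[[k]], fvs[[1]], tolerance = 1e-9)
})
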