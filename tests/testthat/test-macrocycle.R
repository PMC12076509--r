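test_that("porphine macrocycle is detected with correct roles", {
  tpl <- make_template("Zn")
  det <- find_porphyrin_macrocycle(tpl$structure)
  expect_equal(det$n_macrocycles, 1)
  m <- det$map
  expect_setequal(m$n_idx, 1:4)
  expect_setequal(m$ca_idx, 5:12)
  expect_setequal(m$cb_idx, 13:20)
  expect_setequal(m$cm_idx, 21:24)
  expect_equal(m$metal_idx, 25)
})

test_that("detection is invariant to atom-index permutation and rigid motion", {
  tpl <- make_template("Ni", meso = c("Ph", "H", "H", "H"))
  s <- tpl$structure
  set.seed(7)
  perm <- sample(nrow(s$atoms))
  inv <- match(seq_len(nrow(s$atoms)), perm)
  s2 <- new_structure(s$atoms[perm, ],
                      tibble::tibble(i = inv[s$bonds$i], j = inv[s$bonds$j]),
                      source_id = s$source_id)
  s2 <- set_coords(s2, rigid_move(coords(s2)))
  det <- find_porphyrin_macrocycle(s2)
  expect_equal(det$n_macrocycles, 1)
  # same atoms selected, modulo the permutation
  expect_setequal(perm[macrocycle_order24(det$map)], 1:24)
  expect_equal(perm[det$map$metal_idx], 25)
})

test_that("a corrole-like direct pyrrole link is not a porphyrin", {
  tpl <- make_template("Zn")
  s <- tpl$structure
  # delete one meso carbon and bond its two alpha neighbors directly
  cm <- 21L
  nb <- sort(unique(c(s$bonds$j[s$bonds$i == cm], s$bonds$i[s$bonds$j == cm])))
  alphas <- nb[nb %in% 5:12]
  s$bonds <- dplyr::bind_rows(s$bonds,
                              tibble::tibble(i = alphas[1], j = alphas[2],
                                             order = 1L))
  keep <- setdiff(seq_len(nrow(s$atoms)), cm)
  s <- porphgeom:::remove_atoms(s, cm)
  det <- find_porphyrin_macrocycle(s)
  expect_null(det$map)
  expect_equal(det$n_macrocycles, 0)
})

test_that("a covalently linked bis-porphyrin reports two macrocycles", {
  dimer <- make_filter_fixtures()$monomer
  det <- find_porphyrin_macrocycle(dimer)
  expect_equal(det$n_macrocycles, 2)
})

test_that("circuits have the prescribed sizes and atom content", {
  tpl <- make_template("Zn")
  circ <- enumerate_circuits(tpl$map)
  expect_length(circ, 5)
  expect_equal(vapply(circ, function(c) nrow(c$bonds), 1L), c(16L, 5L, 5L, 5L, 5L))
  inner <- circ[[1]]
  expect_length(inner$atoms, 16)
  expect_false(any(tpl$map$cb_idx %in% inner$atoms))           # no Cbeta
  expect_setequal(inner$atoms, c(tpl$map$n_idx, tpl$map$ca_idx, tpl$map$cm_idx))
  # pyrrole atoms + meso carbons partition the 24 macrocycle atoms
  pyr_atoms <- unlist(lapply(circ[-1], `[[`, "atoms"))
  expect_setequal(c(pyr_atoms, tpl$map$cm_idx), macrocycle_order24(tpl$map))
  # every circuit bond exists in the structure
  bonds <- paste(pmin(tpl$structure$bonds$i, tpl$structure$bonds$j),
                 pmax(tpl$structure$bonds$i, tpl$structure$bonds$j))
  for (c in circ) {
    expect_true(all(paste(pmin(c$bonds[, 1], c$bonds[, 2]),
                          pmax(c$bonds[, 1], c$bonds[, 2])) %in% bonds))
  }
})

test_that("substituents classify by attachment position", {
  tpp <- make_template("Zn", meso = "Ph")
  subs <- classify_substituents(tpp$structure, tpp$map)
  expect_equal(sum(subs$position == "meso"), 4)
  expect_equal(sum(subs$position == "beta"), 8)
  expect_true(all(lengths(subs$atoms[subs$position == "meso"]) == 11))
  expect_true(all(lengths(subs$atoms[subs$position == "beta"]) == 1))

  oep <- make_template("Ni", beta = "Et")
  subs <- classify_substituents(oep$structure, oep$map)
  expect_equal(sum(subs$position == "beta" & lengths(subs$atoms) == 7), 8)

  ax <- make_template("Zn", axial = "py")
  subs <- classify_substituents(ax$structure, ax$map)
  expect_equal(sum(subs$position == "axial"), 1)
})

test_that("canonical ordering is idempotent and image-invariant", {
  tpl <- make_template("Zn", meso = c("Ph", "H", "H", "H"))
  canon <- canonical_atom_ordering(tpl$map)
  expect_identical(macrocycle_order24(canonical_atom_ordering(canon)),
                   macrocycle_order24(canon))
  images <- porphgeom:::macrocycle_images(tpl$map)
  canon_all <- lapply(images, function(im) {
    im$metal_idx <- tpl$map$metal_idx
    im$substituents <- tpl$map$substituents
    class(im) <- "porph_macrocycle_map"
    macrocycle_order24(canonical_atom_ordering(im))
  })
  expect_length(unique(canon_all), 1)
})

test_that("different substitution patterns canonicalize differently", {
  one <- make_template("Zn", meso = c("Ph", "H", "H", "H"))
  two <- make_template("Zn", meso = c("Ph", "Ph", "H", "H"))
  enc <- function(tpl) {
    m <- canonical_atom_ordering(tpl$map)
    k <- stats::setNames(m$substituents$key, m$substituents$site)
    paste(k[as.character(c(m$cm_idx, m$cb_idx))], collapse = "|")
  }
  expect_false(identical(enc(one), enc(two)))
  # but a rotated version of the same pattern encodes identically
  rot <- make_template("Zn", meso = c("H", "Ph", "H", "H"))
  expect_identical(enc(one), enc(rot))
})
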