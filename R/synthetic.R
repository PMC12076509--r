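#' Pure-distortion scan of the HOMA scores
#'
#' Starting from the planar reference macrocycle, imposes a pure ruffling
#' or saddling distortion at each requested total out-of-plane amplitude
#' (atoms displace along the plane normal with in-plane coordinates fixed,
#' so bonds elongate geometrically), and scores every circuit with the
#' calibrated HOMA parameters.
#'
#' @param mode `"ruffling"` or `"saddling"`.
#' @param amplitudes Total out-of-plane grid in Angstrom (the mode vectors
#'   are unit-norm, so the imposed amplitude equals the total out-of-plane
#'   value). Default 0 to 4 in 0.1 steps.
#' @param params Calibrated HOMA parameters (default [calibrate()]).
#' @param basis NSD basis.
#' @return A `porph_scan` tibble: `mode`, `amplitude`, `total_oop`,
#'   `homa_inner`, `en_inner`, `geo_inner`, `homa_pyrrole_mean`,
#'   `en_pyrrole_mean`, `geo_pyrrole_mean`.
#' @export
distortion_scan <- function(mode = c("ruffling", "saddling"),
                            amplitudes = seq(0, 4, by = 0.1),
                            params = calibrate(),
                            basis = default_nsd_basis()) {
  mode <- match.arg(mode)
  key <- c(ruffling = "ruf", saddling = "sad")[[mode]]
  ref <- basis$reference
  elements <- ifelse(ref$role == "N", "N", "C")
  map <- new_macrocycle_map(ref$n_idx, ref$ca_idx, ref$cb_idx, ref$cm_idx)
  rows <- lapply(amplitudes, function(a) {
    g <- impose_distortion(basis, stats::setNames(a, key))
    sc <- homa_all_circuits(g, map, params, elements = elements)
    out <- homa_summary(sc)
    out$amplitude <- a
    out$total_oop <- a
    out
  })
  out <- dplyr::bind_rows(rows)
  out$mode <- mode
  out <- dplyr::relocate(out, "mode", "amplitude", "total_oop")
  class(out) <- c("porph_scan", class(out))
  out
}

#' Synthetic population specification
#'
#' Defines the study conditions for the synthetic metalloporphyrin
#' population: sample size, the planted linear law mapping the five steric
#' descriptors (standardized) to the saddling and ruffling amplitudes, the
#' noise level, and the sampling distributions for metals, coordination
#' numbers and substituent bulk. The planted coefficient signs encode the
#' expected chemistry: bulkier ring substituents increase distortion,
#' larger metals and larger axial ligands / coordination numbers decrease
#' it, with ruffling more metal/axial-sensitive and saddling more
#' ring-substituent-sensitive.
#'
#' @param n Number of structures.
#' @param beta_sad,beta_ruf Planted coefficients (Angstrom per standardized
#'   feature unit) for the cone-angle features, in [feature_names()] order.
#' @param intercept_sad,intercept_ruf Baseline amplitudes (Angstrom).
#' @param sigma Noise standard deviation (Angstrom); NULL derives it from
#'   `r2` so that the planted signal explains about that variance fraction.
#' @param r2 Target coefficient of determination when `sigma` is NULL.
#' @param metals Candidate central metals.
#' @param p_axial Probabilities of 0, 1, 2 axial ligands.
#' @param seed Mandatory integer seed.
#' @return A `porph_population_spec` list.
#' @export
population_spec <- function(n = 400,
                            beta_sad = c(metal_radius = -0.20,
                                         coordination_number = -0.05,
                                         mean_axial_cone = -0.08,
                                         mean_meso_cone = 0.30,
                                         mean_beta_cone = 0.25),
                            beta_ruf = c(metal_radius = -0.30,
                                         coordination_number = -0.12,
                                         mean_axial_cone = -0.15,
                                         mean_meso_cone = 0.18,
                                         mean_beta_cone = 0.15),
                            intercept_sad = 1.2, intercept_ruf = 1.0,
                            sigma = NULL, r2 = 0.7,
                            metals = c("Ni", "Zn", "Mg", "Ru", "Pd", "Sn"),
                            p_axial = c(0.35, 0.44, 0.21),
                            seed) {
  stopifnot(n >= 1, is.null(sigma) || sigma >= 0)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  structure(list(n = n, beta_sad = beta_sad, beta_ruf = beta_ruf,
                 intercept_sad = intercept_sad, intercept_ruf = intercept_ruf,
                 sigma = sigma, r2 = r2, metals = metals, p_axial = p_axial,
                 seed = as.integer(seed)),
            class = "porph_population_spec")
}

probe_key <- function(r) sprintf("probe%.2f", r)

#' Generate a synthetic metalloporphyrin population
#'
#' Draws metals, coordination numbers and substituent bulk from the spec's
#' distributions, computes the five steric descriptors, sets each
#' structure's saddling and ruffling amplitudes by the planted linear law
#' plus Gaussian noise, builds the corresponding distorted 3D structures
#' with [distort_template()], and then re-measures every target (NSD and
#' calibrated HOMA) from the built geometries -- so at `sigma = 0` the
#' measured amplitudes reproduce the planted law exactly.
#'
#' @param spec A `porph_population_spec`.
#' @param include_structures Keep the structure objects (default FALSE).
#' @return List with `data` (features for both representations + measured
#'   targets + `sub_ids`), `truth` (planted coefficients, sigma, seed) and
#'   optionally `structures`.
#' @export
generate_population <- function(spec, include_structures = FALSE) {
  stopifnot(inherits(spec, "porph_population_spec"))
  set.seed(spec$seed)
  n <- spec$n
  # distinct radius grids keep meso/beta/axial identities separate, which
  # gives the unseen-substituent split a fine-grained identity pool
  meso_levels <- probe_key(seq(0.90, 1.70, by = 0.1))
  beta_levels <- probe_key(seq(0.85, 1.65, by = 0.1))
  axial_levels <- probe_key(seq(1.00, 2.10, by = 0.1))

  metal <- sample(spec$metals, n, replace = TRUE)
  n_ax <- sample(0:2, n, replace = TRUE, prob = spec$p_axial)
  meso_key <- sample(meso_levels, n, replace = TRUE)
  beta_key <- ifelse(stats::runif(n) < 0.4, "H",
                     sample(beta_levels, n, replace = TRUE))
  axial_key <- sample(axial_levels, n, replace = TRUE)

  params <- calibrate()
  basis <- default_nsd_basis()

  templates <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    ax <- if (n_ax[i] > 0) rep(axial_key[i], n_ax[i]) else character()
    tpl <- make_template(metal[i], meso = meso_key[i], beta = beta_key[i],
                         axial = ax, source_id = sprintf("synth-%04d", i))
    templates[[i]] <- tpl
    feats[[i]] <- dplyr::bind_cols(
      build_feature_vector(tpl$structure, tpl$map, "cone_angles")[, -1],
      build_feature_vector(tpl$structure, tpl$map,
                           "distances")[, c("mean_beta_beta_dist",
                                            "mean_meso_beta_dist")])
  }
  X <- dplyr::bind_rows(feats)

  fn <- feature_names("cone_angles")
  Z <- scale(as.matrix(X[, fn]))
  sig_sad <- drop(Z %*% spec$beta_sad[fn])
  sig_ruf <- drop(Z %*% spec$beta_ruf[fn])
  sigma <- spec$sigma
  if (is.null(sigma)) {
    sigma <- stats::sd(c(sig_sad, sig_ruf)) * sqrt((1 - spec$r2) / spec$r2)
  }
  sad <- spec$intercept_sad + sig_sad + stats::rnorm(n, 0, sigma)
  ruf <- spec$intercept_ruf + sig_ruf + stats::rnorm(n, 0, sigma)

  meas <- vector("list", n)
  structures <- vector("list", n)
  for (i in seq_len(n)) {
    s <- distort_template(templates[[i]], c(sad = sad[i], ruf = ruf[i]),
                          basis = basis)
    structures[[i]] <- s
    nsd <- nsd_decompose(s, templates[[i]]$map, basis)
    hs <- homa_summary(homa_all_circuits(s, templates[[i]]$map, params))
    meas[[i]] <- dplyr::bind_cols(
      nsd[, c("sad", "ruf", "abs_sad", "abs_ruf", "total_oop")],
      hs[, c("homa_inner", "homa_pyrrole_mean")])
  }
  Y <- dplyr::bind_rows(meas)

  data <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("synth-%04d", seq_len(n)),
                   metal = metal,
                   sub_ids = lapply(seq_len(n), function(i) {
                     unique(templates[[i]]$map$substituents$key)
                   })),
    X, Y)
  out <- list(data = data,
              truth = list(beta_sad = spec$beta_sad,
                           beta_ruf = spec$beta_ruf,
                           intercept_sad = spec$intercept_sad,
                           intercept_ruf = spec$intercept_ruf,
                           sigma = sigma, seed = spec$seed,
                           planted_sad = sad, planted_ruf = ruf))
  if (include_structures) out$structures <- structures
  out
}

# --- structure-editing helpers for fixtures ----------------------------

remove_atoms <- function(s, idx) {
  keep <- setdiff(seq_len(nrow(s$atoms)), idx)
  remap <- match(seq_len(nrow(s$atoms)), keep)
  b <- s$bonds[s$bonds$i %in% keep & s$bonds$j %in% keep, ]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  new_structure(s$atoms[keep, ], b, source_id = s$source_id)
}

add_atoms <- function(s, atoms, bonds = NULL) {
  base <- nrow(s$atoms)
  at <- dplyr::bind_rows(s$atoms, tibble::as_tibble(atoms))
  b <- s$bonds
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    b <- dplyr::bind_rows(b, tibble::tibble(i = bonds[, 1], j = bonds[, 2],
                                            order = 1L))
  }
  out <- new_structure(at, b, source_id = s$source_id)
  out
}

combine_structures <- function(s1, s2, source_id = s1$source_id) {
  base <- nrow(s1$atoms)
  b2 <- s2$bonds; b2$i <- b2$i + base; b2$j <- b2$j + base
  new_structure(dplyr::bind_rows(s1$atoms, s2$atoms),
                dplyr::bind_rows(s1$bonds, b2), source_id = source_id)
}

translate_structure <- function(s, v) {
  set_coords(s, sweep(coords(s), 2, v, `+`))
}

#' Curation-filter fixture set
#'
#' Builds one structure passing all seven curation filters and, for each
#' filter, one structure violating exactly that filter: a free-base
#' porphyrin diacid (no central ion), a porphyrin with a detached fragment
#' declared part of the same molecule (disconnected), a directly-linked
#' bis-porphyrin (two macrocycles), a chlorin-like structure with two sp3
#' beta carbons (wrong saturation), an ethylenediamine chelate bound twice
#' to the metal (multidentate), a copper porphine (odd electron count), and
#' a 21-atom counter molecule (counter size).
#'
#' @return Named list of 8 `porph_structure` objects, in filter order.
#' @export
make_filter_fixtures <- function() {
  ref <- reference_geometry()
  zn <- make_template("Zn", source_id = "fixture-pass")$structure

  # 1: free-base diacid: drop the metal, protonate all four N inward
  fb <- make_template("Zn", source_id = "fixture-no-central-ion")$structure
  fb <- remove_atoms(fb, 25L)
  hN <- t(vapply(1:4, function(p) {
    v <- ref$xyz[p, ]; v - 1.01 * v / sqrt(sum(v^2))
  }, numeric(3)))
  fb <- add_atoms(fb,
                  tibble::tibble(element = "H", x = hN[, 1], y = hN[, 2],
                                 z = hN[, 3], mol_id = 1L),
                  cbind(1:4, nrow(fb$atoms) + 1:4))

  # 2: detached formaldehyde declared part of the porphyrin molecule
  disc <- make_template("Zn", source_id = "fixture-disconnected")$structure
  frag <- tibble::tibble(element = c("C", "O", "H", "H"),
                         x = c(0, 1.22, -0.55, -0.55),
                         y = c(0, 0, 0.93, -0.93),
                         z = 5, mol_id = 1L)
  nb <- nrow(disc$atoms)
  disc <- add_atoms(disc, frag, rbind(c(nb + 1, nb + 2), c(nb + 1, nb + 3),
                                      c(nb + 1, nb + 4)))

  # 3: meso-meso directly linked bis-porphyrin (one component)
  a <- make_template("Zn", source_id = "fixture-dimer")$structure
  b <- make_template("Zn")$structure
  # meso 1 of A is atom 21; its H is the grafted substituent on site 21
  subH <- function(s, site) {
    cand <- c(s$bonds$j[s$bonds$i == site], s$bonds$i[s$bonds$j == site])
    cand[cand > 25][1]
  }
  hA <- subH(a, 21L)
  hB <- subH(b, 23L)                  # meso 3 of B (opposite side)
  a2 <- remove_atoms(a, hA)
  b2 <- remove_atoms(b, hB)
  t1 <- reference_geometry()$xyz[21, 1]  # meso radial component
  shift <- 2 * sqrt(2) * t1 + 1.49
  b2 <- translate_structure(b2, c(shift / sqrt(2), shift / sqrt(2), 0))
  dimer <- combine_structures(a2, b2, source_id = "fixture-dimer")
  nb <- nrow(a2$atoms)
  dimer$bonds <- dplyr::bind_rows(dimer$bonds,
                                  tibble::tibble(i = 21L, j = nb + 23L,
                                                 order = 1L))
  dimer$atoms$mol_id <- 1L

  # 4: chlorin-like: one pyrrole's beta carbons made sp3 (extra H each)
  chl <- make_template("Zn", source_id = "fixture-saturation")$structure
  cb <- ref$xyz[13:14, ]
  chl <- add_atoms(chl,
                   tibble::tibble(element = "H",
                                  x = cb[, 1], y = cb[, 2], z = 1.09,
                                  mol_id = 1L),
                   cbind(13:14, nrow(chl$atoms) + 1:2))

  # 5: ethylenediamine bound through both N to the metal
  bid <- make_template("Zn", source_id = "fixture-bidentate")$structure
  en_at <- tibble::tibble(
    element = c("N", "N", "C", "C", rep("H", 8)),
    x = c(1.0, -1.0, 0.72, -0.72, 1.8, 1.2, -1.8, -1.2, 1.4, 0.6, -1.4, -0.6),
    y = c(0, 0, 0, 0, 0.5, -0.8, 0.5, -0.8, 0.9, 1.4, 0.9, 1.4),
    z = c(2.0, 2.0, 3.2, 3.2, 1.8, 1.8, 1.8, 1.8, 3.6, 3.6, 3.6, 3.6),
    mol_id = 1L)
  nb <- nrow(bid$atoms)
  en_b <- rbind(c(25, nb + 1), c(25, nb + 2),           # two metal bonds
                c(nb + 1, nb + 3), c(nb + 2, nb + 4), c(nb + 3, nb + 4),
                c(nb + 1, nb + 5), c(nb + 1, nb + 6),
                c(nb + 2, nb + 7), c(nb + 2, nb + 8),
                c(nb + 3, nb + 9), c(nb + 3, nb + 10),
                c(nb + 4, nb + 11), c(nb + 4, nb + 12))
  bid <- add_atoms(bid, en_at, en_b)

  # 6: copper porphine: odd total electron count (d9 open shell)
  cu <- make_template("Cu", source_id = "fixture-odd-electrons")$structure

  # 7: 21-atom counter molecule (cycloheptane), separate molecule id
  cs <- make_template("Zn", source_id = "fixture-counter-size")$structure
  ang <- 2 * pi * (0:6) / 7
  ring <- cbind(8 + 1.53 / (2 * sin(pi / 7)) * cos(ang),
                1.53 / (2 * sin(pi / 7)) * sin(ang), 8)
  hup <- ring + matrix(rep(c(0.6, 0, 0.9), each = 7), ncol = 3)
  hdn <- ring + matrix(rep(c(-0.6, 0, -0.9), each = 7), ncol = 3)
  cyc <- tibble::tibble(element = c(rep("C", 7), rep("H", 14)),
                        x = c(ring[, 1], hup[, 1], hdn[, 1]),
                        y = c(ring[, 2], hup[, 2], hdn[, 2]),
                        z = c(ring[, 3], hup[, 3], hdn[, 3]),
                        mol_id = 2L)
  nb <- nrow(cs$atoms)
  cyc_b <- rbind(cbind(nb + 1:7, nb + c(2:7, 1)),
                 cbind(nb + 1:7, nb + 8:14),
                 cbind(nb + 1:7, nb + 15:21))
  cs <- add_atoms(cs, cyc, cyc_b)

  list(pass = zn, central_ion = fb, connected = disc, monomer = dimer,
       saturation = chl, monodentate = bid, even_electrons = cu,
       counter_size = cs)
}
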