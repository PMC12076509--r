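#' @keywords internal
#' Pauling bond-number constants shared by the HOMA C-N treatment and the
#' reference geometry. Single/double reference lengths in Angstrom.
pauling_constants <- function() {
  list(cc1 = 1.467, cc2 = 1.349, cn1 = 1.465, cn2 = 1.269,
       c_cc = (1.467 - 1.349) / log(2),
       c_cn = (1.465 - 1.269) / log(2))
}

# C-N length whose Pauling bond number matches a C-C bond of length r_cc
cn_equivalent_of_cc <- function(r_cc, k = pauling_constants()) {
  n <- exp((k$cc1 - r_cc) / k$c_cc)
  k$cn1 - k$c_cn * log(n)
}

# map a C-N bond length onto the C-C scale (same Pauling bond number)
cc_equivalent_of_cn <- function(r_cn, k = pauling_constants()) {
  n <- exp((k$cn1 - r_cn) / k$c_cn)
  k$cc1 - k$c_cc * log(n)
}

#' Geometry parameters of the idealized planar metalloporphine reference
#'
#' The reference macrocycle is planar with D4h symmetry. All C-C bonds of
#' the aromatic inner cross (Calpha-Cmeso) are set to the aromatic optimum
#' 1.388 + offsets below; the N-Calpha length is chosen so that its Pauling
#' bond number equals that of the Calpha-Cmeso bond, i.e. the whole inner
#' circuit carries a uniform bond order (the aromatic-equivalence reference
#' that scores HOMA = 1 by construction). Pyrrole-only bonds take typical
#' crystallographic porphine values.
#'
#' @return Named list of lengths (Angstrom) and angles (degrees).
#' @export
reference_params <- function() {
  list(
    r_ca_cm = 1.395,                      # Calpha-Cmeso (inner-cross CC)
    r_n_ca  = cn_equivalent_of_cc(1.395), # N-Calpha, same bond order
    r_ca_cb = 1.440,                      # Calpha-Cbeta
    r_cb_cb = 1.355,                      # Cbeta-Cbeta
    d_n     = 2.05,                       # metal-N distance
    ang_cnc = 106,                        # Calpha-N-Calpha angle
    r_ch    = 1.09                        # C-H
  )
}

#' Idealized planar metalloporphine reference geometry
#'
#' Builds the 24 macrocycle atoms in the canonical ordering used throughout
#' the package: N 1-4 (pyrrole p at azimuth 90*(p-1) degrees), Calpha 5-12
#' (per pyrrole: entering then leaving atom of the counterclockwise walk),
#' Cbeta 13-20 (same pairing), Cmeso 21-24 (meso p bridges pyrroles p and
#' p+1). z = 0 everywhere; the metal sits at the origin.
#'
#' @param params See [reference_params()].
#' @return List with `xyz` (24 x 3 matrix), `role` (character), `pyrrole`
#'   (integer 1-4, NA for meso), and the index vectors `n_idx`, `ca_idx`,
#'   `cb_idx`, `cm_idx`.
#' @export
reference_geometry <- function(params = reference_params()) {
  p <- params
  h <- (p$ang_cnc / 2) * pi / 180
  xa <- p$d_n + p$r_n_ca * cos(h)
  ya <- p$r_n_ca * sin(h)
  yb <- p$r_cb_cb / 2
  if (ya <= yb) stop("degenerate pyrrole geometry", call. = FALSE)
  xb <- xa + sqrt(p$r_ca_cb^2 - (ya - yb)^2)
  # meso on the diagonal (t, t): equidistant (r_ca_cm) from Calpha (xa, ya)
  # and its 90-degree image (ya, xa)
  bb <- xa + ya
  cc <- (xa^2 + ya^2 - p$r_ca_cm^2) / 2
  disc <- bb^2 - 4 * cc
  if (disc <= 0) stop("degenerate meso geometry", call. = FALSE)
  t <- (bb + sqrt(disc)) / 2

  rot <- function(v, k) {            # rotate 2D point by k*90 degrees
    a <- k * pi / 2
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
  }
  xyz <- matrix(0, 24, 3)
  role <- character(24)
  pyr <- rep(NA_integer_, 24)
  for (k in 0:3) {
    pN <- rot(c(p$d_n, 0), k)
    xyz[1 + k, 1:2] <- pN; role[1 + k] <- "N"; pyr[1 + k] <- k + 1L
    ca_in  <- rot(c(xa, -ya), k)   # entering alpha (from meso p-1 side)
    ca_out <- rot(c(xa,  ya), k)   # leaving alpha (toward meso p)
    xyz[5 + 2 * k, 1:2] <- ca_in;  role[5 + 2 * k] <- "Ca"; pyr[5 + 2 * k] <- k + 1L
    xyz[6 + 2 * k, 1:2] <- ca_out; role[6 + 2 * k] <- "Ca"; pyr[6 + 2 * k] <- k + 1L
    cb_in  <- rot(c(xb, -yb), k)
    cb_out <- rot(c(xb,  yb), k)
    xyz[13 + 2 * k, 1:2] <- cb_in;  role[13 + 2 * k] <- "Cb"; pyr[13 + 2 * k] <- k + 1L
    xyz[14 + 2 * k, 1:2] <- cb_out; role[14 + 2 * k] <- "Cb"; pyr[14 + 2 * k] <- k + 1L
    pm <- rot(c(t, t), k)
    xyz[21 + k, 1:2] <- pm; role[21 + k] <- "Cm"
  }
  list(xyz = xyz, role = role, pyrrole = pyr,
       n_idx = 1:4, ca_idx = 5:12, cb_idx = 13:20, cm_idx = 21:24,
       params = p)
}

# --- substituent library -----------------------------------------------

tetra_dirs <- function() {
  # three unit vectors at 109.47 deg from -x, azimuths 0/120/240 about x
  a <- 1 / 3; b <- sqrt(1 - a^2)
  rbind(c(a, b * cos(0), b * sin(0)),
        c(a, b * cos(2 * pi / 3), b * sin(2 * pi / 3)),
        c(a, b * cos(4 * pi / 3), b * sin(4 * pi / 3)))
}

sub_atoms <- function(element, xyz, vdw = NA_real_) {
  tibble::tibble(element = element,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 vdw = vdw)
}

hexagon_local <- function(d0, r_ring) {
  # regular hexagon in the xz-plane; vertex 1 points back toward the apex
  ctr <- c(d0 + r_ring, 0, 0)
  ang <- pi + (0:5) * pi / 3
  cbind(ctr[1] + r_ring * cos(ang), 0, r_ring * sin(ang))
}

#' Substituent library
#'
#' Local-frame geometries for the packaged substituents. Each entry places
#' the attachment (ring or metal) atom at the origin with the bond along +x;
#' `atoms` is the substituent atom table (first row = the atom bonded to the
#' attachment site), `bonds` the internal bond list (1-based within the
#' substituent), `d_ring`/`d_axial` the attachment bond lengths. Probe
#' substituents (`probe<r>`, e.g. `"probe1.4"`) are single He pseudo-atoms
#' carrying a vdW-radius override of r Angstrom, giving a continuously
#' tunable steric bulk.
#'
#' @param key Substituent name.
#' @return List as described.
#' @export
substituent_geometry <- function(key) {
  td <- tetra_dirs()
  if (grepl("^probe", key)) {
    r <- as.numeric(sub("^probe", "", key))
    if (is.na(r) || r <= 0) stop("unknown substituent key: ", key, call. = FALSE)
    return(list(atoms = sub_atoms("He", matrix(c(1.9, 0, 0), 1), vdw = r),
                bonds = NULL, d_ring = 1.9, d_axial = 2.3))
  }
  halide <- c(F = 1.35, Cl = 1.73, Br = 1.90, I = 2.10)
  if (key %in% names(halide)) {
    d <- halide[[key]]
    return(list(atoms = sub_atoms(key, matrix(c(d, 0, 0), 1)),
                bonds = NULL, d_ring = d, d_axial = d + 0.4))
  }
  switch(key,
    H = list(atoms = sub_atoms("H", matrix(c(1.09, 0, 0), 1)),
             bonds = NULL, d_ring = 1.09, d_axial = 1.6),
    Me = {
      c1 <- c(1.50, 0, 0)
      hs <- sweep(1.09 * td, 2, c1, `+`)
      list(atoms = sub_atoms(c("C", "H", "H", "H"), rbind(c1, hs)),
           bonds = cbind(1, 2:4), d_ring = 1.50, d_axial = 2.1)
    },
    Et = {
      c1 <- c(1.50, 0, 0)
      c2 <- c1 + 1.53 * td[1, ]
      h1 <- sweep(1.09 * td[2:3, ], 2, c1, `+`)
      # methyl H on c2, pointing away from c1
      ax2 <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
      h2 <- t(vapply(1:3, function(i) {
        d <- rotate_about_axis(td[i, ], c(0, 0, 1), pi / 3)
        c2 + 1.09 * align_frame(ax2) %*% d
      }, numeric(3)))
      list(atoms = sub_atoms(c("C", "C", "H", "H", "H", "H", "H"),
                             rbind(c1, c2, h1, h2)),
           bonds = rbind(c(1, 2), cbind(1, 3:4), cbind(2, 5:7)),
           d_ring = 1.50, d_axial = 2.1)
    },
    Ph = {
      ring <- hexagon_local(1.48, 1.39)
      ctr <- c(1.48 + 1.39, 0, 0)
      hpos <- t(apply(ring[2:6, ], 1, function(v) {
        out <- (v - ctr) / sqrt(sum((v - ctr)^2)); v + 1.08 * out
      }))
      list(atoms = sub_atoms(c(rep("C", 6), rep("H", 5)), rbind(ring, hpos)),
           bonds = rbind(cbind(1:6, c(2:6, 1)), cbind(2:6, 7:11)),
           d_ring = 1.48, d_axial = 2.1)
    },
    py = {  # axial pyridine bound through N
      ring <- hexagon_local(2.10, 1.37)
      ctr <- c(2.10 + 1.37, 0, 0)
      hpos <- t(apply(ring[2:6, ], 1, function(v) {
        out <- (v - ctr) / sqrt(sum((v - ctr)^2)); v + 1.08 * out
      }))
      list(atoms = sub_atoms(c("N", rep("C", 5), rep("H", 5)),
                             rbind(ring, hpos)),
           bonds = rbind(cbind(1:6, c(2:6, 1)), cbind(2:6, 7:11)),
           d_ring = 1.48, d_axial = 2.10)
    },
    OH2 = {
      o <- c(2.15, 0, 0)
      hdir <- rbind(c(cos(0.9), sin(0.9), 0), c(cos(0.9), -sin(0.9), 0))
      hs <- sweep(0.96 * hdir, 2, o, `+`)
      list(atoms = sub_atoms(c("O", "H", "H"), rbind(o, hs)),
           bonds = cbind(1, 2:3), d_ring = 1.43, d_axial = 2.15)
    },
    CO = list(atoms = sub_atoms(c("C", "O"),
                                rbind(c(1.95, 0, 0), c(3.08, 0, 0))),
              bonds = matrix(c(1, 2), 1), d_ring = 1.95, d_axial = 1.95),
    NH3 = {
      n0 <- c(2.15, 0, 0)
      hs <- sweep(1.02 * td, 2, n0, `+`)
      list(atoms = sub_atoms(c("N", "H", "H", "H"), rbind(n0, hs)),
           bonds = cbind(1, 2:4), d_ring = 1.47, d_axial = 2.15)
    },
    stop("unknown substituent key: ", key, call. = FALSE)
  )
}

#' Names of the packaged substituents
#' @return Character vector (probes excluded; any `probe<r>` is also valid).
#' @export
substituent_keys <- function() {
  c("H", "F", "Cl", "Br", "I", "Me", "Et", "Ph", "py", "OH2", "CO", "NH3")
}

rotate_about_axis <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation matrix taking local +x to `dir`, local +z as close to `up` as
# possible (deterministic frame completion)
align_frame <- function(dir, up = c(0, 0, 1)) {
  ex <- dir / sqrt(sum(dir^2))
  if (abs(sum(ex * up)) > 0.99) up <- c(1, 0, 0)
  ez <- up - sum(up * ex) * ex
  ez <- ez / sqrt(sum(ez^2))
  ey <- pracma_cross(ez, ex)
  cbind(ex, ey, ez)
}

#' Build an idealized substituted metalloporphine
#'
#' Grafts substituents from the packaged library onto the planar reference
#' macrocycle at the requested beta/meso sites (replacing the default H) and
#' attaches axial ligands to the central metal along +/- z. All bonds are
#' declared explicitly, so the result does not depend on bond re-perception.
#' The unsubstituted template passes all seven curation filters by
#' construction.
#'
#' @param metal Element symbol of the central atom (e.g. "Zn", "Ni").
#' @param meso,beta Substituent keys, recycled to length 4 / 8.
#' @param axial Character vector of 0-2 axial ligand keys.
#' @param params Reference geometry parameters.
#' @param source_id Label for the structure.
#' @return List with `structure` (a `porph_structure`) and `map` (a
#'   `porph_macrocycle_map`, see [find_porphyrin_macrocycle()]).
#' @export
make_template <- function(metal = "Zn", meso = "H", beta = "H",
                          axial = character(), params = reference_params(),
                          source_id = NULL) {
  ref <- reference_geometry(params)
  meso <- rep_len(meso, 4)
  beta <- rep_len(beta, 8)
  if (length(axial) > 2) stop("at most 2 axial ligands", call. = FALSE)
  if (is.null(source_id)) {
    source_id <- sprintf("%s-porphine[m:%s|b:%s|ax:%s]", metal,
                         paste(unique(meso), collapse = ","),
                         paste(unique(beta), collapse = ","),
                         paste(axial, collapse = ","))
  }

  atoms <- tibble::tibble(element = ifelse(ref$role == "N", "N", "C"),
                          x = ref$xyz[, 1], y = ref$xyz[, 2], z = ref$xyz[, 3],
                          vdw = NA_real_)
  bonds <- macrocycle_bond_list()
  metal_idx <- 25L
  atoms <- dplyr::bind_rows(atoms, tibble::tibble(
    element = metal, x = 0, y = 0, z = 0, vdw = NA_real_))
  bonds <- rbind(bonds, cbind(1:4, metal_idx))

  subs <- list()
  graft <- function(atoms, bonds, key, site_idx, dir, up, axial_site = FALSE) {
    g <- substituent_geometry(key)
    d0 <- sqrt(sum((as.matrix(g$atoms[1, c("x", "y", "z")]))^2))
    dtarget <- if (axial_site) g$d_axial else g$d_ring
    R <- align_frame(dir, up)
    loc <- as.matrix(g$atoms[, c("x", "y", "z")])
    loc <- loc * (dtarget / d0)  # radial rescale puts atom 1 at bond length
    if (nrow(loc) > 1) {
      # keep internal geometry: shift all atoms rigidly instead of scaling
      loc <- as.matrix(g$atoms[, c("x", "y", "z")])
      loc[, 1] <- loc[, 1] + (dtarget - d0)
    }
    glob <- t(R %*% t(loc)) + matrix(rep(as.numeric(atoms[site_idx, c("x", "y", "z")]),
                                         each = nrow(loc)), ncol = 3)
    base <- nrow(atoms)
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      element = g$atoms$element, x = glob[, 1], y = glob[, 2], z = glob[, 3],
      vdw = g$atoms$vdw))
    bonds <- rbind(bonds, c(site_idx, base + 1L))
    if (!is.null(g$bonds)) bonds <- rbind(bonds, g$bonds + base)
    list(atoms = atoms, bonds = bonds,
         rec = list(site = site_idx, atom_idx = base + seq_len(nrow(loc)),
                    key = key))
  }

  out_dir <- function(i) {  # in-plane outward direction at ring atom i
    v <- ref$xyz[i, 1:2]
    if (ref$role[i] == "Cb") {
      # external bisector of the two ring bonds
      nb <- setdiff(which(macrocycle_adjacency()[i, ] == 1), integer())
      b1 <- ref$xyz[nb[1], 1:2] - v; b2 <- ref$xyz[nb[2], 1:2] - v
      d <- -(b1 / sqrt(sum(b1^2)) + b2 / sqrt(sum(b2^2)))
      c(d / sqrt(sum(d^2)), 0)
    } else {
      c(v / sqrt(sum(v^2)), 0)
    }
  }

  for (k in 1:4) {  # meso sites
    i <- 20L + k
    r <- graft(atoms, bonds, meso[k], i, out_dir(i), c(0, 0, 1))
    atoms <- r$atoms; bonds <- r$bonds
    subs <- c(subs, list(c(r$rec, position = "meso")))
  }
  for (k in 1:8) {  # beta sites
    i <- 12L + k
    r <- graft(atoms, bonds, beta[k], i, out_dir(i), c(0, 0, 1))
    atoms <- r$atoms; bonds <- r$bonds
    subs <- c(subs, list(c(r$rec, position = "beta")))
  }
  if (length(axial)) {
    zdir <- list(c(0, 0, 1), c(0, 0, -1))
    for (k in seq_along(axial)) {
      r <- graft(atoms, bonds, axial[k], metal_idx, zdir[[k]], c(1, 0, 0),
                 axial_site = TRUE)
      atoms <- r$atoms; bonds <- r$bonds
      subs <- c(subs, list(c(r$rec, position = "axial")))
    }
  }

  s <- new_structure(atoms,
                     tibble::tibble(i = bonds[, 1], j = bonds[, 2]),
                     source_id = source_id)
  s$atoms$mol_id <- 1L
  map <- new_macrocycle_map(
    n_idx = 1:4, ca_idx = 5:12, cb_idx = 13:20, cm_idx = 21:24,
    metal_idx = metal_idx,
    substituents = tibble::tibble(
      site = vapply(subs, function(r) as.integer(r$site), 1L),
      position = vapply(subs, function(r) r$position, ""),
      key = vapply(subs, function(r) r$key, ""),
      atoms = lapply(subs, function(r) as.integer(r$atom_idx))))
  list(structure = s, map = map)
}

# intra-macrocycle bonds in the canonical 24-index layout
macrocycle_bond_list <- function() {
  b <- NULL
  for (k in 0:3) {
    n <- 1 + k; ca_in <- 5 + 2 * k; ca_out <- 6 + 2 * k
    cb_in <- 13 + 2 * k; cb_out <- 14 + 2 * k
    cm <- 21 + k; cm_prev <- 21 + (k + 3) %% 4
    b <- rbind(b,
               c(n, ca_in), c(n, ca_out),
               c(ca_in, cb_in), c(ca_out, cb_out), c(cb_in, cb_out),
               c(ca_out, cm), c(ca_in, cm_prev))
  }
  b
}

macrocycle_adjacency <- function() {
  A <- matrix(0L, 24, 24)
  b <- macrocycle_bond_list()
  A[b] <- 1L; A[b[, 2:1]] <- 1L
  A
}
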