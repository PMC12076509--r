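#' Maximal cone angle of a substituent
#'
#' The minimal full apex angle of a cone, anchored at the attachment
#' (apex) atom, that contains the whole substituent: with atom vectors
#' `v_i = atom_i - apex` and vdW radii `r_i`, the half angle is
#' `min over unit axes u of max_i [ angle(u, v_i) + asin(r_i / |v_i|) ]`
#' and the reported cone angle is twice that, in degrees. The single-atom
#' case is solved in closed form (`2 asin(r/d)`); the general case by
#' Nelder-Mead over the axis direction from a fixed multistart set (atom
#' directions, their mean, and a coarse sphere net), which is deterministic
#' and is verified against dense grid search in the test-suite.
#'
#' @param apex Numeric length-3: apex position (Angstrom).
#' @param positions n x 3 matrix of substituent atom positions.
#' @param radii vdW radii (recycled); ignored when `use_vdw = FALSE`.
#' @param use_vdw Include vdW spheres (default TRUE).
#' @return Cone angle in degrees, in `[0, 360)`.
#' @export
cone_angle <- function(apex, positions, radii = 0, use_vdw = TRUE) {
  positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  v <- sweep(positions, 2, apex)
  d <- sqrt(rowSums(v^2))
  if (any(d < 1e-9)) stop("substituent atom coincides with the apex", call. = FALSE)
  r <- if (use_vdw) rep_len(radii, n) else rep(0, n)
  if (any(r >= d)) stop("apex lies inside an atom's vdW sphere", call. = FALSE)
  half <- asin(r / d)
  u <- v / d
  if (n == 1) return(2 * half[1] * 180 / pi)

  obj <- function(ang) {
    ax <- c(cos(ang[1]) * cos(ang[2]), cos(ang[1]) * sin(ang[2]), sin(ang[1]))
    max(acos(pmin(pmax(u %*% ax, -1), 1)) + half)
  }
  to_ang <- function(x) c(asin(pmin(pmax(x[3], -1), 1)), atan2(x[2], x[1]))
  mean_dir <- colSums(u); nm <- sqrt(sum(mean_dir^2))
  # deterministic multistart: atom directions, their mean, a coarse sphere
  # scan's best directions; Nelder-Mead refinement (restarted once, which
  # helps on the non-smooth max)
  net <- fib_net(600)
  net_val <- apply(net, 1, function(ax) obj(to_ang(ax)))
  starts <- rbind(u, if (nm > 1e-9) mean_dir / nm,
                  net[order(net_val)[1:5], ])
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(to_ang(starts[k, ]), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-13, maxit = 800))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-13, maxit = 800))
    if (o$value < best) best <- o$value
  }
  2 * best * 180 / pi
}

fib_net <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

sphere_net <- function() {
  a <- 1 / sqrt(2); b <- 1 / sqrt(3)
  rbind(diag(3), -diag(3),
        c(a, a, 0), c(a, -a, 0), c(-a, a, 0), c(-a, -a, 0),
        c(a, 0, a), c(a, 0, -a), c(-a, 0, a), c(-a, 0, -a),
        c(0, a, a), c(0, a, -a), c(0, -a, a), c(0, -a, -a),
        c(b, b, b), c(b, b, -b), c(b, -b, b), c(b, -b, -b),
        c(-b, b, b), c(-b, b, -b), c(-b, -b, b), c(-b, -b, -b))
}

#' Cone angle of a substituent record within a structure
#'
#' Apex = the ring attachment atom for beta/meso substituents and the metal
#' atom for axial ligands (the bounded atom the cone originates from).
#'
#' @param s A `porph_structure`.
#' @param map Its macrocycle map.
#' @param sub_row One row of `map$substituents` (or of
#'   [classify_substituents()] output).
#' @param radii Sphere radii convention: `"declared"` (default) uses the
#'   per-atom vdW overrides carried by the structure (the parameterized
#'   steric probes) and treats ordinary atoms as points -- Bondi radii of
#'   atoms bonded directly to the apex exceed the bond length, which would
#'   make the enclosing cone degenerate; `"bondi"` uses the full vdW table
#'   (and errors on such degenerate atoms); `"none"` is the pure
#'   atom-center cone.
#' @return Degrees.
#' @export
substituent_cone_angle <- function(s, map, sub_row,
                                   radii = c("declared", "bondi", "none")) {
  radii <- match.arg(radii)
  apex_idx <- if (identical(sub_row$position, "axial")) map$metal_idx else sub_row$site
  at <- sub_row$atoms[[1]]
  xyz <- coords(s)
  r <- switch(radii,
              none = rep(0, length(at)),
              declared = {
                v <- s$atoms$vdw[at]; v[is.na(v)] <- 0; v
              },
              bondi = {
                v <- s$atoms$vdw[at]
                v[is.na(v)] <- vdw_radius(s$atoms$element[at][is.na(v)])
                v
              })
  cone_angle(xyz[apex_idx, ], xyz[at, , drop = FALSE], r,
             use_vdw = !all(r == 0))
}

# --- surrogate crowding distances --------------------------------------

#' Surrogate attachment frames
#'
#' Fixed idealized fragments presenting two neighboring attachment sites of
#' a given class, used to measure inter-substituent crowding without
#' encoding any per-structure macrocycle information. Site positions and
#' outward bond directions are taken once from the packaged planar
#' reference: `beta_beta` presents two adjacent Cbeta sites of one pyrrole,
#' `meso_beta` a meso site and the nearest Cbeta site of the flanking
#' pyrrole.
#'
#' @param pair_class `"beta_beta"` or `"meso_beta"`.
#' @return List of two sites, each with `pos` and `dir` (unit, in-plane).
#' @export
surrogate_frame <- function(pair_class = c("beta_beta", "meso_beta")) {
  pair_class <- match.arg(pair_class)
  ref <- reference_geometry()
  out_dir24 <- function(i) {
    A <- macrocycle_adjacency()
    v <- ref$xyz[i, 1:2]
    if (i %in% ref$cb_idx) {
      nb <- which(A[i, ] == 1)
      b1 <- ref$xyz[nb[1], 1:2] - v; b2 <- ref$xyz[nb[2], 1:2] - v
      d <- -(b1 / sqrt(sum(b1^2)) + b2 / sqrt(sum(b2^2)))
      c(d / sqrt(sum(d^2)), 0)
    } else {
      c(v / sqrt(sum(v^2)), 0)
    }
  }
  idx <- if (pair_class == "beta_beta") {
    c(ref$cb_idx[1], ref$cb_idx[2])       # the two Cbeta of pyrrole 1
  } else {
    c(ref$cm_idx[1], ref$cb_idx[3])       # meso 1 and entering Cbeta of pyrrole 2
  }
  lapply(idx, function(i) list(pos = c(ref$xyz[i, 1:2], 0),
                               dir = out_dir24(i)))
}

#' Minimal inter-substituent distance on a surrogate frame
#'
#' Rigidly transplants both substituents (in their observed conformations)
#' onto the fixed surrogate frame by superposing each substituent's
#' attachment frame (apex atom position + bond direction, with a
#' deterministic completion of the rotational degree of freedom about the
#' bond axis) onto the corresponding surrogate site, then returns the
#' minimum over atom pairs of the center-to-center distance.
#'
#' @param s A `porph_structure`.
#' @param map Its macrocycle map.
#' @param subA,subB Substituent rows (as in [substituent_cone_angle()]).
#' @param pair_class `"beta_beta"` or `"meso_beta"`.
#' @return Distance in Angstrom (symmetric in A and B).
#' @export
surrogate_distance <- function(s, map, subA, subB,
                               pair_class = c("beta_beta", "meso_beta")) {
  pair_class <- match.arg(pair_class)
  frame <- surrogate_frame(pair_class)
  A <- transplant_substituent(s, map, subA, frame[[1]])
  B <- transplant_substituent(s, map, subB, frame[[2]])
  if (!nrow(A) || !nrow(B)) stop("empty substituent", call. = FALSE)
  dmin <- Inf
  for (k in seq_len(nrow(A))) {
    dk <- sqrt(colSums((t(B) - A[k, ])^2))
    dmin <- min(dmin, dk)
  }
  dmin
}

transplant_substituent <- function(s, map, sub, site) {
  at <- sub$atoms[[1]]
  if (!length(at)) stop("empty substituent", call. = FALSE)
  xyz <- coords(s)
  apex_idx <- if (identical(sub$position, "axial")) map$metal_idx else sub$site
  apex <- xyz[apex_idx, ]
  first <- at[1]
  bond <- xyz[first, ] - apex
  # secondary direction: first other substituent atom off the bond axis,
  # else global z (deterministic completion)
  up <- c(0, 0, 1)
  if (length(at) > 1) {
    w <- xyz[at[2], ] - apex
    w <- w - sum(w * bond) / sum(bond^2) * bond
    if (sqrt(sum(w^2)) > 1e-6) up <- w
  }
  Rsub <- align_frame(bond, up)       # local frame of the substituent
  Rsite <- align_frame(site$dir, c(0, 0, 1))
  rel <- sweep(xyz[at, , drop = FALSE], 2, apex)
  loc <- rel %*% Rsub                 # into substituent-local coordinates
  glob <- loc %*% t(Rsite)
  sweep(glob, 2, site$pos, `+`)
}

#' Metal radius descriptor
#'
#' @param element Central-atom element symbol.
#' @param table `"covalent"` (default, the packaged Cordero-type table).
#' @return Radius in Angstrom.
#' @export
metal_radius <- function(element, table = "covalent") {
  stopifnot(identical(table, "covalent"))
  covalent_radius(element)
}

#' Assemble the five-feature steric descriptor vector
#'
#' Both representations share the metal radius, the coordination number
#' (4 + number of axial ligands) and the mean axial-ligand cone angle
#' (fixed to -1 when the coordination number is 4). The `cone_angles`
#' variant adds the mean meso and mean beta substituent cone angles
#' (hydrogens included); the `distances` variant instead adds the mean
#' surrogate beta-beta and meso-beta crowding distances over all adjacent
#' pairs of the canonical layout.
#'
#' @param s A `porph_structure`.
#' @param map Its (canonicalized) macrocycle map.
#' @param variant `"cone_angles"` or `"distances"`.
#' @param radii Cone radius convention, see [substituent_cone_angle()].
#' @return One-row tibble of the five features plus `variant`.
#' @export
build_feature_vector <- function(s, map, variant = c("cone_angles", "distances"),
                                 radii = "declared") {
  variant <- match.arg(variant)
  subs <- map$substituents
  if (is.null(subs) || !nrow(subs)) stop("missing substituent annotation", call. = FALSE)
  if (is.na(map$metal_idx)) stop("missing metal annotation", call. = FALSE)
  cones <- vapply(seq_len(nrow(subs)), function(k) {
    substituent_cone_angle(s, map, subs[k, ], radii = radii)
  }, 1)
  subs$cone <- cones
  ax <- subs[subs$position == "axial", ]
  cn <- 4L + nrow(ax)
  mean_axial <- if (nrow(ax)) mean(ax$cone) else -1
  base <- tibble::tibble(
    variant = variant,
    metal_radius = metal_radius(s$atoms$element[map$metal_idx]),
    coordination_number = cn,
    mean_axial_cone = mean_axial)
  if (variant == "cone_angles") {
    base$mean_meso_cone <- mean(subs$cone[subs$position == "meso"])
    base$mean_beta_cone <- mean(subs$cone[subs$position == "beta"])
  } else {
    by_site <- stats::setNames(seq_len(nrow(subs)), subs$site)
    pick <- function(site) subs[by_site[[as.character(site)]], ]
    bb <- md <- numeric(0)
    for (p in 1:4) {
      b_in <- map$cb_idx[2 * p - 1]; b_out <- map$cb_idx[2 * p]
      if (all(c(b_in, b_out) %in% subs$site)) {
        bb <- c(bb, surrogate_distance(s, map, pick(b_in), pick(b_out),
                                       "beta_beta"))
      }
      cm <- map$cm_idx[p]
      pn <- (p %% 4) + 1
      nb1 <- map$cb_idx[2 * p]          # leaving Cbeta of pyrrole p
      nb2 <- map$cb_idx[2 * pn - 1]     # entering Cbeta of pyrrole p+1
      for (nb in c(nb1, nb2)) {
        if (all(c(cm, nb) %in% subs$site)) {
          md <- c(md, surrogate_distance(s, map, pick(cm), pick(nb),
                                         "meso_beta"))
        }
      }
    }
    base$mean_beta_beta_dist <- if (length(bb)) mean(bb) else NA_real_
    base$mean_meso_beta_dist <- if (length(md)) mean(md) else NA_real_
  }
  base
}

#' Feature names of a representation variant
#' @param variant `"cone_angles"` or `"distances"`.
#' @return Character vector of the five feature column names.
#' @export
feature_names <- function(variant = c("cone_angles", "distances")) {
  variant <- match.arg(variant)
  c("metal_radius", "coordination_number", "mean_axial_cone",
    if (variant == "cone_angles") c("mean_meso_cone", "mean_beta_cone")
    else c("mean_beta_beta_dist", "mean_meso_beta_dist"))
}
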