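#' Out-of-plane distortion mode basis
#'
#' Builds the six symmetry-adapted out-of-plane modes of the 24-atom
#' macrocycle on the packaged planar reference: saddling (B2u), ruffling
#' (B1u), doming (A2u), waving x/y (Eg) and propellering (A1u). The shapes
#' are constructed geometrically -- ruffling as the linearized rigid
#' counter-rotation of the pyrroles about their radial axes (with the meso
#' carbons following the extended pyrrole planes), saddling as alternating
#' pyrrole tilts about the tangential axes through N, doming as a mean-free
#' radial cone, propellering as same-sense pyrrole rotation, waving as a
#' step-like tilt of one opposite pyrrole pair -- then purged of rigid-body
#' content (net translation and global tilt) and orthonormalized by
#' Gram-Schmidt in a fixed order. All vectors are mutually orthonormal to
#' machine precision and sum to zero.
#'
#' @param reference Output of [reference_geometry()].
#' @return A `porph_nsd_basis`: list with `B` (24 x 6 matrix, columns
#'   `sad`, `ruf`, `dom`, `wav_x`, `wav_y`, `pro`), `ref_xyz`, `roles`.
#' @export
nsd_basis <- function(reference = reference_geometry()) {
  xyz <- reference$xyz
  pyr <- reference$pyrrole            # 1..4, NA for meso
  dn <- reference$params$d_n
  x <- xyz[, 1]; y <- xyz[, 2]
  rho <- sqrt(x^2 + y^2)
  # radial unit vector of each pyrrole (through its N)
  rhat <- t(vapply(1:4, function(p) {
    v <- xyz[reference$n_idx[p], 1:2]; v / sqrt(sum(v^2))
  }, numeric(2)))
  u_of <- function(p, i) rhat[p, 1] * y[i] - rhat[p, 2] * x[i]
  radial_of <- function(p, i) rhat[p, 1] * x[i] + rhat[p, 2] * y[i]
  s_p <- c(1, -1, 1, -1)
  is_meso <- is.na(pyr)
  meso_flank <- cbind(1:4, c(2, 3, 4, 1))  # meso p sits between these

  z_ruf <- numeric(24); z_sad <- numeric(24); z_pro <- numeric(24)
  for (i in which(!is_meso)) {
    p <- pyr[i]
    z_ruf[i] <- s_p[p] * u_of(p, i)
    z_sad[i] <- s_p[p] * (radial_of(p, i) - dn)
    z_pro[i] <- u_of(p, i)
  }
  for (k in 1:4) {
    i <- reference$cm_idx[k]
    p <- meso_flank[k, 1]
    z_ruf[i] <- s_p[p] * u_of(p, i)   # both flanking planes agree
  }
  z_dom <- mean(rho) - rho

  wave <- function(p_pos, p_neg, coord) {
    z <- numeric(24)
    for (i in which(!is_meso)) {
      if (pyr[i] == p_pos) z[i] <- coord[i] - dn
      if (pyr[i] == p_neg) z[i] <- coord[i] + dn
    }
    for (k in 1:4) {
      i <- reference$cm_idx[k]
      pred <- 0
      for (p in meso_flank[k, ]) {
        if (p == p_pos) pred <- pred + (coord[i] - dn)
        if (p == p_neg) pred <- pred + (coord[i] + dn)
      }
      z[i] <- pred / 2
    }
    z
  }
  z_wx <- wave(1, 3, x)
  z_wy <- wave(2, 4, y)

  rigid <- cbind(rep(1, 24), x, y)     # translation + tilts
  purge <- function(z, Q) {
    for (k in seq_len(ncol(Q))) {
      q <- Q[, k]
      z <- z - sum(z * q) / sum(q * q) * q
    }
    z
  }
  raw <- cbind(sad = z_sad, ruf = z_ruf, dom = z_dom,
               wav_x = z_wx, wav_y = z_wy, pro = z_pro)
  B <- matrix(0, 24, 6, dimnames = list(NULL, colnames(raw)))
  done <- NULL
  for (k in 1:6) {
    v <- purge(raw[, k], cbind(rigid, done))
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) stop("degenerate mode construction", call. = FALSE)
    B[, k] <- v / nv
    done <- cbind(done, B[, k])
  }
  structure(list(B = B, ref_xyz = xyz, reference = reference),
            class = "porph_nsd_basis")
}

#' Least-squares reference plane of a macrocycle
#'
#' @param geometry A `porph_structure` or coordinate matrix.
#' @param map The macrocycle map (atom indices into `geometry`).
#' @param mode `"N4"` (plane through the four pyrrole N, the default) or
#'   `"mean24"` (all macrocycle atoms).
#' @return List with `normal` (unit, oriented toward the metal's axial
#'   hemisphere when a metal exists, else toward the z-majority side),
#'   `center`, `residuals` (signed distances of the fitted atoms), `rmsd`.
#' @export
fit_reference_plane <- function(geometry, map, mode = c("N4", "mean24")) {
  mode <- match.arg(mode)
  xyz <- if (inherits(geometry, "porph_structure")) coords(geometry) else geometry
  idx <- if (mode == "N4") map$n_idx else macrocycle_order24(map)
  P <- xyz[idx, , drop = FALSE]
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-9) stop("degenerate (collinear) plane fit", call. = FALSE)
  normal <- sv$v[, 3]
  orient <- if (!is.na(map$metal_idx) &&
                map$metal_idx <= nrow(xyz)) {
    sum((xyz[map$metal_idx, ] - ctr) * normal)
  } else {
    sum(sign(Pc %*% normal))
  }
  if (orient < 0) normal <- -normal
  res <- as.numeric(Pc %*% normal)
  list(normal = normal, center = ctr, residuals = res,
       rmsd = sqrt(mean(res^2)))
}

kabsch_rotation <- function(X, Y) {
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# align 24-atom geometry to the reference frame by minimizing the in-plane
# (x, y) mismatch over proper rotations (Gauss-Newton on the rotation
# manifold); exact for pure out-of-plane displacements of the reference
align_to_reference <- function(X, ref_xyz, max_iter = 60, tol = 1e-15) {
  Xc <- sweep(X, 2, colMeans(X))
  ref_xy <- ref_xyz[, 1:2]

  exp_so3 <- function(w) {
    th <- sqrt(sum(w^2))
    if (th < 1e-300) return(diag(3))
    K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * K %*% K
  }

  run <- function(R0) {
    R <- R0
    obj_prev <- Inf
    for (it in seq_len(max_iter)) {
      P <- Xc %*% R
      rx <- P[, 1] - ref_xy[, 1]
      ry <- P[, 2] - ref_xy[, 2]
      obj <- sum(rx^2 + ry^2)
      if (obj_prev - obj < tol * (1 + obj)) break
      obj_prev <- obj
      # residual Jacobian wrt an infinitesimal rotation p -> p + w x p
      Jx <- cbind(0, P[, 3], -P[, 2])
      Jy <- cbind(-P[, 3], 0, P[, 1])
      J <- rbind(Jx, Jy)
      g <- crossprod(J, c(rx, ry))
      H <- crossprod(J) + 1e-12 * diag(3)
      w <- -solve(H, g)
      R <- R %*% t(exp_so3(as.numeric(w)))
    }
    P <- Xc %*% R
    list(R = R, P = P, obj = sum((P[, 1:2] - ref_xy)^2))
  }

  # initial orientation from the principal plane, both normal signs
  sv <- svd(Xc)
  n3 <- sv$v[, 3]
  base <- align_frame(n3)            # columns: n3 mapped from ez
  R0 <- cbind(base[, 2], base[, 3], base[, 1])  # rotation with R0 %*% ez ~ n3
  R0 <- t(R0)                        # Xc %*% t(...) puts normal on z
  cand <- list(run(inplane_spin(Xc, R0, ref_xy)),
               run(inplane_spin(Xc, R0 %*% diag(c(1, -1, -1)), ref_xy)))
  best <- which.min(vapply(cand, `[[`, 1, "obj"))
  cand[[best]]
}

# compose an in-plane rotation about z that best matches ref_xy
inplane_spin <- function(Xc, R, ref_xy) {
  P <- (Xc %*% R)[, 1:2]
  num <- sum(P[, 1] * ref_xy[, 2] - P[, 2] * ref_xy[, 1])
  den <- sum(P[, 1] * ref_xy[, 1] + P[, 2] * ref_xy[, 2])
  psi <- atan2(num, den)
  Rz <- rbind(c(cos(psi), sin(psi), 0), c(-sin(psi), cos(psi), 0), c(0, 0, 1))
  R %*% Rz
}

#' Normal-coordinate structural decomposition
#'
#' Aligns the 24 macrocycle atoms to the planar reference (in-plane
#' superposition: rotation chosen to minimize the in-plane mismatch, which
#' recovers the reference frame exactly for pure out-of-plane distortions),
#' then projects the out-of-plane displacement vector z onto the six mode
#' vectors. Amplitudes are signed; mirror-image distortions flip sign.
#' `total_oop` is the Euclidean norm of z and satisfies
#' `sum(amplitudes^2) + residual^2 = total_oop^2`.
#'
#' @param geometry A `porph_structure` or full coordinate matrix.
#' @param map Macrocycle map giving the canonical 24-atom ordering.
#' @param basis A `porph_nsd_basis` (default: basis on the packaged
#'   reference).
#' @return A one-row `porph_nsd` tibble: signed `sad`, `ruf`, `dom`,
#'   `wav_x`, `wav_y`, `pro`, then `abs_sad`, `abs_ruf`, `total_oop`,
#'   `residual`, `mean_dev` (per-atom deviation, total_oop / 24).
#' @export
nsd_decompose <- function(geometry, map, basis = default_nsd_basis()) {
  xyz <- if (inherits(geometry, "porph_structure")) coords(geometry) else geometry
  idx <- macrocycle_order24(map)
  if (max(idx) > nrow(xyz)) stop("macrocycle ordering does not match geometry",
                                 call. = FALSE)
  X <- xyz[idx, , drop = FALSE]
  al <- align_to_reference(X, basis$ref_xyz)
  z <- al$P[, 3]
  a <- drop(t(basis$B) %*% z)
  resid <- sqrt(sum((z - drop(basis$B %*% a))^2))
  out <- tibble::as_tibble(as.list(a))
  out$abs_sad <- abs(out$sad); out$abs_ruf <- abs(out$ruf)
  out$total_oop <- sqrt(sum(z^2))
  out$residual <- resid
  out$mean_dev <- out$total_oop / 24
  class(out) <- c("porph_nsd", class(out))
  out
}

.basis_env <- new.env(parent = emptyenv())

#' Packaged NSD basis on the default reference
#' @return A `porph_nsd_basis` (memoized).
#' @export
default_nsd_basis <- function() {
  if (is.null(.basis_env$basis)) .basis_env$basis <- nsd_basis()
  .basis_env$basis
}

#' Impose pure out-of-plane distortions on the reference macrocycle
#'
#' @param basis A `porph_nsd_basis`.
#' @param amplitudes Named numeric over the modes (missing modes = 0), e.g.
#'   `c(ruf = 1.0)`.
#' @return 24 x 3 coordinate matrix: reference + displacement along the
#'   plane normal. Round-trips through [nsd_decompose()] exactly.
#' @export
impose_distortion <- function(basis, amplitudes) {
  a <- numeric(6); names(a) <- colnames(basis$B)
  if (length(amplitudes)) {
    if (is.null(names(amplitudes))) {
      stopifnot(length(amplitudes) == 6)
      a[] <- amplitudes
    } else {
      bad <- setdiff(names(amplitudes), names(a))
      if (length(bad)) stop("unknown mode(s): ", paste(bad, collapse = ","),
                            call. = FALSE)
      a[names(amplitudes)] <- amplitudes
    }
  }
  out <- basis$ref_xyz
  out[, 3] <- out[, 3] + drop(basis$B %*% a)
  out
}

#' Distort a full template structure
#'
#' Displaces the macrocycle atoms by the requested mode amplitudes along
#' the reference plane normal; substituent atoms rigidly follow their
#' attachment ring atom; the metal and axial ligands stay in place.
#' Requires a structure whose macrocycle is in the reference orientation
#' (as produced by [make_template()]).
#'
#' @param template List with `structure` and `map` from [make_template()].
#' @param amplitudes As in [impose_distortion()].
#' @param basis NSD basis.
#' @return The distorted `porph_structure`.
#' @export
distort_template <- function(template, amplitudes,
                             basis = default_nsd_basis()) {
  s <- template$structure
  map <- template$map
  idx <- macrocycle_order24(map)
  new24 <- impose_distortion(basis, amplitudes)
  dz <- new24[, 3] - basis$ref_xyz[, 3]
  xyz <- coords(s)
  xyz[idx, 3] <- xyz[idx, 3] + dz
  subs <- map$substituents
  for (k in seq_len(nrow(subs))) {
    site <- subs$site[k]
    slot <- match(site, idx)
    if (!is.na(slot)) {
      xyz[subs$atoms[[k]], 3] <- xyz[subs$atoms[[k]], 3] + dz[slot]
    }
  }
  set_coords(s, xyz)
}

#' Mean per-atom out-of-plane deviation
#'
#' Converts a total out-of-plane value to the per-atom convention
#' (total / 24); e.g. a total of 0.6 Angstrom is a mean deviation of
#' 0.025 Angstrom per macrocycle atom.
#'
#' @param x A `porph_nsd` row or a numeric total out-of-plane value.
#' @return Numeric, Angstrom.
#' @export
mean_per_atom_deviation <- function(x) {
  if (inherits(x, "porph_nsd") || (is.list(x) && !is.null(x$total_oop))) {
    x <- x$total_oop
  }
  x / 24
}
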