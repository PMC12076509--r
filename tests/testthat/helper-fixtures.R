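# Shared fixtures built in code.

water_xyz <- function() {
  c("3", "water",
    "O  0.000000  0.000000  0.117300",
    "H  0.000000  0.757200 -0.469200",
    "H  0.000000 -0.757200 -0.469200")
}

# minimal P-1 CIF with one water in the asymmetric unit (two molecules in
# the cell after expansion)
water_cif <- function() {
  c("data_water",
    "_cell_length_a 10.0",
    "_cell_length_b 10.0",
    "_cell_length_c 10.0",
    "_cell_angle_alpha 90",
    "_cell_angle_beta 90",
    "_cell_angle_gamma 90",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "  'x,y,z'",
    "  '-x,-y,-z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "O1 O 0.25 0.25 0.25 1.0",
    "H1 H 0.175 0.25 0.30 1.0",
    "H2 H 0.325 0.25 0.30 1.0")
}

disorder_cif <- function(occ1 = 0.7, occ2 = 0.3) {
  c("data_dis",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "loop_",
    "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "_atom_site_occupancy", "_atom_site_disorder_assembly",
    "_atom_site_disorder_group",
    "C1 C 0.10 0.10 0.10 1.0 . .",
    sprintf("F1 F 0.12 0.24 0.10 %.2f A 1", occ1),
    sprintf("F2 F 0.12 0.00 0.24 %.2f A 2", occ2))
}

# dense direction net for brute-force cone-angle search
fib_sphere <- function(n = 20000) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# brute-force minimax over directions: global coarse pass, then a dense
# local pass in a cap around the coarse optimum (pure grid search oracle)
grid_cone_angle <- function(apex, positions, radii = 0, n = 20000) {
  positions <- matrix(positions, ncol = 3)
  v <- sweep(positions, 2, apex)
  d <- sqrt(rowSums(v^2))
  r <- rep_len(radii, nrow(positions))
  half <- asin(r / d)
  u <- v / d
  eval_dirs <- function(dirs) {
    ang <- acos(pmin(pmax(u %*% t(dirs), -1), 1))
    apply(ang + half, 2, max)
  }
  dirs <- fib_sphere(n)
  vals <- eval_dirs(dirs)
  best_dir <- dirs[which.min(vals), ]
  spacing <- sqrt(4 * pi / n)
  # dense polar grid on a cap of radius 2*spacing around the coarse optimum
  Q <- qr.Q(qr(cbind(best_dir, diag(3)[, 1:2])))
  e2 <- Q[, 2]; e3 <- Q[, 3]
  grid2 <- expand.grid(rho = seq(0, 2 * spacing, length.out = 60)[-1],
                       az = seq(0, 2 * pi, length.out = 121)[-1])
  cap <- rbind(best_dir,
               outer(cos(grid2$rho), best_dir) +
                 outer(sin(grid2$rho) * cos(grid2$az), e2) +
                 outer(sin(grid2$rho) * sin(grid2$az), e3))
  vals2 <- eval_dirs(cap)
  2 * min(min(vals), min(vals2)) * 180 / pi
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rigid_move <- function(xyz, axis = c(1, 2, 3), angle = 0.63,
                       shift = c(1, -2, 0.5)) {
  R <- rotation_matrix(axis, angle)
  sweep(xyz %*% t(R), 2, shift, `+`)
}

ref_map24 <- function(ref = reference_geometry()) {
  new_macrocycle_map(ref$n_idx, ref$ca_idx, ref$cb_idx, ref$cm_idx)
}

mode_names <- c("sad", "ruf", "dom", "wav_x", "wav_y", "pro")
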