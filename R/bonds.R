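#' Distance-based bond perception
#'
#' Two atoms i, j are bonded iff their distance satisfies
#' `d_ij <= scale * (r_cov(i) + r_cov(j))` with the packaged covalent-radius
#' table, and `d_ij > min_dist` (guards against duplicate atoms). Bond orders
#' are then assigned by a simple valence heuristic: all bonds start at order
#' 1 and, for C/N atoms with remaining valence (C: 4, N: 3), the shortest
#' eligible bond between two unsaturated atoms is promoted to a double bond,
#' repeating until no promotion is possible. Downstream analyses use only
#' connectivity (a double bond counts as one connection), so the heuristic is
#' cosmetic; it is deterministic for a fixed input.
#'
#' @param s A `porph_structure`.
#' @param scale Cutoff scale applied to the radius sum (default 1.15).
#' @param min_dist Minimum distance for a bond (default 0.4 A).
#' @param assign_orders Run the valence heuristic? Default TRUE.
#' @return The structure with its `bonds` table replaced.
#' @export
perceive_bonds <- function(s, scale = 1.15, min_dist = 0.4,
                           assign_orders = TRUE) {
  xyz <- coords(s)
  n <- nrow(xyz)
  r <- covalent_radius(s$atoms$element)
  d <- as.matrix(stats::dist(xyz))
  cutoff <- outer(r, r, `+`) * scale
  adj <- d <= cutoff & d > min_dist
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  bonds <- tibble::tibble(i = idx[, 1], j = idx[, 2], order = 1L)
  if (assign_orders && nrow(bonds) > 0) {
    bonds <- assign_bond_orders(s$atoms$element, bonds, d)
  }
  s$bonds <- bonds
  s
}

assign_bond_orders <- function(elements, bonds, dmat) {
  target <- c(C = 4L, N = 3L)[elements]
  deg <- tabulate(c(bonds$i, bonds$j), nbins = length(elements))
  free <- target - deg          # NA for non-C/N
  free[is.na(free)] <- 0L
  blen <- dmat[cbind(bonds$i, bonds$j)]
  ord <- order(blen)
  for (k in ord) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (free[i] > 0L && free[j] > 0L) {
      bonds$order[k] <- 2L
      free[i] <- free[i] - 1L
      free[j] <- free[j] - 1L
    }
  }
  bonds
}

#' Electron count of a component
#'
#' Sum of atomic numbers minus the sum of formal charges over the atoms of a
#' component. Formal charges default to zero when a source file does not
#' declare them, so parity then depends only on elemental composition.
#'
#' @param s A `porph_structure`.
#' @param atoms Integer vector of atom indices (default: all atoms).
#' @return Integer electron count.
#' @export
count_electrons <- function(s, atoms = seq_len(nrow(s$atoms))) {
  sum(atomic_number(s$atoms$element[atoms])) - sum(s$atoms$charge[atoms])
}
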