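#' Element property table
#'
#' Atomic numbers, single-bond covalent radii (Cordero-type values, in
#' Angstrom; low-spin values for Mn/Fe/Co, as appropriate for most
#' metalloporphyrins), Bondi-type van der Waals radii where tabulated, and a
#' metal/non-metal flag. This table backs bond perception
#' ([perceive_bonds()]), electron counting ([count_electrons()]), the
#' metal-radius descriptor ([metal_radius()]) and the vdW cones of
#' [cone_angle()].
#'
#' @return A tibble with columns `element`, `z`, `r_cov`, `r_vdw`, `metal`.
#' @export
element_table <- function() {
  el <- function(element, z, r_cov, r_vdw, metal) {
    tibble::tibble(element = element, z = z, r_cov = r_cov,
                   r_vdw = r_vdw, metal = metal)
  }
  dplyr::bind_rows(
    el("H",  1,  0.31, 1.20, FALSE),
    el("He", 2,  0.28, 1.40, FALSE),
    el("Li", 3,  1.28, 1.82, TRUE),
    el("Be", 4,  0.96, NA,   TRUE),
    el("B",  5,  0.84, 1.92, FALSE),
    el("C",  6,  0.76, 1.70, FALSE),
    el("N",  7,  0.71, 1.55, FALSE),
    el("O",  8,  0.66, 1.52, FALSE),
    el("F",  9,  0.57, 1.47, FALSE),
    el("Ne", 10, 0.58, 1.54, FALSE),
    el("Na", 11, 1.66, 2.27, TRUE),
    el("Mg", 12, 1.41, 1.73, TRUE),
    el("Al", 13, 1.21, 1.84, TRUE),
    el("Si", 14, 1.11, 2.10, FALSE),
    el("P",  15, 1.07, 1.80, FALSE),
    el("S",  16, 1.05, 1.80, FALSE),
    el("Cl", 17, 1.02, 1.75, FALSE),
    el("Ar", 18, 1.06, 1.88, FALSE),
    el("K",  19, 2.03, 2.75, TRUE),
    el("Ca", 20, 1.76, 2.31, TRUE),
    el("Sc", 21, 1.70, NA,   TRUE),
    el("Ti", 22, 1.60, NA,   TRUE),
    el("V",  23, 1.53, NA,   TRUE),
    el("Cr", 24, 1.39, NA,   TRUE),
    el("Mn", 25, 1.39, NA,   TRUE),
    el("Fe", 26, 1.32, NA,   TRUE),
    el("Co", 27, 1.26, NA,   TRUE),
    el("Ni", 28, 1.24, 1.63, TRUE),
    el("Cu", 29, 1.32, 1.40, TRUE),
    el("Zn", 30, 1.22, 1.39, TRUE),
    el("Ga", 31, 1.22, 1.87, TRUE),
    el("Ge", 32, 1.20, 2.11, FALSE),
    el("As", 33, 1.19, 1.85, FALSE),
    el("Se", 34, 1.20, 1.90, FALSE),
    el("Br", 35, 1.20, 1.85, FALSE),
    el("Kr", 36, 1.16, 2.02, FALSE),
    el("Rb", 37, 2.20, NA,   TRUE),
    el("Sr", 38, 1.95, NA,   TRUE),
    el("Y",  39, 1.90, NA,   TRUE),
    el("Zr", 40, 1.75, NA,   TRUE),
    el("Nb", 41, 1.64, NA,   TRUE),
    el("Mo", 42, 1.54, NA,   TRUE),
    el("Tc", 43, 1.47, NA,   TRUE),
    el("Ru", 44, 1.46, NA,   TRUE),
    el("Rh", 45, 1.42, NA,   TRUE),
    el("Pd", 46, 1.39, 1.63, TRUE),
    el("Ag", 47, 1.45, 1.72, TRUE),
    el("Cd", 48, 1.44, 1.58, TRUE),
    el("In", 49, 1.42, 1.93, TRUE),
    el("Sn", 50, 1.39, 2.17, TRUE),
    el("Sb", 51, 1.39, 2.06, TRUE),
    el("Te", 52, 1.38, 2.06, FALSE),
    el("I",  53, 1.39, 1.98, FALSE),
    el("Xe", 54, 1.40, 2.16, FALSE),
    el("Cs", 55, 2.44, NA,   TRUE),
    el("Ba", 56, 2.15, NA,   TRUE),
    el("La", 57, 2.07, NA,   TRUE),
    el("Ce", 58, 2.04, NA,   TRUE),
    el("Hf", 72, 1.75, NA,   TRUE),
    el("Ta", 73, 1.70, NA,   TRUE),
    el("W",  74, 1.62, NA,   TRUE),
    el("Re", 75, 1.51, NA,   TRUE),
    el("Os", 76, 1.44, NA,   TRUE),
    el("Ir", 77, 1.41, NA,   TRUE),
    el("Pt", 78, 1.36, 1.75, TRUE),
    el("Au", 79, 1.36, 1.66, TRUE),
    el("Hg", 80, 1.32, 1.55, TRUE),
    el("Tl", 81, 1.45, 1.96, TRUE),
    el("Pb", 82, 1.46, 2.02, TRUE),
    el("Bi", 83, 1.48, 2.07, TRUE)
  )
}

.element_env <- new.env(parent = emptyenv())

element_lookup <- function() {
  if (is.null(.element_env$tab)) {
    tab <- element_table()
    .element_env$tab <- tab
    .element_env$idx <- stats::setNames(seq_len(nrow(tab)), tab$element)
  }
  .element_env
}

element_field <- function(elements, field) {
  env <- element_lookup()
  i <- env$idx[elements]
  if (anyNA(i)) {
    bad <- unique(elements[is.na(i)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  env$tab[[field]][i]
}

#' Atomic number of one or more element symbols
#' @param elements character vector of element symbols.
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(elements) element_field(elements, "z")

#' Covalent radius (Angstrom)
#' @inheritParams atomic_number
#' @return Numeric vector of covalent radii.
#' @export
covalent_radius <- function(elements) element_field(elements, "r_cov")

#' Van der Waals radius (Angstrom)
#'
#' Bondi-type values; elements without a tabulated value fall back to 2.0 A
#' (a conservative metal-sized sphere).
#' @inheritParams atomic_number
#' @return Numeric vector of vdW radii.
#' @export
vdw_radius <- function(elements) {
  r <- element_field(elements, "r_vdw")
  r[is.na(r)] <- 2.0
  r
}

#' Is an element a metal?
#' @inheritParams atomic_number
#' @return Logical vector.
#' @export
is_metal_element <- function(elements) element_field(elements, "metal")
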