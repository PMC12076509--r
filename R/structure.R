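#' Molecular structure container
#'
#' A `porph_structure` is a light S3 container for one crystallographic or
#' synthetic molecular model: an atom table (element symbols and Cartesian
#' coordinates in Angstrom, plus optional per-atom formal charge, vdW-radius
#' override and molecule id) and a bond table (index pairs with an integer
#' bond order). Connected components are always derived from the bond graph,
#' never stored.
#'
#' @param atoms A data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (formal charge, default 0), `vdw` (per-atom vdW
#'   radius override, default NA = use [vdw_radius()]), `mol_id` (integer
#'   molecule label from the source file, default NA).
#' @param bonds A data frame with columns `i`, `j` (1-based atom indices) and
#'   optionally `order` (integer, default 1), or NULL for no bonds.
#' @param source_id Free-text provenance label.
#' @return A `porph_structure` object.
#' @export
new_structure <- function(atoms, bonds = NULL, source_id = "") {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  atoms$charge[is.na(atoms$charge)] <- 0
  if (!"vdw" %in% names(atoms)) atoms$vdw <- NA_real_
  if (!"mol_id" %in% names(atoms)) atoms$mol_id <- NA_integer_
  atoms <- atoms[, c("element", "x", "y", "z", "charge", "vdw", "mol_id")]
  if (nrow(atoms) == 0L) stop("empty structure: no atoms", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (is.null(bonds)) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- tibble::as_tibble(bonds)
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    bonds <- bonds[, c("i", "j", "order")]
    if (nrow(bonds) > 0) {
      if (any(bonds$i < 1 | bonds$i > nrow(atoms) |
              bonds$j < 1 | bonds$j > nrow(atoms))) {
        stop("bond index out of range", call. = FALSE)
      }
      swap <- bonds$i > bonds$j
      tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
      bonds <- dplyr::distinct(bonds, .data$i, .data$j, .keep_all = TRUE)
    }
  }
  structure(list(atoms = atoms, bonds = bonds, source_id = source_id),
            class = "porph_structure")
}

#' @export
print.porph_structure <- function(x, ...) {
  comp <- structure_components(x)
  cat(sprintf("<porph_structure> %s: %d atoms, %d bonds, %d component(s)\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds), length(comp)))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param s A `porph_structure`.
#' @return An n x 3 numeric matrix.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

set_coords <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

bond_graph <- function(s) {
  igraph::graph_from_data_frame(
    d = if (nrow(s$bonds)) s$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(s$atoms))))
}

#' Connected components of the bond graph
#' @param s A `porph_structure`.
#' @return A list of integer vectors of atom indices, largest first.
#' @export
structure_components <- function(s) {
  g <- bond_graph(s)
  m <- igraph::components(g)$membership
  comp <- split(seq_len(nrow(s$atoms)), m)
  comp <- unname(comp[order(-vapply(comp, length, 1L),
                            vapply(comp, min, 1L))])
  comp
}

#' Parse a structure file
#'
#' Reads XYZ (verbatim Cartesian coordinates) or small-molecule CIF text.
#' CIF models are symmetry-expanded to the complete bonded molecule(s) around
#' one asymmetric unit; see [parse_cif()].
#'
#' @param text File content as a single string or character vector of lines,
#'   or a file path.
#' @param format `"xyz"` or `"cif"`.
#' @param source_id Provenance label; defaults to the file name when `text`
#'   is a path.
#' @param ... Passed on to [parse_cif()].
#' @return A `porph_structure` (for CIF, bonds are already perceived).
#' @export
parse_structure <- function(text, format = c("xyz", "cif"), source_id = NULL,
                            ...) {
  format <- match.arg(format)
  lines <- as_text_lines(text)
  if (is.null(source_id)) {
    source_id <- if (length(text) == 1 && file.exists(text)) basename(text) else ""
  }
  switch(format,
         xyz = parse_xyz(lines, source_id = source_id),
         cif = parse_cif(lines, source_id = source_id, ...))
}

as_text_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

parse_xyz <- function(lines, source_id = "") {
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) <= 2]
  if (!length(lines)) stop("unparseable XYZ: no input", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("unparseable XYZ: first line is not an atom count", call. = FALSE)
  if (n == 0L) stop("empty structure: XYZ declares 0 atoms", call. = FALSE)
  if (length(lines) < 3) stop("unparseable XYZ: fewer atom lines than declared", call. = FALSE)
  body <- lines[seq(3, length.out = n)]
  if (length(body) < n || anyNA(body)) {
    stop("unparseable XYZ: fewer atom lines than declared", call. = FALSE)
  }
  parts <- strsplit(trimws(body), "\\s+")
  bad <- vapply(parts, length, 1L) < 4
  if (any(bad)) stop("unparseable XYZ: malformed atom line", call. = FALSE)
  atoms <- tibble::tibble(
    element = vapply(parts, `[[`, "", 1),
    x = as.numeric(vapply(parts, `[[`, "", 2)),
    y = as.numeric(vapply(parts, `[[`, "", 3)),
    z = as.numeric(vapply(parts, `[[`, "", 4)))
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    stop("unparseable XYZ: non-numeric coordinate", call. = FALSE)
  }
  new_structure(atoms, source_id = source_id)
}

#' Write a structure to XYZ format
#'
#' @param s A `porph_structure`.
#' @param path Output file, or NULL to return the lines invisibly.
#' @param comment Second-line comment; defaults to the structure's source id.
#' @return The character vector of lines, invisibly.
#' @export
write_xyz <- function(s, path = NULL, comment = NULL) {
  if (is.null(comment)) comment <- s$source_id
  lines <- c(
    sprintf("%d", nrow(s$atoms)),
    comment,
    sprintf("%-3s %16.8f %16.8f %16.8f",
            s$atoms$element, s$atoms$x, s$atoms$y, s$atoms$z))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
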