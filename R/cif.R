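#' Read a small-molecule CIF into a crystal model
#'
#' Minimal core-dictionary reader: the first `data_` block's cell
#' parameters, symmetry operations (`_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`; identity assumed when absent) and the
#' `_atom_site` loop with fractional coordinates, occupancies and disorder
#' assembly/group tags. Charges are not read and default to neutral.
#'
#' @param text CIF content (string, lines, or file path).
#' @param source_id Provenance label.
#' @return A `porph_cif_model`: list with `cell` (named lengths/angles),
#'   `symops` (list of 3x4 matrices), `sites` (tibble with `label`,
#'   `element`, `fx`, `fy`, `fz`, `occ`, `assembly`, `group`), `source_id`.
#' @export
read_cif_model <- function(text, source_id = "") {
  lines <- as_text_lines(text)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("unparseable CIF: empty input", call. = FALSE)

  items <- list()
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^loop_", ln)) {
      i <- i + 1L
      tags <- character()
      while (i <= n && grepl("^_", lines[i])) {
        tags <- c(tags, strsplit(lines[i], "\\s+")[[1]][1])
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && !grepl("^(_|loop_|data_)", lines[i])) {
        rows <- c(rows, list(cif_tokens(lines[i])))
        i <- i + 1L
      }
      vals <- unlist(rows, use.names = FALSE)
      if (length(tags) && length(vals) %% length(tags) == 0 && length(vals)) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        colnames(m) <- tolower(tags)
        loops <- c(loops, list(m))
      }
    } else if (grepl("^_", ln)) {
      toks <- cif_tokens(ln)
      key <- tolower(toks[1])
      if (length(toks) >= 2) {
        items[[key]] <- toks[2]
      } else if (i + 1L <= n && grepl("^;", lines[i + 1L])) {
        # multi-line text field: skip
        i <- i + 1L
        repeat {
          i <- i + 1L
          if (i > n || grepl("^;", lines[i])) break
        }
      }
      i <- i + 1L
    } else {
      i <- i + 1L  # data_ header or stray token
    }
  }

  num <- function(key, default = NA_real_) {
    v <- items[[key]]
    if (is.null(v)) return(default)
    as.numeric(sub("\\(.*\\)", "", v))
  }
  cell <- c(a = num("_cell_length_a"), b = num("_cell_length_b"),
            c = num("_cell_length_c"),
            alpha = num("_cell_angle_alpha", 90),
            beta  = num("_cell_angle_beta", 90),
            gamma = num("_cell_angle_gamma", 90))
  if (anyNA(cell[1:3])) stop("unparseable CIF: missing cell lengths", call. = FALSE)

  find_loop <- function(tag) {
    for (m in loops) if (tag %in% colnames(m)) return(m)
    NULL
  }
  symloop <- find_loop("_symmetry_equiv_pos_as_xyz")
  symcol <- "_symmetry_equiv_pos_as_xyz"
  if (is.null(symloop)) {
    symloop <- find_loop("_space_group_symop_operation_xyz")
    symcol <- "_space_group_symop_operation_xyz"
  }
  symops <- if (is.null(symloop)) list(cbind(diag(3), 0)) else
    lapply(symloop[, symcol], parse_symop)

  atloop <- find_loop("_atom_site_fract_x")
  if (is.null(atloop)) stop("unparseable CIF: no _atom_site loop", call. = FALSE)
  col <- function(tag, default = NA_character_) {
    if (tag %in% colnames(atloop)) atloop[, tag] else
      rep(default, nrow(atloop))
  }
  numcol <- function(tag, default = NA_real_) {
    v <- col(tag)
    out <- suppressWarnings(as.numeric(sub("\\(.*\\)", "", v)))
    out[is.na(out)] <- default
    out
  }
  label <- col("_atom_site_label")
  elem <- col("_atom_site_type_symbol")
  if (all(is.na(elem))) elem <- gsub("[^A-Za-z].*$", "", label)
  elem <- normalize_element(elem)
  sites <- tibble::tibble(
    label = label,
    element = elem,
    fx = numcol("_atom_site_fract_x"),
    fy = numcol("_atom_site_fract_y"),
    fz = numcol("_atom_site_fract_z"),
    occ = numcol("_atom_site_occupancy", 1),
    assembly = col("_atom_site_disorder_assembly"),
    group = col("_atom_site_disorder_group"))
  if (anyNA(sites$fx) || anyNA(sites$fy) || anyNA(sites$fz)) {
    stop("unparseable CIF: non-numeric fractional coordinate", call. = FALSE)
  }
  if (nrow(sites) == 0L) stop("empty structure: CIF has no atom sites", call. = FALSE)
  structure(list(cell = cell, symops = symops, sites = sites,
                 source_id = source_id),
            class = "porph_cif_model")
}

cif_tokens <- function(line) {
  out <- character()
  rest <- trimws(line)
  while (nzchar(rest)) {
    if (startsWith(rest, "'") || startsWith(rest, '"')) {
      q <- substr(rest, 1, 1)
      end <- regexpr(paste0(q, "(\\s|$)"), substr(rest, 2, nchar(rest)))
      if (end < 0) end <- nchar(rest)
      out <- c(out, substr(rest, 2, end))
      rest <- trimws(substr(rest, end + 2, nchar(rest)))
    } else {
      sp <- regexpr("\\s", rest)
      if (sp < 0) { out <- c(out, rest); break }
      out <- c(out, substr(rest, 1, sp - 1))
      rest <- trimws(substr(rest, sp, nchar(rest)))
    }
  }
  out
}

normalize_element <- function(x) {
  x <- gsub("[^A-Za-z]", "", x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

# "x,-y+1/2,z" -> 3x4 [R | t] acting on fractional coordinates
parse_symop <- function(op) {
  op <- tolower(gsub("\\s", "", op))
  parts <- strsplit(op, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("unparseable CIF symmetry op: ", op, call. = FALSE)
  if (!all(grepl("^[xyz0-9+/.-]+$", parts))) {
    stop("unparseable CIF symmetry op: ", op, call. = FALSE)
  }
  evalc <- function(expr, x, y, z) {
    eval(parse(text = expr)[[1]], list(x = x, y = y, z = z))
  }
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (k in 1:3) {
    t[k] <- evalc(parts[k], 0, 0, 0)
    R[k, 1] <- evalc(parts[k], 1, 0, 0) - t[k]
    R[k, 2] <- evalc(parts[k], 0, 1, 0) - t[k]
    R[k, 3] <- evalc(parts[k], 0, 0, 1) - t[k]
  }
  cbind(R, t)
}

cell_matrix <- function(cell) {
  a <- cell["a"]; b <- cell["b"]; cc <- cell["c"]
  al <- cell["alpha"] * pi / 180
  be <- cell["beta"] * pi / 180
  ga <- cell["gamma"] * pi / 180
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(ga), b * sin(ga), 0)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cc^2 - cx^2 - cy^2, 0))
  unname(rbind(v1, v2, c(cx, cy, cz)))  # rows = cell vectors
}

#' Resolve disordered sites to the dominant alternative
#'
#' For every disorder assembly, the alternative group with the strictly
#' highest mean occupancy is kept and the others dropped. A tie at the
#' maximum (within `tol`) means there is no dominant position and the whole
#' structure is rejected: the return value is then a `porph_rejection`
#' object, not an error.
#'
#' @param model A `porph_cif_model`.
#' @param tol Occupancy tolerance for calling a tie (default 1e-6).
#' @return The model with disordered alternatives resolved, or a
#'   `porph_rejection` (test with [is_rejected()]).
#' @export
select_dominant_disorder <- function(model, tol = 1e-6) {
  stopifnot(inherits(model, "porph_cif_model"))
  s <- model$sites
  grp <- s$group
  grp[grp %in% c(".", "?", "")] <- NA
  disordered <- !is.na(grp) & grp != "0"
  if (!any(disordered)) return(model)
  asm <- s$assembly
  asm[asm %in% c(".", "?", "")] <- NA
  asm[is.na(asm)] <- "(none)"
  keep <- rep(TRUE, nrow(s))
  for (a in unique(asm[disordered])) {
    in_a <- disordered & asm == a
    occ_by_group <- tapply(s$occ[in_a], grp[in_a], mean)
    best <- max(occ_by_group)
    winners <- names(occ_by_group)[occ_by_group > best - tol]
    if (length(winners) > 1) {
      return(structure(
        list(source_id = model$source_id,
             reason = sprintf("no dominant occupancy in disorder assembly '%s'", a)),
        class = "porph_rejection"))
    }
    keep[in_a] <- grp[in_a] == winners
  }
  model$sites <- s[keep, ]
  model
}

#' Was a structure rejected?
#' @param x Any object.
#' @return TRUE for `porph_rejection` objects.
#' @export
is_rejected <- function(x) inherits(x, "porph_rejection")

#' @export
print.porph_rejection <- function(x, ...) {
  cat(sprintf("<rejected> %s: %s\n", x$source_id, x$reason))
  invisible(x)
}

#' Expand a CIF model to the bonded molecules around one asymmetric unit
#'
#' Applies all symmetry operations, merges coincident images into unique
#' crystallographic sites, and grows bonded molecules outward from the home
#' unit cell through neighboring lattice translations, so that each molecule
#' is chemically complete. Each site is used in exactly one molecule.
#'
#' @param model A `porph_cif_model` (disorder already resolved).
#' @param scale Bond-perception cutoff scale (see [perceive_bonds()]).
#' @param max_shift Largest |lattice translation| explored per axis.
#' @return A `porph_structure` with bonds perceived and `mol_id` set per
#'   assembled molecule.
#' @export
expand_cif_model <- function(model, scale = 1.15, max_shift = 2L) {
  stopifnot(inherits(model, "porph_cif_model"))
  M <- cell_matrix(model$cell)   # rows = cell vectors; cart = frac %*% M
  s <- model$sites
  frac0 <- as.matrix(s[, c("fx", "fy", "fz")])

  # unique crystallographic sites from all symmetry images
  uf <- matrix(numeric(0), 0, 3); uel <- character(0); ulab <- character(0)
  for (op in model$symops) {
    img <- t(op[, 1:3] %*% t(frac0) + op[, 4])
    img <- img - floor(img)
    for (k in seq_len(nrow(img))) {
      if (nrow(uf)) {
        d <- sweep(uf, 2, img[k, ])
        d <- d - round(d)           # periodic difference
        dc <- sqrt(rowSums((d %*% M)^2))
        if (any(dc < 0.3 & uel == s$element[k])) next
      }
      uf <- rbind(uf, img[k, ]); uel <- c(uel, s$element[k])
      ulab <- c(ulab, s$label[k])
    }
  }

  shifts <- as.matrix(expand.grid(-max_shift:max_shift, -max_shift:max_shift,
                                  -max_shift:max_shift))
  rcov <- covalent_radius(uel)
  nsite <- nrow(uf)
  used <- rep(FALSE, nsite)

  atoms <- list(); bonds_i <- integer(); bonds_j <- integer()
  mol <- 0L; atom_count <- 0L
  for (seed in seq_len(nsite)) {
    if (used[seed]) next
    mol <- mol + 1L
    # BFS over (site, shift) nodes
    node_site <- seed; node_shift <- matrix(0, 1, 3)
    used[seed] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      new_frontier <- integer()
      for (f in frontier) {
        pf <- uf[node_site[f], ] + node_shift[f, ]
        pc <- as.numeric(pf %*% M)
        cand_sites <- which(!used)
        if (!length(cand_sites)) next
        for (cs in cand_sites) {
          if (used[cs]) next
          # nearest images of cs around pf
          rel <- sweep(shifts, 2, uf[cs, ] + 0, `+`)  # cs frac + shift
          d <- sweep(rel, 2, pf)
          dc <- sqrt(rowSums((d %*% M)^2))
          cut <- (rcov[node_site[f]] + rcov[cs]) * scale
          hit <- which(dc <= cut & dc > 0.4)
          if (length(hit)) {
            sh <- shifts[hit[which.min(dc[hit])], ]
            used[cs] <- TRUE
            node_site <- c(node_site, cs)
            node_shift <- rbind(node_shift, sh)
            new_frontier <- c(new_frontier, length(node_site))
          }
        }
      }
      frontier <- new_frontier
    }
    pf <- uf[node_site, , drop = FALSE] + node_shift
    pc <- pf %*% M
    atoms[[mol]] <- tibble::tibble(
      element = uel[node_site],
      x = pc[, 1], y = pc[, 2], z = pc[, 3],
      mol_id = mol)
    atom_count <- atom_count + length(node_site)
  }
  at <- dplyr::bind_rows(atoms)
  out <- new_structure(at, source_id = model$source_id)
  perceive_bonds(out, scale = scale)
}

parse_cif <- function(lines, source_id = "", scale = 1.15,
                      resolve_disorder = TRUE) {
  model <- read_cif_model(lines, source_id = source_id)
  if (resolve_disorder) {
    model <- select_dominant_disorder(model)
    if (is_rejected(model)) return(model)
  }
  expand_cif_model(model, scale = scale)
}
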