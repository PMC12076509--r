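#' Macrocycle map constructor
#'
#' Holds the canonical role assignment of the 24 porphyrin macrocycle atoms.
#' `n_idx`, `ca_idx`, `cb_idx`, `cm_idx` are atom indices in walk order:
#' pyrrole p contributes N\[p\], Calpha entering/leaving (`ca_idx[2p-1]`,
#' `ca_idx[2p]`), Cbeta entering/leaving, and meso p bridges pyrroles p and
#' p+1.
#'
#' @param n_idx,ca_idx,cb_idx,cm_idx Integer index vectors (4, 8, 8, 4).
#' @param metal_idx Central atom index or NA.
#' @param axial_idx Indices of ligand atoms bonded to the metal (excluding
#'   the four N).
#' @param substituents Tibble with columns `site`, `position`, `key`,
#'   `atoms` (list of atom-index vectors).
#' @return A `porph_macrocycle_map`.
#' @export
new_macrocycle_map <- function(n_idx, ca_idx, cb_idx, cm_idx,
                               metal_idx = NA_integer_,
                               axial_idx = integer(),
                               substituents = NULL) {
  stopifnot(length(n_idx) == 4, length(ca_idx) == 8,
            length(cb_idx) == 8, length(cm_idx) == 4)
  idx24 <- c(n_idx, ca_idx, cb_idx, cm_idx)
  stopifnot(!anyDuplicated(idx24))
  if (is.null(substituents)) {
    substituents <- tibble::tibble(site = integer(), position = character(),
                                   key = character(), atoms = list())
  }
  structure(list(n_idx = as.integer(n_idx), ca_idx = as.integer(ca_idx),
                 cb_idx = as.integer(cb_idx), cm_idx = as.integer(cm_idx),
                 metal_idx = as.integer(metal_idx),
                 axial_idx = as.integer(axial_idx),
                 substituents = substituents),
            class = "porph_macrocycle_map")
}

#' Canonical 24-atom index vector of a map
#' @param map A `porph_macrocycle_map`.
#' @return Integer vector (N1-4, Ca1-8, Cb1-8, Cm1-4).
#' @export
macrocycle_order24 <- function(map) {
  c(map$n_idx, map$ca_idx, map$cb_idx, map$cm_idx)
}

#' @export
print.porph_macrocycle_map <- function(x, ...) {
  cat(sprintf("<macrocycle map> metal at %s, %d axial ligand(s), %d substituent record(s)\n",
              ifelse(is.na(x$metal_idx), "none", x$metal_idx),
              length(x$axial_idx), nrow(x$substituents)))
  invisible(x)
}

adjacency_list <- function(s) {
  n <- nrow(s$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(s$bonds))) {
    i <- s$bonds$i[k]; j <- s$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Detect the porphyrin macrocycle
#'
#' Pure graph substructure search (geometry-free, so distorted macrocycles
#' are found): four pyrrole rings (N + 2 Calpha + 2 Cbeta) bridged into a
#' 16-membered inner ring by four single-carbon meso bridges. The central
#' atom is any atom bonded to all four pyrrole N (no element whitelist).
#'
#' @param s A bonded `porph_structure`.
#' @return A list with `map` (a `porph_macrocycle_map`, canonicalized, or
#'   NULL if no macrocycle), and `n_macrocycles` (count of distinct
#'   macrocycles, for the monomer filter).
#' @export
find_porphyrin_macrocycle <- function(s) {
  el <- s$atoms$element
  adj <- adjacency_list(s)
  is_c <- el == "C"; is_n <- el == "N"

  # enumerate pyrrole rings
  pyrroles <- list()
  for (n0 in which(is_n)) {
    cns <- adj[[n0]][is_c[adj[[n0]]]]
    if (length(cns) < 2) next
    prs <- utils::combn(cns, 2)
    for (q in seq_len(ncol(prs))) {
      ca1 <- prs[1, q]; ca2 <- prs[2, q]
      cb1s <- setdiff(adj[[ca1]][is_c[adj[[ca1]]]], c(n0, ca2))
      cb2s <- setdiff(adj[[ca2]][is_c[adj[[ca2]]]], c(n0, ca1))
      for (cb1 in cb1s) for (cb2 in cb2s) {
        if (cb1 != cb2 && cb2 %in% adj[[cb1]]) {
          pyrroles <- c(pyrroles, list(c(n = n0, ca1 = ca1, ca2 = ca2,
                                         cb1 = cb1, cb2 = cb2)))
        }
      }
    }
  }
  # dedupe (same ring found with swapped alpha labels)
  if (length(pyrroles)) {
    keys <- vapply(pyrroles, function(p) paste(sort(p), collapse = "-"), "")
    pyrroles <- pyrroles[!duplicated(keys)]
  }
  np <- length(pyrroles)
  if (np < 4) return(list(map = NULL, n_macrocycles = 0L))

  ring_atoms <- lapply(pyrroles, function(p) sort(unname(p)))
  all_ring <- unique(unlist(ring_atoms))

  # meso bridges: carbon not in any pyrrole, bonded to alphas of 2 pyrroles
  bridges <- list()
  for (m in which(is_c)) {
    if (m %in% all_ring) next
    hits <- list()
    for (pi in seq_len(np)) {
      p <- pyrroles[[pi]]
      ca_hit <- intersect(adj[[m]], c(p["ca1"], p["ca2"]))
      if (length(ca_hit) == 1) hits[[length(hits) + 1]] <- c(pi, ca_hit)
    }
    if (length(hits) >= 2) {
      cmb <- utils::combn(length(hits), 2)
      for (q in seq_len(ncol(cmb))) {
        h1 <- hits[[cmb[1, q]]]; h2 <- hits[[cmb[2, q]]]
        if (h1[1] != h2[1]) {
          bridges <- c(bridges, list(list(m = m, p1 = h1[1], ca1 = h1[2],
                                          p2 = h2[1], ca2 = h2[2])))
        }
      }
    }
  }
  if (length(bridges) < 4) return(list(map = NULL, n_macrocycles = 0L))

  # find 4-cycles of pyrroles through distinct bridges, each pyrrole using
  # its two different alphas
  macros <- list()
  bkey <- function(b) paste(b$p1, b$p2, b$m)
  for (i1 in seq_along(bridges)) {
    b1 <- bridges[[i1]]
    for (i2 in seq_along(bridges)) {
      if (i2 == i1) next
      b2 <- orient_bridge(bridges[[i2]], b1$p2)
      if (is.null(b2) || b2$p2 == b1$p1) next
      if (b2$ca1 == b1$ca2) next  # must enter through the other alpha
      for (i3 in seq_along(bridges)) {
        if (i3 %in% c(i1, i2)) next
        b3 <- orient_bridge(bridges[[i3]], b2$p2)
        if (is.null(b3) || b3$p2 %in% c(b1$p1, b1$p2)) next
        if (b3$ca1 == b2$ca2) next
        for (i4 in seq_along(bridges)) {
          if (i4 %in% c(i1, i2, i3)) next
          b4 <- orient_bridge(bridges[[i4]], b3$p2)
          if (is.null(b4) || b4$p2 != b1$p1) next
          if (b4$ca1 == b3$ca2 || b4$ca2 == b1$ca1) next
          atoms24 <- sort(c(unlist(ring_atoms[c(b1$p1, b2$p1, b3$p1, b4$p1)]),
                            b1$m, b2$m, b3$m, b4$m))
          macros <- c(macros, list(list(bs = list(b1, b2, b3, b4),
                                        atoms = atoms24)))
        }
      }
    }
  }
  if (!length(macros)) return(list(map = NULL, n_macrocycles = 0L))
  akeys <- vapply(macros, function(m) paste(m$atoms, collapse = "-"), "")
  macros <- macros[!duplicated(akeys)]
  n_mac <- length(macros)

  # build the map from the first macrocycle (deterministic: ordered search)
  bs <- macros[[1]]$bs
  pyr_seq <- vapply(bs, function(b) as.integer(b$p1), 1L)
  n_idx <- ca_idx <- cb_idx <- integer(0)
  cm_idx <- vapply(bs, function(b) as.integer(b$m), 1L)
  for (k in 1:4) {
    p <- pyrroles[[pyr_seq[k]]]
    prev <- bs[[((k + 2) %% 4) + 1]]   # bridge entering pyrrole k
    ca_in <- prev$ca2
    ca_out <- bs[[k]]$ca1
    cb_in <- intersect(adj[[ca_in]], c(p["cb1"], p["cb2"]))[1]
    cb_out <- intersect(adj[[ca_out]], c(p["cb1"], p["cb2"]))[1]
    n_idx <- c(n_idx, unname(p["n"]))
    ca_idx <- c(ca_idx, ca_in, ca_out)
    cb_idx <- c(cb_idx, cb_in, cb_out)
  }

  metal_idx <- NA_integer_
  cand <- Reduce(intersect, adj[n_idx])
  cand <- setdiff(cand, c(n_idx, ca_idx, cb_idx, cm_idx))
  if (length(cand)) metal_idx <- cand[1]
  axial_idx <- if (!is.na(metal_idx)) {
    setdiff(adj[[metal_idx]], n_idx)
  } else integer()

  map <- new_macrocycle_map(n_idx, ca_idx, cb_idx, cm_idx, metal_idx,
                            axial_idx)
  map <- attach_substituents(s, map)
  map <- canonical_atom_ordering(map, s)
  list(map = map, n_macrocycles = n_mac)
}

orient_bridge <- function(b, from_p) {
  if (b$p1 == from_p) return(b)
  if (b$p2 == from_p) {
    return(list(m = b$m, p1 = b$p2, ca1 = b$ca2, p2 = b$p1, ca2 = b$ca1))
  }
  NULL
}

#' Classify substituents by attachment position
#'
#' Every connected set of non-macrocycle, non-metal atoms is traced to its
#' attachment site(s): Cbeta attachment is a beta substituent, Cmeso a meso
#' substituent, a direct metal bond an axial ligand. Attachment to Calpha or
#' N violates the curation assumptions and is flagged. A substituent with
#' more than one attachment bond is flagged multidentate.
#'
#' @param s A `porph_structure`.
#' @param map Its macrocycle map.
#' @return Tibble with `site`, `position`, `key` (canonical graph hash),
#'   `atoms`, `n_attach`, `flagged`.
#' @export
classify_substituents <- function(s, map) {
  core <- c(macrocycle_order24(map),
            if (!is.na(map$metal_idx)) map$metal_idx)
  n <- nrow(s$atoms)
  rest <- setdiff(seq_len(n), core)
  recs <- list()
  if (length(rest)) {
    sub <- igraph::induced_subgraph(bond_graph(s), rest)
    memb <- igraph::components(sub)$membership
    vids <- as.integer(igraph::V(sub)$name)
    for (cc in unique(memb)) {
      at <- sort(vids[memb == cc])
      att <- s$bonds[ (s$bonds$i %in% at & s$bonds$j %in% core) |
                      (s$bonds$j %in% at & s$bonds$i %in% core), ]
      sites <- ifelse(att$i %in% core, att$i, att$j)
      pos <- vapply(sites, function(x) {
        if (x %in% map$cb_idx) "beta"
        else if (x %in% map$cm_idx) "meso"
        else if (!is.na(map$metal_idx) && x == map$metal_idx) "axial"
        else "invalid"
      }, "")
      recs[[length(recs) + 1]] <- tibble::tibble(
        site = if (length(sites)) sites[1] else NA_integer_,
        position = if (length(pos)) pos[1] else "detached",
        key = substituent_key(s, at),
        atoms = list(at),
        n_attach = length(sites),
        flagged = any(pos == "invalid") || length(sites) != 1)
    }
  }
  if (!length(recs)) {
    return(tibble::tibble(site = integer(), position = character(),
                          key = character(), atoms = list(),
                          n_attach = integer(), flagged = logical()))
  }
  dplyr::bind_rows(recs)
}

attach_substituents <- function(s, map) {
  recs <- classify_substituents(s, map)
  map$substituents <- recs[, c("site", "position", "key", "atoms")]
  map
}

#' Canonical graph hash of a substituent
#'
#' Morgan-style iterative neighborhood refinement over the substituent's
#' induced subgraph, seeded with element symbols (plus any vdW override, so
#' steric probes of different bulk get different identities). Used as the
#' substituent identity for the unseen-substituent train/test split.
#'
#' @param s A `porph_structure`.
#' @param atoms Atom indices of the substituent.
#' @param iters Refinement rounds.
#' @return A single string.
#' @export
substituent_key <- function(s, atoms, iters = 5L) {
  lab <- s$atoms$element[atoms]
  vdw <- s$atoms$vdw[atoms]
  lab <- ifelse(is.na(vdw), lab, sprintf("%s[r=%.2f]", lab, vdw))
  pos <- match(seq_len(nrow(s$atoms)), atoms)  # global -> local
  bl <- s$bonds[s$bonds$i %in% atoms & s$bonds$j %in% atoms, ]
  adj <- vector("list", length(atoms))
  for (k in seq_len(nrow(bl))) {
    i <- pos[bl$i[k]]; j <- pos[bl$j[k]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (it in seq_len(iters)) {
    lab <- vapply(seq_along(atoms), function(i) {
      paste0(lab[i], "(", paste(sort(lab[adj[[i]]]), collapse = ","), ")")
    }, "")
    # compress to keep strings short
    lab <- as.character(match(lab, sort(unique(lab))))
  }
  paste0("S", length(atoms), "b", nrow(bl), ":",
         paste(sort(table(lab)), collapse = "."), ":",
         digest_chr(paste(sort(lab), collapse = "|")))
}

# tiny deterministic string hash (djb2), enough to separate identities
digest_chr <- function(x) {
  v <- utf8ToInt(x)
  h <- 5381
  for (c in v) h <- (h * 33 + c) %% 2147483647
  sprintf("%x", h)
}

#' Canonicalize the macrocycle atom ordering
#'
#' The same substitution pattern can be written in 8 symmetry-equivalent
#' walk orders (4 rotations x 2 walk directions). This relabels the map to
#' the image whose substituent-pattern encoding is lexicographically
#' smallest (ties broken by atom index), so that symmetrically equivalent
#' molecules produce identical descriptor layouts.
#'
#' @param map A `porph_macrocycle_map`.
#' @param s The structure (only needed to refresh substituent records).
#' @return The canonicalized map.
#' @export
canonical_atom_ordering <- function(map, s = NULL) {
  key_at_site <- local({
    k <- stats::setNames(map$substituents$key, map$substituents$site)
    function(site) {
      v <- k[as.character(site)]
      ifelse(is.na(v), "-", v)
    }
  })
  images <- macrocycle_images(map)
  enc <- vapply(images, function(im) {
    sites <- c(im$cm_idx, im$cb_idx)
    paste(key_at_site(sites), collapse = "|")
  }, "")
  tie <- vapply(images, function(im) {
    paste(sprintf("%06d", macrocycle_order24(im)), collapse = "")
  }, "")
  best <- order(enc, tie)[1]
  out <- images[[best]]
  out$metal_idx <- map$metal_idx
  out$axial_idx <- map$axial_idx
  out$substituents <- map$substituents
  class(out) <- "porph_macrocycle_map"
  out
}

# the 8 walk-order images (rotations x direction reversal)
macrocycle_images <- function(map) {
  images <- list()
  for (r in 0:3) {
    for (refl in c(FALSE, TRUE)) {
      n_idx <- integer(4); ca <- integer(8); cb <- integer(8); cm <- integer(4)
      for (p in 1:4) {
        if (!refl) {
          q <- ((p - 1 + r) %% 4) + 1
          n_idx[p] <- map$n_idx[q]
          ca[2 * p - 1] <- map$ca_idx[2 * q - 1]; ca[2 * p] <- map$ca_idx[2 * q]
          cb[2 * p - 1] <- map$cb_idx[2 * q - 1]; cb[2 * p] <- map$cb_idx[2 * q]
          cm[p] <- map$cm_idx[q]
        } else {
          q <- ((r - (p - 1)) %% 4) + 1
          n_idx[p] <- map$n_idx[q]
          ca[2 * p - 1] <- map$ca_idx[2 * q]; ca[2 * p] <- map$ca_idx[2 * q - 1]
          cb[2 * p - 1] <- map$cb_idx[2 * q]; cb[2 * p] <- map$cb_idx[2 * q - 1]
          cm[p] <- map$cm_idx[((q - 2) %% 4) + 1]
        }
      }
      im <- list(n_idx = n_idx, ca_idx = ca, cb_idx = cb, cm_idx = cm)
      images <- c(images, list(im))
    }
  }
  images
}

#' Enumerate the HOMA circuits of a macrocycle
#'
#' Returns the 16-bond inner circuit (4 N + 8 Calpha + 4 Cmeso -- the
#' aromatic pathway of metalated porphyrins) and the four 5-bond pyrrole
#' circuits.
#'
#' @param map A `porph_macrocycle_map`.
#' @return List of circuits: each a list with `name`, `type` ("inner" or
#'   "pyrrole"), `atoms` (ordered closed walk) and `bonds` (2-column index
#'   matrix).
#' @export
enumerate_circuits <- function(map) {
  walk_bonds <- function(atoms) {
    cbind(atoms, c(atoms[-1], atoms[1]))
  }
  # walk: N_p, Ca_out_p, Cm_p, Ca_in_{p+1}, N_{p+1}, ... (16 atoms)
  inner_atoms <- integer(0)
  for (p in 1:4) {
    pn <- (p %% 4) + 1
    inner_atoms <- c(inner_atoms, map$n_idx[p], map$ca_idx[2 * p],
                     map$cm_idx[p], map$ca_idx[2 * pn - 1])
  }
  circuits <- list(list(name = "inner", type = "inner",
                        atoms = inner_atoms, bonds = walk_bonds(inner_atoms)))
  for (p in 1:4) {
    at <- c(map$n_idx[p], map$ca_idx[2 * p - 1], map$cb_idx[2 * p - 1],
            map$cb_idx[2 * p], map$ca_idx[2 * p])
    circuits[[length(circuits) + 1]] <-
      list(name = paste0("pyrrole_", p), type = "pyrrole",
           atoms = at, bonds = walk_bonds(at))
  }
  circuits
}
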