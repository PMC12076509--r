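#' Names of the seven curation filters, in sequence
#' @return Character vector of length 7.
#' @export
filter_names <- function() {
  c("central_ion", "connected", "monomer", "saturation",
    "monodentate", "even_electrons", "counter_size")
}

#' Apply the seven structure-curation filters
#'
#' Evaluates, per structure: (1) a central atom bonded to all four pyrrole
#' N; (2) the porphyrin-bearing molecule is a single connected component
#' (evaluated through the source file's molecule labels when present;
#' structures without labels treat each component as its own molecule and
#' pass vacuously); (3) exactly one porphyrin macrocycle in the whole
#' structure; (4) every macrocycle C/N has exactly three connections, a
#' double bond counting as one connection; (5) every substituent attaches
#' through exactly one bond to the macrocycle or metal (no multidentate
#' ligands); (6) every component has an even electron count; (7) counter
#' components contain no metal atoms and have at most 20 atoms. Each filter
#' is a pure predicate; failures are verdicts, never exceptions.
#'
#' @param structures A `porph_structure` or list of them (bonds perceived).
#' @return A `porph_curation_report`: tibble with one row per structure,
#'   one logical column per filter, and `pass`; the attribute `survivors`
#'   holds the non-increasing count of structures surviving the filter
#'   sequence.
#' @export
apply_filters <- function(structures) {
  if (inherits(structures, "porph_structure")) structures <- list(structures)
  rows <- lapply(structures, filter_verdicts)
  rep <- dplyr::bind_rows(rows)
  rep$pass <- Reduce(`&`, rep[filter_names()])
  surv <- integer(7)
  alive <- rep(TRUE, nrow(rep))
  for (k in seq_along(filter_names())) {
    alive <- alive & rep[[filter_names()[k]]]
    surv[k] <- sum(alive)
  }
  attr(rep, "survivors") <- stats::setNames(surv, filter_names())
  class(rep) <- c("porph_curation_report", class(rep))
  rep
}

filter_verdicts <- function(s) {
  det <- find_porphyrin_macrocycle(s)
  map <- det$map
  comp <- structure_components(s)
  n_atoms <- nrow(s$atoms)

  if (!is.null(map)) {
    mac24 <- macrocycle_order24(map)
    main_comp_id <- which(vapply(comp, function(cc) any(mac24 %in% cc), TRUE))[1]
  } else {
    mac24 <- integer()
    main_comp_id <- which.max(vapply(comp, length, 1L))
  }
  main_atoms <- comp[[main_comp_id]]

  # molecule label of the main molecule (NA when the file carries none)
  mid <- if (length(mac24)) {
    m <- s$atoms$mol_id[mac24]; m <- m[!is.na(m)]
    if (length(m)) m[1] else NA_integer_
  } else NA_integer_

  f1 <- !is.null(map) && !is.na(map$metal_idx)

  f2 <- if (!is.na(mid)) {
    mol_atoms <- which(!is.na(s$atoms$mol_id) & s$atoms$mol_id == mid)
    all(mol_atoms %in% main_atoms)
  } else TRUE

  f3 <- det$n_macrocycles == 1L

  f4 <- if (length(mac24)) {
    deg <- tabulate(c(s$bonds$i, s$bonds$j), nbins = n_atoms)
    all(deg[mac24] == 3L)
  } else TRUE

  f5 <- if (!is.null(map)) {
    subs <- classify_substituents(s, map)
    attached <- subs$n_attach[subs$n_attach > 0L]  # detached sets are counters
    length(attached) == 0 || all(attached == 1L)
  } else TRUE

  f6 <- all(vapply(comp, function(cc) count_electrons(s, cc) %% 2L == 0L, TRUE))

  counters <- if (!is.na(mid)) {
    comp[vapply(comp, function(cc) {
      m <- s$atoms$mol_id[cc]
      !any(!is.na(m) & m == mid)
    }, TRUE)]
  } else {
    comp[-main_comp_id]
  }
  f7 <- all(vapply(counters, function(cc) {
    length(cc) <= 20L && !any(is_metal_element(s$atoms$element[cc]))
  }, TRUE))

  tibble::tibble(source_id = s$source_id,
                 central_ion = f1, connected = f2, monomer = f3,
                 saturation = f4, monodentate = f5,
                 even_electrons = f6, counter_size = f7)
}

#' Curate a set of structures
#'
#' Runs [apply_filters()] and returns both the report and the surviving
#' structures.
#'
#' @param structures List of bonded `porph_structure` objects.
#' @return List with `report` and `curated` (the passing structures).
#' @export
curate_structures <- function(structures) {
  if (inherits(structures, "porph_structure")) structures <- list(structures)
  rep <- apply_filters(structures)
  list(report = rep, curated = structures[rep$pass])
}
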