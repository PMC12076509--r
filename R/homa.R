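#' HOMA parameter set
#'
#' The harmonic-oscillator model of aromaticity scores a circuit of bonds as
#' `HOMA = 1 - EN - GEO`, with `EN = alpha * (R_opt - Rbar)^2` (penalty for
#' the mean bond length deviating from the aromatic optimum) and
#' `GEO = alpha / n * sum((Rbar - R_i)^2)` (penalty for bond alternation).
#' Heteroatom C-N bonds are first mapped onto the C-C length scale through
#' the Pauling bond-number relation (equal bond order = equal effective
#' length), so a single `R_opt`/`alpha` pair per circuit type applies.
#'
#' @param r_opt Named numeric: optimal (C-C scale) bond length per circuit
#'   type; a single unnamed value applies to every circuit. Default: the
#'   literature C-C optimum 1.388 Angstrom.
#' @param alpha Normalization, Angstrom^-2 (literature C-C value 257.7).
#' @param calibration Tag recording how the parameters were obtained
#'   ("literature", "reference_ropt" or "rescale").
#' @param ref_scores Reference-circuit raw HOMA per circuit type (only used
#'   by the "rescale" mechanism).
#' @return A `porph_homa_params` list.
#' @export
homa_params <- function(r_opt = c(default = 1.388), alpha = 257.7,
                        calibration = "literature", ref_scores = NULL) {
  if (is.null(names(r_opt))) names(r_opt) <- rep("default", length(r_opt))
  structure(list(r_opt = r_opt, alpha = alpha, calibration = calibration,
                 ref_scores = ref_scores, pauling = pauling_constants()),
            class = "porph_homa_params")
}

circuit_ropt <- function(params, type) {
  v <- params$r_opt[type]
  if (is.na(v)) v <- params$r_opt["default"]
  if (is.na(v)) v <- 1.388
  unname(v)
}

# effective (C-C scale) bond lengths of a circuit
effective_lengths <- function(circuit, xyz, elements, params) {
  b <- circuit$bonds
  if (is.null(b) || nrow(b) == 0) stop("empty circuit", call. = FALSE)
  if (max(b) > nrow(xyz)) stop("circuit bond outside geometry", call. = FALSE)
  d <- sqrt(rowSums((xyz[b[, 1], , drop = FALSE] -
                     xyz[b[, 2], , drop = FALSE])^2))
  cls <- paste0(pmin(elements[b[, 1]], elements[b[, 2]]),
                pmax(elements[b[, 1]], elements[b[, 2]]))
  is_cn <- cls == "CN"
  if (any(!cls %in% c("CC", "CN"))) {
    stop("circuit contains a bond class other than CC/CN: ",
         paste(unique(cls[!cls %in% c("CC", "CN")]), collapse = ","),
         call. = FALSE)
  }
  d[is_cn] <- cc_equivalent_of_cn(d[is_cn], params$pauling)
  d
}

#' HOMA, EN and GEO of one circuit
#'
#' @param circuit A circuit from [enumerate_circuits()] (bond indices refer
#'   to the structure's atoms).
#' @param geometry A `porph_structure` or an n x 3 coordinate matrix; a
#'   matrix needs `elements`.
#' @param params A `porph_homa_params`.
#' @param elements Element symbols when `geometry` is a bare matrix.
#' @return One-row tibble: `circuit`, `type`, `homa`, `en`, `geo`,
#'   `n_bonds`, `r_mean`. The identity `homa = 1 - en - geo` holds exactly.
#'   Scores are not clamped to \[0, 1\]; out-of-range values are reported
#'   as-is (with a warning), since clamping would mask calibration errors.
#' @export
homa <- function(circuit, geometry, params = homa_params(), elements = NULL) {
  if (inherits(geometry, "porph_structure")) {
    elements <- geometry$atoms$element
    xyz <- coords(geometry)
  } else {
    xyz <- geometry
    if (is.null(elements)) stop("elements required with a bare matrix", call. = FALSE)
  }
  d <- effective_lengths(circuit, xyz, elements, params)
  if (any(d <= 0)) stop("degenerate (zero-length) bond", call. = FALSE)
  n <- length(d)
  rbar <- mean(d)
  r_opt <- circuit_ropt(params, circuit$type)
  en <- params$alpha * (r_opt - rbar)^2
  geo <- params$alpha / n * sum((rbar - d)^2)
  h <- 1 - en - geo
  if (identical(params$calibration, "rescale") &&
      !is.null(params$ref_scores)) {
    h0 <- params$ref_scores[circuit$type]
    if (!is.na(h0)) {
      h <- h / unname(h0)
      # keep the decomposition identity by scaling EN/GEO proportionally
      tot <- en + geo
      if (tot > 0) {
        k <- (1 - h) / tot
        en <- en * k; geo <- geo * k
      }
    }
  }
  if (h < 0 || h > 1 + 1e-12) {
    rlang::warn(sprintf("HOMA outside [0,1] for circuit %s: %.4f",
                        circuit$name, h),
                .frequency = "once", .frequency_id = "homa_range")
  }
  circuit_name <- circuit$name; circuit_type <- circuit$type
  tibble::tibble(circuit = circuit_name, type = circuit_type,
                 homa = h, en = en, geo = geo, n_bonds = n, r_mean = rbar)
}

#' Score every circuit of a structure
#'
#' @param s A `porph_structure` (or coordinate matrix with `elements`).
#' @param map Its macrocycle map.
#' @param params HOMA parameters.
#' @param elements Optional element vector for matrix input.
#' @return Tibble with one row per circuit plus summary columns available
#'   via [homa_summary()].
#' @export
homa_all_circuits <- function(s, map, params = homa_params(), elements = NULL) {
  circuits <- enumerate_circuits(map)
  dplyr::bind_rows(lapply(circuits, homa, geometry = s, params = params,
                          elements = elements))
}

#' Wide per-structure HOMA summary
#'
#' @param scores Output of [homa_all_circuits()].
#' @return One-row tibble: `homa_inner`, `en_inner`, `geo_inner`,
#'   `homa_pyrrole_mean`, `en_pyrrole_mean`, `geo_pyrrole_mean`.
#' @export
homa_summary <- function(scores) {
  inner <- scores[scores$type == "inner", ]
  pyr <- scores[scores$type == "pyrrole", ]
  tibble::tibble(
    homa_inner = inner$homa[1], en_inner = inner$en[1],
    geo_inner = inner$geo[1],
    homa_pyrrole_mean = mean(pyr$homa), en_pyrrole_mean = mean(pyr$en),
    geo_pyrrole_mean = mean(pyr$geo))
}

#' Calibrate HOMA parameters on the planar reference porphine
#'
#' The calibration contract is that the planar, unsubstituted reference
#' scores HOMA = 1. Two mechanisms are provided. The default,
#' `"reference_ropt"`, sets `R_opt` per circuit type to that circuit's mean
#' effective bond length on the reference geometry, so the reference's EN
#' vanishes by construction (and, for the aromatic-equivalence inner
#' circuit whose effective lengths are all equal, GEO vanishes too and the
#' score is exactly 1). The alternative, `"rescale"`, keeps the literature
#' `R_opt` and divides every score by the reference's raw score for the
#' same circuit type. The mechanism is recorded in the params tag.
#'
#' @param reference Reference geometry (`reference_geometry()` by default).
#' @param mechanism `"reference_ropt"` or `"rescale"`.
#' @param alpha Normalization constant (default literature 257.7).
#' @return A calibrated `porph_homa_params`.
#' @export
calibrate <- function(reference = reference_geometry(),
                      mechanism = c("reference_ropt", "rescale"),
                      alpha = 257.7) {
  mechanism <- match.arg(mechanism)
  xyz <- reference$xyz
  if (any(!is.finite(xyz))) stop("degenerate reference geometry", call. = FALSE)
  elements <- ifelse(reference$role == "N", "N", "C")
  map <- new_macrocycle_map(reference$n_idx, reference$ca_idx,
                            reference$cb_idx, reference$cm_idx)
  circuits <- enumerate_circuits(map)
  base <- homa_params(alpha = alpha)
  lens <- lapply(circuits, effective_lengths, xyz = xyz,
                 elements = elements, params = base)
  if (any(unlist(lens) <= 0)) stop("degenerate reference geometry", call. = FALSE)
  types <- vapply(circuits, `[[`, "", "type")
  if (mechanism == "reference_ropt") {
    r_opt <- vapply(split(lens, types), function(l) mean(unlist(l)), 1)
    homa_params(r_opt = r_opt, alpha = alpha, calibration = "reference_ropt")
  } else {
    raw <- dplyr::bind_rows(lapply(circuits, homa, geometry = xyz,
                                   params = base, elements = elements))
    ref_scores <- vapply(split(raw$homa, raw$type), mean, 1)
    homa_params(alpha = alpha, calibration = "rescale",
                ref_scores = ref_scores)
  }
}
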