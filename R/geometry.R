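#' Poiseuille resistance of a vessel segment
#'
#' Computes the hydraulic resistance of a vessel segment from its length and
#' sampled lumen cross-sectional areas, assuming fully developed Poiseuille
#' flow through a tube whose effective area is the arithmetic mean of the
#' samples: `R = 8 * pi * mu * L / A_bar^2` in CGS units, converted to the
#' clinical unit mmHg.s/mL.
#'
#' @param lumen_areas Numeric vector of lumen cross-sectional areas (cm^2),
#'   typically 10--20 samples along the centerline.
#' @param length Segment length (cm).
#' @param viscosity Dynamic viscosity of blood (poise). The default 0.04
#'   matches a glycerine-water blood analog.
#' @return Resistance in mmHg.s/mL.
#' @export
#' @examples
#' poiseuille_resistance(pi, 10) # r = 1 cm tube, 10 cm long
poiseuille_resistance <- function(lumen_areas, length, viscosity = 0.04) {
  if (length < 0) stop("invalid geometry: negative segment length", call. = FALSE)
  if (any(!is.finite(lumen_areas)) || any(lumen_areas <= 0)) {
    stop("invalid geometry: lumen areas must all be positive", call. = FALSE)
  }
  if (!is.finite(viscosity) || viscosity <= 0) {
    stop("invalid geometry: viscosity must be positive", call. = FALSE)
  }
  a_bar <- mean(lumen_areas)
  r_cgs <- 8 * pi * viscosity * length / a_bar^2 # dyn.s/cm^5
  r_cgs / 1333.22                               # mmHg.s/mL
}

#' Split a resistance into three equal series sub-resistors
#'
#' Each named vessel segment is represented by three resistor sub-elements in
#' series; the split conserves the total resistance exactly.
#'
#' @param resistance Total segment resistance (mmHg.s/mL), non-negative.
#' @return Numeric vector of length 3 summing to `resistance`.
#' @export
split_into_series <- function(resistance) {
  if (!is.finite(resistance) || resistance < 0) {
    stop("resistance must be non-negative", call. = FALSE)
  }
  rep(resistance / 3, 3)
}

required_outlets <- c(
  "right_subclavian", "right_carotid", "left_carotid",
  "left_subclavian", "coronaries", "descending_aorta"
)

#' Read a vessel geometry description
#'
#' The geometry file is JSON: a list of segment records with fields `name`,
#' `parent` (name of the parent segment, or `"heart"` for the root), and
#' `length_cm` and `areas_cm2` (sampled lumen areas). Outlet segments carry
#' an `outlet` field naming the vascular bed they feed; the segment whose
#' distal end hosts the counterpulsation device may set `device_site: true`.
#'
#' @param path Path to a geometry JSON file.
#' @return A list of segment records.
#' @export
read_geometry <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Path to the synthetic aortic geometry shipped with the package
#'
#' A plausible adult aortic tree (ascending aorta in two segments so the
#' device has an insertion edge, arch, arch branches, coronary trunk,
#' descending aorta) with six outlets. The geometry is synthetic: it stands
#' in for a patient CT-derived model, and the absolute branch resistances it
#' implies are later dominated by the calibrated terminal beds.
#'
#' @return File path.
#' @export
hemopulse_geometry <- function() {
  system.file("extdata", "geometry_synthetic.json", package = "hemopulse",
              mustWork = TRUE)
}

#' Build the arterial network from a geometry description
#'
#' Computes per-segment Poiseuille resistances (split into three series
#' sub-resistors), assembles the tree topology rooted at the aortic valve,
#' and attaches one placeholder RCR Windkessel terminal per outlet. Terminal
#' values are starting points for [calibrate()].
#'
#' @param geometry A list of segment records (see [read_geometry()]) or a
#'   path to a geometry JSON file.
#' @param viscosity Blood viscosity in poise (default 0.04).
#' @return An object of class `cv_network`: a list with a `segments` tibble
#'   (one row per segment with resistances and node indices), a `terminals`
#'   tibble (one RCR row per outlet), node bookkeeping, and the device
#'   insertion node.
#' @export
build_network <- function(geometry, viscosity = 0.04) {
  if (is.character(geometry)) geometry <- read_geometry(geometry)
  if (!length(geometry)) stop("schema error: empty geometry", call. = FALSE)

  allowed <- c("name", "parent", "length_cm", "areas_cm2", "outlet", "device_site")
  for (rec in geometry) {
    for (f in c("name", "parent", "length_cm", "areas_cm2")) {
      if (is.null(rec[[f]])) {
        stop(sprintf("schema error: segment '%s' is missing field '%s'",
                     rec$name %||% "<unnamed>", f), call. = FALSE)
      }
    }
    extra <- setdiff(names(rec), allowed)
    if (length(extra)) {
      stop(sprintf("schema error: segment '%s' has unknown field '%s'",
                   rec$name, extra[[1]]), call. = FALSE)
    }
  }

  seg_names <- vapply(geometry, function(r) r$name, character(1))
  if (anyDuplicated(seg_names)) {
    stop("schema error: duplicated segment name", call. = FALSE)
  }
  parents <- vapply(geometry, function(r) r$parent, character(1))
  bad_parent <- setdiff(parents, c("heart", seg_names))
  if (length(bad_parent)) {
    stop(sprintf("schema error: unknown parent '%s'", bad_parent[[1]]),
         call. = FALSE)
  }
  if (!any(parents == "heart")) {
    stop("schema error: no root segment (parent 'heart')", call. = FALSE)
  }

  outlets <- vapply(geometry, function(r) r$outlet %||% NA_character_, character(1))
  missing_outlet <- setdiff(required_outlets, outlets[!is.na(outlets)])
  if (length(missing_outlet)) {
    stop(sprintf("schema error: geometry omits outlet '%s'", missing_outlet[[1]]),
         call. = FALSE)
  }
  extra_outlet <- setdiff(outlets[!is.na(outlets)], required_outlets)
  if (length(extra_outlet)) {
    stop(sprintf("schema error: unknown outlet '%s'", extra_outlet[[1]]),
         call. = FALSE)
  }

  # cycle check: walk each segment to the root
  for (s in seg_names) {
    seen <- character(0)
    cur <- s
    while (cur != "heart") {
      if (cur %in% seen) stop("schema error: cyclic topology", call. = FALSE)
      seen <- c(seen, cur)
      cur <- parents[match(cur, seg_names)]
    }
  }

  # node numbering: node 1 = aortic root; each segment's distal end is a node
  node_of <- c(heart = 1L)
  for (i in seq_along(seg_names)) node_of[seg_names[i]] <- i + 1L

  segments <- tibble::tibble(
    name = seg_names,
    parent = parents,
    from_node = node_of[parents],
    to_node = node_of[seg_names],
    length_cm = vapply(geometry, function(r) as.numeric(r$length_cm), numeric(1)),
    mean_area_cm2 = vapply(geometry, function(r) mean(unlist(r$areas_cm2)), numeric(1)),
    n_area_samples = vapply(geometry, function(r) length(unlist(r$areas_cm2)), integer(1)),
    resistance = vapply(geometry, function(r) {
      poiseuille_resistance(unlist(r$areas_cm2), as.numeric(r$length_cm), viscosity)
    }, numeric(1)),
    inertance = 0,
    outlet = outlets
  )
  segments$sub_resistances <- lapply(segments$resistance, split_into_series)

  # device insertion: distal node of the flagged segment, or of the root segment
  flagged <- vapply(geometry, function(r) isTRUE(r$device_site), logical(1))
  if (sum(flagged) > 1) stop("schema error: multiple device sites", call. = FALSE)
  dev_seg <- if (any(flagged)) seg_names[flagged] else seg_names[parents == "heart"][1]
  device_node <- unname(node_of[dev_seg])

  # placeholder terminals (uniform; calibration retunes them)
  term <- segments[!is.na(segments$outlet), ]
  terminals <- tibble::tibble(
    name = term$outlet,
    node = term$to_node,
    R_proximal = 0.35,
    C = 0.15,
    R_distal = 6.0,
    stored_pressure = 80
  )

  structure(
    list(
      segments = segments,
      terminals = terminals,
      n_nodes = length(seg_names) + 1L,
      root_node = 1L,
      device_node = device_node,
      viscosity = viscosity
    ),
    class = "cv_network"
  )
}

#' @export
print.cv_network <- function(x, ...) {
  cat("<cv_network> ", nrow(x$segments), " segments, ",
      nrow(x$terminals), " RCR terminals, device insertion at node ",
      x$device_node, "\n", sep = "")
  invisible(x)
}

#' Summarize a network as a tidy table
#'
#' One row per segment with its Poiseuille resistance, followed by one row
#' per RCR terminal. Suitable for writing with [readr::write_csv()].
#'
#' @param network A `cv_network`.
#' @return A tibble with columns `element`, `type`, `length_cm`,
#'   `mean_area_cm2`, `resistance`, `R_proximal`, `C`, `R_distal`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "cv_network"))
  seg <- dplyr::transmute(
    network$segments,
    element = .data$name, type = "segment",
    length_cm = .data$length_cm, mean_area_cm2 = .data$mean_area_cm2,
    resistance = .data$resistance,
    R_proximal = NA_real_, C = NA_real_, R_distal = NA_real_
  )
  ter <- dplyr::transmute(
    network$terminals,
    element = .data$name, type = "terminal",
    length_cm = NA_real_, mean_area_cm2 = NA_real_, resistance = NA_real_,
    R_proximal = .data$R_proximal, C = .data$C, R_distal = .data$R_distal
  )
  dplyr::bind_rows(seg, ter)
}

# Nodal conductance matrix of the resistive tree (terminal proximal
# resistors included as conductances to their capacitor nodes, which enter
# the right-hand side as sources).  Constant for fixed resistances.
network_conductance <- function(network) {
  n <- network$n_nodes
  G <- matrix(0, n, n)
  for (i in seq_len(nrow(network$segments))) {
    a <- network$segments$from_node[i]
    b <- network$segments$to_node[i]
    g <- 1 / max(network$segments$resistance[i], 1e-8)
    G[a, a] <- G[a, a] + g
    G[b, b] <- G[b, b] + g
    G[a, b] <- G[a, b] - g
    G[b, a] <- G[b, a] - g
  }
  for (k in seq_len(nrow(network$terminals))) {
    nd <- network$terminals$node[k]
    G[nd, nd] <- G[nd, nd] + 1 / network$terminals$R_proximal[k]
  }
  G
}

`%||%` <- function(x, y) if (is.null(x)) y else x
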