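# Standardization of the situational risk factors (RCS, DFD, RNC) to the
# unit interval, and their evaluation from scene geometry.

#' Four-level risk standardization
#'
#' Every situational factor — the strength of the hazard event (RCS), the
#' distance from the danger source (DFD), and the reaction of the
#' neighbourhood crowd (RNC) — is graded on four levels L1..L4, from the most
#' alarming (L1) to the mildest (L4), and standardized onto the unit
#' interval as 1.00, 0.75, 0.50, 0.25.
#'
#' @param level Integer level index 1..4 (L1..L4), vectorised.
#' @return Standardized scale value(s) in {1.00, 0.75, 0.50, 0.25}.
#' @examples
#' standardize_level(1:4)
#' @export
standardize_level <- function(level) {
  if (any(!is.finite(level)) || any(level %ni% 1:4))
    stop("risk level must be in 1..4 (L1..L4)", call. = FALSE)
  c(1.00, 0.75, 0.50, 0.25)[level]
}

#' @rdname standardize_level
#' @return `risk_scales()` returns the four standardized values, L1 first.
#' @export
risk_scales <- function() c(1.00, 0.75, 0.50, 0.25)

#' @rdname standardize_level
#' @param scale Standardized value in {1.00, 0.75, 0.50, 0.25}.
#' @return `level_of_scale()` returns the level index, inverting the mapping.
#' @export
level_of_scale <- function(scale) {
  idx <- match(round(scale, 10), risk_scales())
  if (anyNA(idx))
    stop("scale must be one of 1.00, 0.75, 0.50, 0.25", call. = FALSE)
  idx
}

#' Distance-from-danger level
#'
#' Bins the metric distance to the hazard source into the four standard
#' levels. The bands are below 20 m (L1), 20-40 m (L2), 40-60 m (L3) and
#' beyond 60 m (L4); bins are half-open `[lo, hi)` so 20 m falls in L2 and
#' 60 m in L4.
#'
#' @param distance Distance(s) to the hazard source in metres, >= 0.
#' @return Integer level(s) 1..4.
#' @examples
#' dfd_level(c(15, 20, 45, 70))
#' @export
dfd_level <- function(distance) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be finite and >= 0", call. = FALSE)
  findInterval(distance, c(0, 20, 40, 60))
}

#' Neighbourhood-reaction level
#'
#' The crowd reaction is summarised as the fraction of neighbours (within a
#' configurable radius) who have already reacted. Quartile cut-points map
#' the fraction to the four behavioural grades: three quarters or more
#' reacting corresponds to the most alarming grade (screaming and running,
#' L1), below one quarter to passive waiting (L4).
#'
#' @param fraction Fraction(s) in [0, 1] of already-reacting neighbours.
#' @return Integer level(s) 1..4.
#' @examples
#' rnc_level(c(0, 0.3, 0.6, 1))
#' @export
rnc_level <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("reacting fraction must lie in [0, 1]", call. = FALSE)
  5L - findInterval(fraction, c(0, 0.25, 0.50, 0.75))
}

#' Risk context of a pedestrian at a point in time
#'
#' Composes the three standardized factors for one agent in a scene: RCS is
#' the standardized level of the fire event itself, DFD standardizes the
#' Euclidean distance from the agent to the fire source, and RNC
#' standardizes the fraction of other agents within `radius` metres who have
#' already reacted (escaped). With `continuous = TRUE` the quantization is
#' bypassed: DFD becomes `max(0, 1 - d/80)` and RNC the raw fraction.
#'
#' @param position Length-2 numeric, the agent position (m).
#' @param scene A [build_scene()] scene.
#' @param neighbour_positions Matrix (n x 2) of other agents' positions, or
#'   `NULL` for an empty neighbourhood.
#' @param neighbour_reacted Logical vector, whether each neighbour has
#'   already reacted.
#' @param radius Neighbourhood radius in metres (default 10).
#' @param continuous Use continuous (unquantized) factor values.
#' @param invert_rcs Treat the fire's level ordering as inverted, so a
#'   declared Level 4 maps to the strongest scale 1.00 (see the scene
#'   discussion in the package vignette).
#' @return List with numeric `rcs`, `dfd`, `rnc`.
#' @export
context_at <- function(position, scene, neighbour_positions = NULL,
                       neighbour_reacted = logical(0), radius = 10,
                       continuous = FALSE, invert_rcs = FALSE) {
  stopifnot(inherits(scene, "evac_scene"))
  if (!in_bounds(scene, position))
    stop("pedestrian position is outside the scene bounds", call. = FALSE)
  lvl <- scene$fire$level
  if (invert_rcs) lvl <- 5L - lvl
  rcs <- standardize_level(lvl)

  d <- sqrt(sum((position - scene$fire$source)^2))
  f <- 0
  if (!is.null(neighbour_positions) && nrow(neighbour_positions)) {
    dd <- sqrt((neighbour_positions[, 1] - position[1])^2 +
               (neighbour_positions[, 2] - position[2])^2)
    near <- dd <= radius
    if (any(near)) f <- mean(neighbour_reacted[near])
  }
  if (continuous) {
    list(rcs = rcs, dfd = max(0, 1 - d / 80), rnc = f)
  } else {
    list(rcs = rcs,
         dfd = standardize_level(dfd_level(d)),
         rnc = standardize_level(rnc_level(f)))
  }
}

#' Dump the level tables as JSON
#'
#' Writes the level-to-scale mapping and the distance and reaction cut
#' points to a JSON document, for reports and external tools.
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_level_tables <- function(path) {
  obj <- list(
    scale = stats::setNames(as.list(risk_scales()), paste0("L", 1:4)),
    dfd_bins_m = list(L1 = "[0,20)", L2 = "[20,40)", L3 = "[40,60)",
                      L4 = "[60,Inf)"),
    rnc_bins_fraction = list(L1 = "[0.75,1]", L2 = "[0.50,0.75)",
                             L3 = "[0.25,0.50)", L4 = "[0,0.25)"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
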