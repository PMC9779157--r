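# Multi-zone scene geometry: rectangular halls, a connection graph with
# origins and exits, a fire source and a linearly spreading smoke front.

#' Build and validate an evacuation scene
#'
#' A scene is a set of axis-aligned rectangular zones (the halls where
#' agents wait), a connection graph whose nodes are the zones plus the exit
#' nodes, a fire specification (source point, zone, four-grade level) and a
#' smoke front that expands as a circle around the source at constant
#' speed.
#'
#' @param zones Data frame with columns `id`, `xmin`, `xmax`, `ymin`,
#'   `ymax`; zones must have positive area and must not overlap.
#' @param exits Integer vector of exit (destination) node ids.
#' @param edges Two-column matrix of undirected node-id pairs; every zone
#'   must reach at least one exit.
#' @param fire List with `source` (length-2 numeric, metres), `zone` (zone
#'   id containing the source) and `level` (1..4).
#' @param smoke_speed Smoke front speed in m/s (default 0.3).
#' @return Object of class `evac_scene`.
#' @seealso [default_scene()] for the layout shipped with the package.
#' @export
build_scene <- function(zones, exits, edges, fire, smoke_speed = 0.3) {
  stopifnot(is.data.frame(zones),
            all(c("id", "xmin", "xmax", "ymin", "ymax") %in% names(zones)))
  w <- zones$xmax - zones$xmin
  h <- zones$ymax - zones$ymin
  if (any(w <= 0) || any(h <= 0))
    stop("zone(s) with zero or negative area: ",
         paste(zones$id[w <= 0 | h <= 0], collapse = ", "), call. = FALSE)
  nz <- nrow(zones)
  for (i in seq_len(nz)) for (j in seq_len(nz)) if (i < j) {
    ox <- min(zones$xmax[i], zones$xmax[j]) - max(zones$xmin[i], zones$xmin[j])
    oy <- min(zones$ymax[i], zones$ymax[j]) - max(zones$ymin[i], zones$ymin[j])
    if (ox > 0 && oy > 0)
      stop("zones ", zones$id[i], " and ", zones$id[j], " overlap",
           call. = FALSE)
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  nodes <- sort(unique(c(zones$id, exits, as.vector(edges))))
  # connectivity: every origin zone must reach an exit
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  for (z in zones$id) {
    seen <- z
    frontier <- z
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[as.character(frontier)])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (!any(exits %in% seen))
      stop("zone ", z, " is not connected to any exit", call. = FALSE)
  }
  zf <- zones[zones$id == fire$zone, , drop = FALSE]
  if (!nrow(zf)) stop("fire zone ", fire$zone, " not found", call. = FALSE)
  s <- fire$source
  if (s[1] < zf$xmin || s[1] > zf$xmax || s[2] < zf$ymin || s[2] > zf$ymax)
    stop("fire source lies outside its declared zone", call. = FALSE)
  if (fire$level %ni% 1:4) stop("fire level must be 1..4", call. = FALSE)
  if (smoke_speed <= 0) stop("smoke_speed must be > 0", call. = FALSE)
  structure(list(zones = zones, exits = as.integer(exits), edges = edges,
                 fire = list(source = as.numeric(s),
                             zone = as.integer(fire$zone),
                             level = as.integer(fire$level)),
                 smoke_speed = smoke_speed,
                 bounds = c(xmin = min(zones$xmin), xmax = max(zones$xmax),
                            ymin = min(zones$ymin), ymax = max(zones$ymax))),
            class = "evac_scene")
}

#' Default three-hall scene
#'
#' The layout used throughout the package's examples: a 100 m x 60 m
#' rectangle split into three equal halls (origin zones 1-3), exit nodes 4
#' and 5 on the left and right walls, connections 1-2, 2-3, 1-4 and 3-5,
#' and a fire of the given level at the centre of Zone 3 with a 0.3 m/s
#' smoke front. All geometry is configurable through [build_scene()].
#'
#' @param fire_level Fire level 1..4 (default 4).
#' @param smoke_speed Smoke speed in m/s.
#' @return An `evac_scene`.
#' @export
default_scene <- function(fire_level = 4L, smoke_speed = 0.3) {
  zones <- data.frame(id = 1:3,
                      xmin = c(0, 100 / 3, 200 / 3),
                      xmax = c(100 / 3, 200 / 3, 100),
                      ymin = 0, ymax = 60)
  build_scene(zones, exits = 4:5,
              edges = rbind(c(1, 2), c(2, 3), c(1, 4), c(3, 5)),
              fire = list(source = c(250 / 3, 30), zone = 3L,
                          level = fire_level),
              smoke_speed = smoke_speed)
}

in_bounds <- function(scene, position) {
  b <- scene$bounds
  position[1] >= b["xmin"] && position[1] <= b["xmax"] &&
    position[2] >= b["ymin"] && position[2] <= b["ymax"]
}

#' @export
print.evac_scene <- function(x, ...) {
  cat(sprintf("Evacuation scene: %d zones, %d exit(s)\n",
              nrow(x$zones), length(x$exits)))
  cat(sprintf("  fire: level %d in zone %d at (%.1f, %.1f); smoke %.2f m/s\n",
              x$fire$level, x$fire$zone, x$fire$source[1], x$fire$source[2],
              x$smoke_speed))
  invisible(x)
}

#' Smoke-front radius at a given time
#'
#' The smoke front is a circle around the fire source growing at the
#' scene's constant smoke speed; walls do not block it.
#'
#' @param t Time(s) in seconds since ignition, >= 0.
#' @param scene An `evac_scene`.
#' @return Radius in metres.
#' @examples
#' smoke_radius(120, default_scene())
#' @export
smoke_radius <- function(t, scene) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  scene$smoke_speed * t
}

#' Read / write a scene layout as JSON
#'
#' @param scene An `evac_scene`.
#' @param path File path.
#' @return `write_scene` returns `path` invisibly; `read_scene` the scene.
#' @export
write_scene <- function(scene, path) {
  obj <- list(schema = "preevac-scene/1",
              zones = scene$zones, exits = scene$exits,
              edges = as.data.frame(scene$edges),
              fire = scene$fire, smoke_speed = scene$smoke_speed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "preevac-scene/1"))
    stop("unrecognized scene schema in ", path, call. = FALSE)
  build_scene(as.data.frame(obj$zones), exits = obj$exits,
              edges = as.matrix(obj$edges),
              fire = list(source = unlist(obj$fire$source),
                          zone = obj$fire$zone, level = obj$fire$level),
              smoke_speed = obj$smoke_speed)
}
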