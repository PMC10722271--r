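#' An anthropogenic risk element
#'
#' One disturbance source (village, factory, road, artificial or economic
#' forest) with a base interference intensity that decays with distance and
#' vanishes at a maximum distance.
#'
#' @param geom a [geometry()] (point, polyline or polygon, projected meters).
#' @param element_type one of `village`, `factory`, `road`,
#'   `artificial_forest`, `economic_forest`.
#' @param intensity base interference intensity I0 at distance 0 (>= 0).
#' @param max_distance distance (m) at which interference reaches 0 (> 0).
#' @param decay decay kernel: `linear`, `constant`, `convex` or `concave`.
#' @param exponent power gamma for the convex (> 1) / concave (< 1) kernels.
#' @return an object of class `risk_element`.
#' @export
risk_element <- function(geom, element_type, intensity, max_distance,
                         decay = c("linear", "constant", "convex", "concave"),
                         exponent = 1) {
  decay <- match.arg(decay)
  types <- c("village", "factory", "road", "artificial_forest", "economic_forest")
  if (!element_type %in% types)
    stop("element_type must be one of: ", paste(types, collapse = ", "))
  if (intensity < 0) stop("intensity must be nonnegative")
  if (max_distance <= 0) stop("max_distance must be positive")
  if (exponent <= 0) stop("exponent must be positive")
  if (decay == "convex" && exponent <= 1)
    warning("convex decay expects exponent > 1")
  if (decay == "concave" && exponent >= 1)
    warning("concave decay expects exponent < 1")
  structure(list(geometry = geom, element_type = element_type,
                 intensity = intensity, max_distance = max_distance,
                 decay = decay, exponent = exponent),
            class = "risk_element")
}

#' Default per-type risk parameters
#'
#' Synthetic placeholder intensities and maximum disturbance distances for
#' the five element types (the calibrated per-element values used in real
#' reserves are site-specific and must be supplied by the analyst). All
#' decays default to linear, the kernel used throughout the pipeline.
#'
#' @return data.frame with columns `element_type`, `intensity`,
#'   `max_distance`, `decay`, `exponent`.
#' @export
default_risk_params <- function() {
  data.frame(
    element_type = c("village", "factory", "road",
                     "artificial_forest", "economic_forest"),
    intensity = c(10, 8, 6, 4, 5),
    max_distance = c(1500, 1000, 800, 500, 600),
    decay = "linear",
    exponent = 1
  )
}

#' Interference intensity at a distance
#'
#' Distance-decay kernels: `linear` falls at a constant rate from I0 at the
#' source to 0 at `max_distance`; `constant` keeps I0 up to (but not at)
#' `max_distance`; `convex`/`concave` are power-law variants
#' I0 * (1 - d/Dmax)^gamma with gamma > 1 / gamma < 1. All kernels return
#' I0 at d = 0 and exactly 0 for d >= `max_distance`.
#'
#' @param d distance(s) in meters (>= 0), vectorized.
#' @param element a [risk_element()].
#' @return interference intensity, same length as `d`.
#' @export
decay_intensity <- function(d, element) {
  if (any(d < 0)) stop("distance must be nonnegative")
  I0 <- element$intensity; Dmax <- element$max_distance
  frac <- 1 - pmin(d, Dmax) / Dmax
  out <- switch(element$decay,
    linear = I0 * frac,
    constant = ifelse(d < Dmax, I0, 0),
    convex = I0 * frac^element$exponent,
    concave = I0 * frac^element$exponent
  )
  out[d >= Dmax] <- 0
  out
}

#' Distance raster to one risk element
#'
#' Per-cell Euclidean distance from the cell center to the nearest point of
#' the element's geometry (0 inside polygons).
#'
#' @param template `raster_grid` defining the output geometry; NA cells
#'   propagate to the output.
#' @param element a [risk_element()] or bare [geometry()].
#' @return `raster_grid` of distances (m).
#' @export
distance_to_element <- function(template, element) {
  geom <- if (inherits(element, "risk_element")) element$geometry else element
  ctr <- cell_centers(template)
  d <- dist_to_geometry(ctr$x, ctr$y, geom)
  out <- matrix(d, nrow(template$values), ncol(template$values), byrow = TRUE)
  out[is.na(template$values)] <- NA_real_
  raster_grid(out, template$xmin, template$ymin, template$cell_size,
              template$crs)
}

#' Build the summed anthropogenic disturbance surface
#'
#' Environmental risk surface: each cell receives the sum, over all risk
#' elements, of the element's decayed interference intensity at the cell's
#' distance from it. An empty element list yields an all-zero surface;
#' NA (nodata) cells of the template propagate.
#'
#' @param template `raster_grid` defining the output grid.
#' @param elements list of [risk_element()]s.
#' @return `raster_grid` of total interference intensity.
#' @export
build_risk_surface <- function(template, elements) {
  acc <- template
  acc$values[] <- 0
  acc$values[is.na(template$values)] <- NA_real_
  for (el in elements) {
    if (!inherits(el, "risk_element")) stop("elements must be risk_element objects")
    d <- distance_to_element(template, el)
    acc$values <- acc$values + decay_intensity_matrix(d$values, el)
  }
  acc
}

decay_intensity_matrix <- function(d, element) {
  out <- d
  ok <- !is.na(d)
  out[ok] <- decay_intensity(d[ok], element)
  out
}

#' Write risk elements as GeoJSON
#'
#' One Feature per element (Point / LineString / Polygon) with properties
#' `element_type`, `intensity`, `max_distance`, `decay`, `exponent`.
#'
#' @param elements list of [risk_element()]s.
#' @param path output `.geojson` path.
#' @export
write_risk_geojson <- function(elements, path) {
  feat <- lapply(elements, function(el) {
    co <- el$geometry$coords
    geom <- switch(el$geometry$type,
      point = list(type = "Point", coordinates = c(co[1, 1], co[1, 2])),
      polyline = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(co)),
                                           function(i) c(co[i, 1], co[i, 2]))),
      polygon = {
        ring <- rbind(co, co[1, , drop = FALSE])
        list(type = "Polygon",
             coordinates = list(lapply(seq_len(nrow(ring)),
                                       function(i) c(ring[i, 1], ring[i, 2]))))
      })
    list(type = "Feature", geometry = geom,
         properties = list(element_type = el$element_type,
                           intensity = el$intensity,
                           max_distance = el$max_distance,
                           decay = el$decay, exponent = el$exponent))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read risk elements from GeoJSON
#'
#' @param path a `.geojson` file as written by [write_risk_geojson()] (or
#'   any FeatureCollection of Points/LineStrings/Polygons with the same
#'   properties).
#' @return list of [risk_element()]s.
#' @export
read_risk_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  lapply(js$features, function(f) {
    g <- f$geometry
    coords <- switch(g$type,
      Point = matrix(unlist(g$coordinates), ncol = 2, byrow = TRUE),
      LineString = do.call(rbind, lapply(g$coordinates, unlist)),
      Polygon = {
        ring <- do.call(rbind, lapply(g$coordinates[[1]], unlist))
        ring[-nrow(ring), , drop = FALSE]
      },
      stop("unsupported GeoJSON geometry: ", g$type))
    type <- switch(g$type, Point = "point", LineString = "polyline",
                   Polygon = "polygon")
    p <- f$properties
    risk_element(geometry(type, coords), p$element_type, p$intensity,
                 p$max_distance, p$decay, p$exponent)
  })
}
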