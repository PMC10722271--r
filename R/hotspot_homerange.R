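#' Delineate top-decile diversity hotspots
#'
#' Hotspots are the grid cells whose predicted diversity lies in the top
#' (1 - q) share of all valid cells — the top 10% by default, a widely used
#' threshold. The cut is value-based: the threshold is the q-quantile of
#' the valid cells and every cell at or above it is flagged, so ties at the
#' threshold are all included (the flagged fraction can then slightly
#' exceed 10%).
#'
#' @param surface `raster_grid` of predicted diversity.
#' @param q quantile defining the cut (default 0.90).
#' @return an object of class `hotspot_mask`: list with `mask` (logical
#'   `raster_grid`), `threshold`, `q`, `n_flagged`, `n_valid`.
#' @export
identify_hotspots <- function(surface, q = 0.90) {
  v <- surface$values
  valid <- !is.na(v)
  n_valid <- sum(valid)
  if (n_valid == 0) stop("surface has no valid cells")
  if (n_valid < 10) stop("need at least 10 valid cells")
  threshold <- stats::quantile(v[valid], q, names = FALSE)
  flag <- v >= threshold & valid
  if (all(flag[valid]))
    warning("all valid cells tie at the hotspot threshold")
  mask <- surface
  mask$values <- matrix(NA_real_, nrow(v), ncol(v))
  mask$values[valid] <- as.numeric(flag[valid])
  structure(list(mask = mask, threshold = threshold, q = q,
                 n_flagged = sum(flag), n_valid = n_valid),
            class = "hotspot_mask")
}

#' @export
print.hotspot_mask <- function(x, ...) {
  cat(sprintf("hotspot_mask: %d of %d valid cells (%.1f%%) >= %.4g (q = %.2f)\n",
              x$n_flagged, x$n_valid, 100 * x$n_flagged / x$n_valid,
              x$threshold, x$q))
  invisible(x)
}

#' Radius of a circular home range
#'
#' r = sqrt(area / pi), with the area given in km2 and the radius returned
#' in meters (1.49 km2 gives 688 m to the nearest meter).
#'
#' @param area_km2 home-range area in km2 (> 0).
#' @return radius in meters.
#' @export
home_range_radius <- function(area_km2) {
  if (any(area_km2 <= 0)) stop("area must be positive")
  sqrt(area_km2 * 1e6 / pi)
}

#' Build circular home ranges around group centers
#'
#' Each family group gets a frequent range (disk of radius r around its
#' center, r from the home-range area) and an infrequent range (the
#' frequent range plus a buffer ring of width r, i.e. a disk of radius 2r).
#'
#' @param centers data.frame with `group`, `x`, `y` (projected meters).
#' @param area_km2 home-range area in km2 (default 1.49).
#' @return data.frame with one row per group: `group`, `x`, `y`,
#'   `frequent_radius`, `infrequent_radius` (meters).
#' @export
build_home_ranges <- function(centers, area_km2 = 1.49) {
  if (nrow(centers) < 1) stop("need at least one group center")
  if (anyDuplicated(centers$group))
    stop("duplicate group ids: ",
         paste(unique(centers$group[duplicated(centers$group)]), collapse = ", "))
  r <- home_range_radius(area_km2)
  data.frame(group = centers$group, x = centers$x, y = centers$y,
             frequent_radius = r, infrequent_radius = 2 * r)
}

#' Overlay hotspots with home ranges
#'
#' A grid cell belongs to a range iff its center lies inside the disk.
#' For every group, range tier and the given index label, reports the
#' number of hotspot cells inside the range, their area, and the fraction
#' of the range's cells that are hotspots.
#'
#' @param hotspots a `hotspot_mask` (from [identify_hotspots()]).
#' @param ranges home-range table from [build_home_ranges()].
#' @param index label recorded in the report (e.g. "richness").
#' @return data.frame with columns `group`, `tier`, `index`,
#'   `range_cells`, `hotspot_cells`, `hotspot_area_m2`, `coverage`.
#' @export
overlay_hotspots <- function(hotspots, ranges, index = "diversity") {
  mask <- hotspots$mask
  ctr <- cell_centers(mask)
  flag <- as.vector(t(mask$values)) == 1
  valid <- !is.na(as.vector(t(mask$values)))
  cs2 <- mask$cell_size^2
  rows <- list()
  for (i in seq_len(nrow(ranges))) {
    for (tier in c("frequent", "infrequent")) {
      r <- ranges[[paste0(tier, "_radius")]][i]
      inside <- valid &
        (ctr$x - ranges$x[i])^2 + (ctr$y - ranges$y[i])^2 <= r^2
      if (!any(inside))
        warning(sprintf("range %s (%s) covers no valid cells",
                        ranges$group[i], tier))
      n_in <- sum(inside)
      n_hot <- sum(inside & flag)
      rows[[length(rows) + 1L]] <- data.frame(
        group = ranges$group[i], tier = tier, index = index,
        range_cells = n_in, hotspot_cells = n_hot,
        hotspot_area_m2 = n_hot * cs2,
        coverage = if (n_in > 0) n_hot / n_in else 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
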