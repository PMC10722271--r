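#' Configuration of a synthetic study landscape
#'
#' Defines the geometry and stochastic structure of a simulated reserve:
#' a rectangular extent on a square analysis grid (20 m by default, the
#' resolution all predictors share), the spatial correlation length of the
#' generated climate/soil fields, and how many fields of each group to draw.
#'
#' @param extent numeric vector `c(xmin, ymin, xmax, ymax)` in meters; width
#'   and height must be positive multiples of `cell_size`.
#' @param cell_size analysis cell size in meters.
#' @param correlation_length Gaussian correlation length of the random
#'   fields, in meters (0 gives i.i.d. cell noise).
#' @param n_climate,n_soil number of climate / soil fields to generate.
#' @param seed integer RNG seed; identical configs reproduce identical
#'   landscapes bit for bit.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(extent = c(0, 0, 16000, 12000), cell_size = 20,
                             correlation_length = 800,
                             n_climate = 4, n_soil = 3, seed = 1) {
  if (cell_size <= 0) stop("cell_size must be positive")
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  if (w <= 0 || h <= 0) stop("extent must have positive width and height")
  if (abs(w / cell_size - round(w / cell_size)) > 1e-9 ||
      abs(h / cell_size - round(h / cell_size)) > 1e-9)
    stop("extent width and height must be multiples of cell_size")
  if (correlation_length < 0) stop("correlation_length must be nonnegative")
  structure(
    list(extent = extent, cell_size = cell_size,
         correlation_length = correlation_length,
         n_climate = n_climate, n_soil = n_soil, seed = as.integer(seed)),
    class = "landscape_config"
  )
}

empty_raster <- function(config) {
  nr <- round((config$extent[4] - config$extent[2]) / config$cell_size)
  nc <- round((config$extent[3] - config$extent[1]) / config$cell_size)
  raster_grid(matrix(0, nr, nc), config$extent[1], config$extent[2],
              config$cell_size)
}

random_field <- function(config) {
  tmpl <- empty_raster(config)
  v <- matrix(stats::rnorm(length(tmpl$values)), nrow(tmpl$values))
  g <- gaussian_smooth(raster_grid(v, tmpl$xmin, tmpl$ymin, tmpl$cell_size),
                       config$correlation_length / config$cell_size)
  g$values <- (g$values - mean(g$values)) / stats::sd(g$values)
  g
}

#' Named stack of aligned predictor rasters
#'
#' @param rasters named list of `raster_grid`s on one common grid.
#' @param groups named character vector mapping each raster to a predictor
#'   group (`climate`, `soil`, `topography`, `anthropogenic`).
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(rasters, groups) {
  if (is.null(names(rasters)) || any(names(rasters) == ""))
    stop("all rasters must be named")
  tmpl <- rasters[[1]]
  for (r in rasters) if (!same_grid(r, tmpl)) stop("rasters are not aligned")
  groups <- groups[names(rasters)]
  if (anyNA(groups)) stop("every raster needs a group label")
  structure(list(rasters = rasters, groups = groups),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers (%s)\n", length(x$rasters),
              paste(sprintf("%s: %d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Add a layer to a predictor stack
#'
#' @param stack a `predictor_stack`.
#' @param name layer name.
#' @param raster aligned `raster_grid`.
#' @param group predictor group label.
#' @export
stack_add <- function(stack, name, raster, group) {
  stack$rasters[[name]] <- raster
  stack$groups[name] <- group
  predictor_stack(stack$rasters, stack$groups)
}

#' Generate the synthetic predictor stack
#'
#' Climate and soil layers are stationary Gaussian random fields (white
#' noise smoothed to the configured correlation length, then
#' z-standardized). A DEM-like elevation surface is generated the same way
#' and rescaled to a tropical-mountain range; slope and aspect are derived
#' from it by Horn's stencil. All layers share the 20 m analysis grid.
#'
#' @param config a [landscape_config()].
#' @return a `predictor_stack` with groups climate / soil / topography.
#' @export
generate_predictor_stack <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  rasters <- list(); groups <- character()
  for (i in seq_len(config$n_climate)) {
    nm <- sprintf("climate_%02d", i)
    rasters[[nm]] <- random_field(config); groups[nm] <- "climate"
  }
  for (i in seq_len(config$n_soil)) {
    nm <- sprintf("soil_%02d", i)
    rasters[[nm]] <- random_field(config); groups[nm] <- "soil"
  }
  elev <- random_field(config)
  elev$values <- 700 + 280 * elev$values   # ~100-1400 m relief
  rasters[["elevation"]] <- elev; groups["elevation"] <- "topography"
  ter <- terrain_slope_aspect(elev)
  rasters[["slope"]] <- ter$slope; groups["slope"] <- "topography"
  rasters[["aspect"]] <- ter$aspect; groups["aspect"] <- "topography"
  predictor_stack(rasters, groups)
}

#' Generate synthetic anthropogenic risk elements
#'
#' Villages and factories are points, roads polylines crossing the extent,
#' artificial and economic forests convex polygon patches. Each element
#' carries the intensity, maximum disturbance distance and decay kind for
#' its type from `params` (see [default_risk_params()]).
#'
#' @param config a [landscape_config()].
#' @param counts named integer vector over the five element types
#'   (`village`, `factory`, `road`, `artificial_forest`, `economic_forest`).
#' @param params per-type parameter table as from [default_risk_params()].
#' @return list of [risk_element()]s.
#' @export
generate_risk_elements <- function(config,
                                   counts = c(village = 3, factory = 1,
                                              road = 2, artificial_forest = 2,
                                              economic_forest = 2),
                                   params = default_risk_params()) {
  stopifnot(all(counts >= 0))
  known <- c("village", "factory", "road", "artificial_forest", "economic_forest")
  if (!all(names(counts) %in% known))
    stop("unknown element type in counts: ",
         paste(setdiff(names(counts), known), collapse = ", "))
  set.seed(config$seed + 1L)
  ex <- config$extent
  runif_x <- function(n) stats::runif(n, ex[1], ex[3])
  runif_y <- function(n) stats::runif(n, ex[2], ex[4])
  elements <- list()
  add <- function(el) elements[[length(elements) + 1L]] <<- el
  mk <- function(type, geom) {
    p <- params[params$element_type == type, ]
    risk_element(geom, type, intensity = p$intensity,
                 max_distance = p$max_distance, decay = p$decay,
                 exponent = p$exponent)
  }
  for (type in known) {
    n <- if (type %in% names(counts)) counts[[type]] else 0L
    if (n == 0L) next
    for (i in seq_len(n)) {
      if (type %in% c("village", "factory")) {
        g <- geometry("point", cbind(runif_x(1), runif_y(1)))
      } else if (type == "road") {
        # polyline crossing the extent west-east with jittered waypoints
        xs <- seq(ex[1], ex[3], length.out = 6L)
        ys <- runif_y(1) + cumsum(stats::rnorm(6L, 0, (ex[4] - ex[2]) / 20))
        ys <- pmin(pmax(ys, ex[2]), ex[4])
        g <- geometry("polyline", cbind(xs, ys))
      } else {
        # convex polygon patch around a random center
        cx <- runif_x(1); cy <- runif_y(1)
        ang <- sort(stats::runif(6L, 0, 2 * pi))
        rad <- stats::runif(6L, 200, 700)
        g <- geometry("polygon", cbind(cx + rad * cos(ang), cy + rad * sin(ang)))
      }
      add(mk(type, g))
    }
  }
  elements
}

grid_nodes <- function(extent, spacing) {
  xs <- seq(ceiling(extent[1] / spacing) * spacing, extent[3], by = spacing)
  ys <- seq(ceiling(extent[2] / spacing) * spacing, extent[4], by = spacing)
  xs <- xs[xs > extent[1] & xs < extent[3]]
  ys <- ys[ys > extent[2] & ys < extent[4]]
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

#' Generate the two-tier survey plot layout
#'
#' Mirrors a kilometer-grid field campaign: `n_coarse` plots centered on
#' 1 km grid nodes across the whole extent, plus `n_fine` plots on 0.5 km
#' nodes inside a focal zone (densified sampling in the zone of interest).
#' Nodes are sampled without replacement under the config seed; fine nodes
#' never duplicate a chosen coarse center.
#'
#' @param config a [landscape_config()].
#' @param n_coarse,n_fine number of plots per tier.
#' @param focal_zone `c(xmin, ymin, xmax, ymax)` inside the extent; `NULL`
#'   uses the inner 3/4 of the extent.
#' @param plot_side plot edge length in meters.
#' @param coarse_spacing,fine_spacing node spacing (m) of the two grids.
#' @return data.frame with columns `plot_id`, `x`, `y`, `tier`, `plot_side`.
#' @export
generate_plot_layout <- function(config, n_coarse = 114, n_fine = 277,
                                 focal_zone = NULL, plot_side = 20,
                                 coarse_spacing = 1000, fine_spacing = 500) {
  ex <- config$extent
  if (is.null(focal_zone)) {
    mx <- (ex[3] - ex[1]) / 8; my <- (ex[4] - ex[2]) / 8
    focal_zone <- c(ex[1] + mx, ex[2] + my, ex[3] - mx, ex[4] - my)
  }
  if (focal_zone[1] < ex[1] || focal_zone[2] < ex[2] ||
      focal_zone[3] > ex[3] || focal_zone[4] > ex[4])
    stop("focal_zone must lie inside the extent")
  set.seed(config$seed + 2L)
  coarse_nodes <- grid_nodes(ex, coarse_spacing)
  if (n_coarse > nrow(coarse_nodes))
    stop(sprintf("coarse grid holds only %d nodes (%d requested)",
                 nrow(coarse_nodes), n_coarse))
  ci <- sort(sample.int(nrow(coarse_nodes), n_coarse))
  coarse <- coarse_nodes[ci, , drop = FALSE]
  fine_nodes <- grid_nodes(focal_zone, fine_spacing)
  taken <- paste(coarse$x, coarse$y)
  fine_nodes <- fine_nodes[!(paste(fine_nodes$x, fine_nodes$y) %in% taken), ,
                           drop = FALSE]
  if (n_fine > nrow(fine_nodes))
    stop(sprintf("fine grid holds only %d free nodes (%d requested)",
                 nrow(fine_nodes), n_fine))
  fi <- sort(sample.int(nrow(fine_nodes), n_fine))
  fine <- fine_nodes[fi, , drop = FALSE]
  out <- rbind(
    if (n_coarse > 0) data.frame(x = coarse$x, y = coarse$y, tier = "coarse"),
    if (n_fine > 0) data.frame(x = fine$x, y = fine$y, tier = "fine")
  )
  if (is.null(out)) out <- data.frame(x = numeric(), y = numeric(),
                                      tier = character())
  out <- cbind(plot_id = sprintf("P%03d", seq_len(nrow(out))), out)
  out$plot_side <- rep(plot_side, nrow(out))
  rownames(out) <- NULL
  out
}

#' Ground-truth effect structure for community simulation
#'
#' Names the predictors that truly drive diversity and their effect sizes,
#' so parameter-recovery tests can check that the pipeline finds them.
#' Richness acts on the log scale (Poisson mean); evenness acts on the
#' logit of the geometric-series dominance ratio.
#'
#' @param beta_richness,beta_evenness named coefficient vectors over
#'   predictor names (missing predictors have effect 0).
#' @param intercept_richness intercept of log expected richness.
#' @param intercept_evenness intercept of logit dominance ratio.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(beta_richness = c(climate_01 = 0.5, soil_01 = 0.4),
                         beta_evenness = c(climate_01 = 0.8, soil_01 = 0.5),
                         intercept_richness = log(25),
                         intercept_evenness = 1.0) {
  structure(list(beta_richness = beta_richness,
                 beta_evenness = beta_evenness,
                 intercept_richness = intercept_richness,
                 intercept_evenness = intercept_evenness),
            class = "ground_truth")
}

linear_predictor <- function(X, intercept, beta) {
  missing <- setdiff(names(beta), colnames(X))
  if (length(missing) > 0)
    stop("ground-truth coefficients name unknown predictors: ",
         paste(missing, collapse = ", "))
  eta <- rep(intercept, nrow(X))
  for (nm in names(beta)) eta <- eta + beta[[nm]] * X[, nm]
  eta
}

rpois_trunc <- function(n, lambda, lo, hi) {
  out <- integer(n)
  pending <- seq_len(n)
  lam <- rep_len(lambda, n)
  while (length(pending) > 0) {
    draw <- stats::rpois(length(pending), lam[pending])
    ok <- draw >= lo & draw <= hi
    out[pending[ok]] <- draw[ok]
    pending <- pending[!ok]
  }
  out
}

#' Simulate plot communities with known effect structure
#'
#' For each plot, expected log-richness is the ground-truth linear
#' predictor evaluated at the plot's cell; realized richness is Poisson,
#' rejection-truncated to `[1, species_pool]`. Species are drawn from a
#' common pool and abundances follow a geometric series whose dominance
#' ratio k is a logistic function of the evenness linear predictor, so
#' Shannon evenness carries covariate signal as well. Stem diameters are
#' drawn (log-normal) for realism but not used downstream.
#'
#' @param layout plot layout from [generate_plot_layout()].
#' @param stack a `predictor_stack` covering the plots.
#' @param truth a [ground_truth()].
#' @param species_pool number of species available (>= 2).
#' @param mean_extra_stems mean number of stems beyond the one-per-species
#'   minimum (Poisson).
#' @param seed integer RNG seed.
#' @return `community_table` data.frame (`plot_id`, `species`, `abundance`,
#'   `mean_dbh`) with attributes `realized_richness` and `dominance_ratio`
#'   (named per plot) for bookkeeping checks.
#' @export
simulate_communities <- function(layout, stack, truth, species_pool = 120,
                                 mean_extra_stems = 120, seed = 1) {
  if (species_pool < 2) stop("species_pool must be at least 2")
  X <- extract_at_plots(stack, layout)
  eta_s <- linear_predictor(X, truth$intercept_richness, truth$beta_richness)
  eta_e <- linear_predictor(X, truth$intercept_evenness, truth$beta_evenness)
  set.seed(seed)
  n <- nrow(layout)
  S <- rpois_trunc(n, exp(eta_s), 1L, species_pool)
  k <- stats::plogis(eta_e)
  pool <- sprintf("sp%03d", seq_len(species_pool))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- sample(pool, S[i])
    # geometric-series abundance profile, dominance ratio k
    w <- k[i]^(seq_len(S[i]) - 1L)
    extra <- stats::rpois(1L, mean_extra_stems)
    ab <- rep(1L, S[i])
    if (extra > 0)
      ab <- ab + as.integer(stats::rmultinom(1L, extra, w / sum(w)))
    rows[[i]] <- data.frame(plot_id = layout$plot_id[i], species = sp,
                            abundance = ab,
                            mean_dbh = round(stats::rlnorm(S[i], log(8), 0.5), 1))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "realized_richness") <- stats::setNames(S, layout$plot_id)
  attr(out, "dominance_ratio") <- stats::setNames(k, layout$plot_id)
  class(out) <- c("community_table", "data.frame")
  out
}
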