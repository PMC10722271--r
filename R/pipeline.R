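#' Default end-to-end pipeline configuration
#'
#' Bundles every stage's parameters. The default is a small demonstration
#' landscape that runs in well under a minute; `study_config()` gives the
#' full-size synthetic study system.
#'
#' @param landscape a [landscape_config()].
#' @param truth a [ground_truth()].
#' @param n_coarse,n_fine plots per layout tier.
#' @param coarse_spacing,fine_spacing grid-node spacing (m) of the two
#'   tiers.
#' @param focal_zone rectangle `c(xmin, ymin, xmax, ymax)` of the fine
#'   tier; `NULL` uses the inner 3/4 of the extent.
#' @param species_pool species available to the community simulator.
#' @param risk_counts named counts of risk elements per type.
#' @param settings a [model_settings()] shared by both diversity indices.
#' @param group_centers home-range group centers (`group`, `x`, `y`);
#'   `NULL` places four clustered groups in the focal zone and one group
#'   8 km east of them (or at the extent edge on small landscapes).
#' @param home_range_km2 circular home-range area in km2.
#' @param hotspot_q hotspot quantile (default 0.90).
#' @param selection_tolerance backward-elimination CV-RMSE tolerance.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(landscape = landscape_config(
                              extent = c(0, 0, 1200, 1200), cell_size = 20,
                              correlation_length = 150, n_climate = 4,
                              n_soil = 3, seed = 1),
                            truth = ground_truth(),
                            n_coarse = 20, n_fine = 30,
                            coarse_spacing = 200, fine_spacing = 100,
                            focal_zone = NULL,
                            species_pool = 120,
                            risk_counts = c(village = 2, factory = 1, road = 1,
                                            artificial_forest = 1,
                                            economic_forest = 1),
                            settings = model_settings(ntree = 150,
                                                      cv_folds = 5,
                                                      seed = 1),
                            group_centers = NULL,
                            home_range_km2 = 1.49,
                            hotspot_q = 0.90,
                            selection_tolerance = 0.01) {
  structure(list(landscape = landscape, truth = truth,
                 n_coarse = n_coarse, n_fine = n_fine,
                 coarse_spacing = coarse_spacing, fine_spacing = fine_spacing,
                 focal_zone = focal_zone, species_pool = species_pool,
                 risk_counts = risk_counts, settings = settings,
                 group_centers = group_centers,
                 home_range_km2 = home_range_km2, hotspot_q = hotspot_q,
                 selection_tolerance = selection_tolerance),
            class = "pipeline_config")
}

#' Full-size synthetic study configuration
#'
#' The study conditions of the synthetic system: a 16 km x 12 km landscape
#' on a 20 m grid, kilometer-grid plot campaign of 114 coarse + 277 fine =
#' 391 plots, eleven predictors (4 climate + 3 soil + 3 topography + 1
#' anthropogenic disturbance), forests of 1000 trees with 10-fold CV.
#'
#' @param seed global seed propagated to every stochastic stage.
#' @param ntree trees per forest (default 1000).
#' @return a `pipeline_config`.
#' @export
study_config <- function(seed = 1, ntree = 1000) {
  ls <- landscape_config(extent = c(0, 0, 16000, 12000), cell_size = 20,
                         correlation_length = 800, n_climate = 4, n_soil = 3,
                         seed = seed)
  pipeline_config(
    landscape = ls,
    n_coarse = 114, n_fine = 277,
    coarse_spacing = 1000, fine_spacing = 500,
    focal_zone = c(2000, 1500, 14000, 10500),
    settings = model_settings(ntree = ntree, cv_folds = 10, seed = seed)
  )
}

default_group_centers <- function(config) {
  fz <- config$focal_zone
  ex <- config$landscape$extent
  if (is.null(fz)) {
    mx <- (ex[3] - ex[1]) / 8; my <- (ex[4] - ex[2]) / 8
    fz <- c(ex[1] + mx, ex[2] + my, ex[3] - mx, ex[4] - my)
  }
  cx <- (fz[1] + fz[3]) / 2; cy <- (fz[2] + fz[4]) / 2
  sp <- min(900, (fz[3] - fz[1]) / 6)
  # four clustered groups plus one distant group (8 km east when it fits)
  ex_x <- min(cx + 8000, ex[3] - (fz[3] - fz[1]) / 20)
  data.frame(group = c("A", "B", "C", "D", "E"),
             x = c(cx - sp, cx + sp, cx - sp, cx + sp, ex_x),
             y = c(cy - sp, cy - sp, cy + sp, cy + sp, cy))
}

write_csv_ <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full diversity-mapping pipeline
#'
#' Simulate the landscape, census the plots, build the disturbance surface,
#' select predictors, fit and tune the random forest, bias-correct the
#' predicted surface, delineate hotspots and overlay them with the gibbon
#' home ranges — for both diversity indices (species richness and
#' Shannon-Wiener). Every intermediate artifact is written under `out_dir`
#' and listed, with md5 checksums, in the returned manifest
#' (`manifest.json`).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param write_rasters write the full raster artifacts (ASCII grids); turn
#'   off to keep only tables on very large landscapes.
#' @param quiet suppress stage progress messages.
#' @return the manifest, invisibly: per-index results (`models`,
#'   `selection`, `importance`, `varpart`, `bias`, `hotspots`, `overlap`)
#'   plus `files` with checksums.
#' @export
run_diversity_pipeline <- function(config = pipeline_config(),
                                   out_dir = tempfile("divscape_run_"),
                                   write_rasters = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character()
  keep <- function(path) { files[[length(files) + 1L]] <<- path; path }
  t0 <- Sys.time()

  say("[1/8] synthetic landscape")
  stack <- generate_predictor_stack(config$landscape)
  elements <- generate_risk_elements(config$landscape, config$risk_counts)
  say("[2/8] disturbance risk surface (%d elements)", length(elements))
  tmpl <- stack$rasters[[1]]
  disturbance <- build_risk_surface(tmpl, elements)
  stack <- stack_add(stack, "disturbance", disturbance, "anthropogenic")

  say("[3/8] plot layout and communities")
  layout <- generate_plot_layout(config$landscape, config$n_coarse,
                                 config$n_fine, config$focal_zone,
                                 coarse_spacing = config$coarse_spacing,
                                 fine_spacing = config$fine_spacing)
  comm <- simulate_communities(layout, stack, config$truth,
                               species_pool = config$species_pool,
                               seed = config$landscape$seed + 3L)
  say("[4/8] diversity indices for %d plots", nrow(layout))
  div <- compute_diversity_table(comm, layout)
  X_full <- extract_at_plots(stack, layout)

  keep(write_csv_(layout, file.path(out_dir, "plots.csv")))
  keep(write_csv_(as.data.frame(comm), file.path(out_dir, "communities.csv")))
  keep(write_csv_(div, file.path(out_dir, "diversity.csv")))
  keep(write_risk_geojson(elements, file.path(out_dir, "risk_elements.geojson")))
  if (write_rasters)
    keep(write_ascii_grid(disturbance, file.path(out_dir, "disturbance.asc")))

  centers <- config$group_centers
  if (is.null(centers)) centers <- default_group_centers(config)
  ranges <- build_home_ranges(centers, config$home_range_km2)
  keep(write_csv_(ranges, file.path(out_dir, "home_ranges.csv")))

  results <- list()
  for (index in c("richness", "shannon")) {
    say("[5/8] predictor selection (%s)", index)
    y <- div[[index]]
    sel <- select_predictors(X_full, y, config$settings,
                             tolerance = config$selection_tolerance)
    say("[6/8] tuned random forest (%s: %d predictors)", index,
        ncol(sel$X))
    model <- fit_tuned_forest(sel$X, y, config$settings)
    imp <- permutation_importance(model)
    vp <- variance_partitioning(sel$X, y, config$settings)
    bias <- estimate_bias(model)
    say("[7/8] diversity surface + hotspots (%s)", index)
    raw_surface <- predict_surface(model, stack)
    surface <- bias_correct(raw_surface, bias$a, bias$b)
    hot <- identify_hotspots(surface, config$hotspot_q)
    unc <- uncertainty_map(model, layout, tmpl)
    overlap <- overlay_hotspots(hot, ranges, index)

    pre <- file.path(out_dir, index)
    keep(write_csv_(model$cv_table, paste0(pre, "_cv_table.csv")))
    keep(write_csv_(imp, paste0(pre, "_importance.csv")))
    keep(write_csv_(vp$fractions, paste0(pre, "_varpart.csv")))
    keep(write_csv_(overlap, paste0(pre, "_overlap.csv")))
    sel_json <- c(sel$report[c("final_variables")],
                  list(dropped_by_correlation = sel$report$dropped_by_correlation,
                       dropped_by_vif = sel$report$dropped_by_vif,
                       elimination_path = sel$report$elimination_path,
                       bias = bias, chosen_mtry = model$mtry,
                       cv_metrics = model$metrics,
                       hotspot_threshold = hot$threshold))
    jsonlite::write_json(sel_json, keep(paste0(pre, "_model.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (write_rasters) {
      keep(write_ascii_grid(surface, paste0(pre, "_surface.asc")))
      keep(write_ascii_grid(hot$mask, paste0(pre, "_hotspots.asc")))
      keep(write_ascii_grid(unc$classes, paste0(pre, "_uncertainty.asc")))
    }
    results[[index]] <- list(model = model, selection = sel$report,
                             importance = imp, varpart = vp, bias = bias,
                             hotspots = hot, uncertainty = unc,
                             overlap = overlap)
  }

  say("[8/8] manifest")
  checks <- tools::md5sum(unlist(files))
  manifest <- list(
    seed = config$landscape$seed,
    n_plots = nrow(layout),
    predictors = colnames(X_full),
    indices = names(results),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = data.frame(file = basename(names(checks)),
                       md5 = unname(checks))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  out <- list(manifest = manifest, results = results, out_dir = out_dir,
              layout = layout, diversity = div, X = X_full,
              stack_names = names(stack$rasters))
  invisible(out)
}
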