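# Shared configuration for the analysis scripts (01 ... 06).
#
# One medium-sized synthetic reserve: 6 km x 4 km on the 20 m analysis grid,
# a two-tier plot campaign (60 coarse plots on a 500 m grid, 80 fine plots
# on a 250 m grid in the focal zone), eleven predictors in four groups and
# forests of 500 trees. Everything is seeded, so each script can regenerate
# the earlier stages deterministically instead of reloading them.

library(divscape)

ANALYSIS_SEED <- 7L

analysis_config <- function() {
  ls <- landscape_config(extent = c(0, 0, 6000, 4000), cell_size = 20,
                         correlation_length = 500, n_climate = 4, n_soil = 3,
                         seed = ANALYSIS_SEED)
  pipeline_config(
    landscape = ls,
    n_coarse = 60, n_fine = 80,
    coarse_spacing = 500, fine_spacing = 250,
    focal_zone = c(1000, 800, 5000, 3200),
    settings = model_settings(ntree = 500, cv_folds = 10,
                              seed = ANALYSIS_SEED)
  )
}

results_dir <- file.path("results")
scratch_dir <- file.path("scratch", "analysis")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(scratch_dir, showWarnings = FALSE, recursive = TRUE)

# deterministic rebuild of the landscape stages used by several scripts
build_landscape <- function(cfg = analysis_config()) {
  stack <- generate_predictor_stack(cfg$landscape)
  elements <- generate_risk_elements(cfg$landscape, cfg$risk_counts)
  disturbance <- build_risk_surface(stack$rasters[[1]], elements)
  stack <- stack_add(stack, "disturbance", disturbance, "anthropogenic")
  layout <- generate_plot_layout(cfg$landscape, cfg$n_coarse, cfg$n_fine,
                                 cfg$focal_zone,
                                 coarse_spacing = cfg$coarse_spacing,
                                 fine_spacing = cfg$fine_spacing)
  comm <- simulate_communities(layout, stack, cfg$truth,
                               species_pool = cfg$species_pool,
                               seed = cfg$landscape$seed + 3L)
  list(cfg = cfg, stack = stack, elements = elements,
       disturbance = disturbance, layout = layout, communities = comm)
}
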