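# shared fixture builders (all data generated in code)

# stack of constant-free layers built directly from matrices
stack_from_matrices <- function(mats, groups, cell_size = 20) {
  rasters <- lapply(mats, raster_grid, xmin = 0, ymin = 0,
                    cell_size = cell_size)
  predictor_stack(rasters, groups)
}

# small landscape config used across tests
tiny_config <- function(seed = 1, corr = 100) {
  landscape_config(extent = c(0, 0, 1000, 800), cell_size = 20,
                   correlation_length = corr, n_climate = 2, n_soil = 2,
                   seed = seed)
}

# random predictor matrix with independent standard-normal columns
rand_X <- function(n, p, seed = 1, prefix = "x") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("%s%02d", prefix, seq_len(p))))
  X
}

fast_settings <- function(ntree = 150, cv_folds = 5, seed = 1, mtry = NULL) {
  model_settings(ntree = ntree, mtry = mtry, cv_folds = cv_folds, seed = seed)
}

# independent point-to-segment distance used by brute-force oracles
oracle_seg_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / L2))
  sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2)
}
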