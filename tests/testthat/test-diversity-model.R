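strong_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      X <- rand_X(250, 5, seed = 40)
      y <- 15 + 3 * X[, "x01"]                  # exact monotone function
      cache <<- list(X = X, y = y,
                     model = fit_tuned_forest(X, y,
                       fast_settings(ntree = 250, mtry = c(2, 3, 5), seed = 2)))
    }
    cache
  }
})

test_that("a noiseless monotone signal is learned with high CV R2", {
  sf <- strong_fit()
  expect_gt(sf$model$metrics$r2, 0.9)
  # chosen mtry attains the minimum CV RMSE of the candidate table
  expect_equal(sf$model$cv_table$mtry[which.min(sf$model$cv_table$rmse)],
               sf$model$mtry)
  expect_equal(sum(sf$model$cv_table$best3), 3L)
})

test_that("pure-noise responses give near-zero CV R2", {
  set.seed(41)
  X <- rand_X(400, 5, seed = 42)
  y <- rnorm(400)
  m <- fit_tuned_forest(X, y, fast_settings(ntree = 200, mtry = 2, seed = 3))
  expect_lt(abs(m$metrics$r2), 0.1)
})

test_that("mtry candidate handling is faithful", {
  X <- rand_X(60, 3, seed = 43)
  y <- X[, 1] + rnorm(60, sd = 0.1)
  m <- fit_tuned_forest(X, y, fast_settings(ntree = 80, mtry = 2, seed = 1))
  expect_equal(m$mtry, 2L)                      # single candidate is chosen
  expect_warning(
    m2 <- fit_tuned_forest(X, y, fast_settings(ntree = 80, mtry = c(2, 9),
                                               seed = 1)),
    "skipped")
  expect_equal(m2$cv_table$mtry, 2L)
})

test_that("permutation importance ranks the informative predictor first", {
  set.seed(44)
  n <- 200
  X <- rand_X(n, 5, seed = 45)
  y <- 2.5 * X[, "x02"] + rnorm(n, sd = 0.4)
  m <- fit_tuned_forest(X, y, fast_settings(ntree = 300, mtry = 2, seed = 4))
  imp <- permutation_importance(m)
  expect_equal(imp$predictor[1], "x02")
  expect_true(imp$crucial[1])
  # agrees with randomForest's own importance on the leading predictor
  rf_imp <- randomForest::importance(m$forest, type = 1)
  expect_equal(rownames(rf_imp)[which.max(rf_imp)], "x02")
  # identical across repeated calls (seeded)
  expect_identical(imp, permutation_importance(m))
})

test_that("a constant predictor has (near-)zero permutation importance", {
  set.seed(46)
  n <- 150
  X <- cbind(rand_X(n, 3, seed = 47), flat = rep(1.5, n))
  y <- X[, 1] + rnorm(n, sd = 0.3)
  forest <- divscape:::fit_forest(X, y, 2, 200, seed = 5)
  imp <- oob_permutation_importance(forest, X, y, seed = 5)
  expect_equal(imp$inc_mse[imp$predictor == "flat"], 0, tolerance = 1e-10)
})

test_that("partial dependence tracks monotone signals and stays flat on null ones", {
  sf <- strong_fit()
  pd <- partial_dependence(sf$model, "x01", grid_size = 20)
  expect_gt(cor(pd$value, pd$prediction, method = "spearman"), 0.9)
  pd_null <- partial_dependence(sf$model, "x04", grid_size = 20)
  expect_lt(max(pd_null$prediction) - min(pd_null$prediction),
            0.1 * sd(sf$y))
  pd1 <- partial_dependence(sf$model, "x01", grid_size = 1)
  expect_equal(nrow(pd1), 1L)
  expect_equal(pd1$prediction,
               mean(predict(sf$model$forest, as.data.frame(sf$X))),
               tolerance = 1e-9)
  expect_error(partial_dependence(sf$model, "nope"), "unknown predictor")
})

test_that("variance partitioning fractions sum to the full-model CV R2", {
  set.seed(48)
  n <- 150
  X <- rand_X(n, 6, seed = 49)
  groups <- c(x01 = "climate", x02 = "climate", x03 = "soil", x04 = "soil",
              x05 = "topography", x06 = "topography")
  attr(X, "groups") <- groups
  y <- 1.5 * X[, "x01"] + rnorm(n, sd = 0.5)
  vp <- variance_partitioning(X, y, fast_settings(ntree = 120, seed = 6))
  expect_equal(sum(vp$fractions$fraction), vp$full_r2, tolerance = 1e-9)
  expect_equal(nrow(vp$fractions), 2^3 - 1)
  # y driven by one climate variable: climate-unique is the largest atom
  expect_equal(vp$fractions$component[which.max(vp$fractions$fraction)],
               "climate")
})

test_that("a driver duplicated across two groups shows up as shared variance", {
  set.seed(50)
  n <- 150
  z <- rnorm(n)
  X <- cbind(a1 = z + rnorm(n, sd = 0.05), b1 = z + rnorm(n, sd = 0.05),
             a2 = rnorm(n), b2 = rnorm(n))
  attr(X, "groups") <- c(a1 = "climate", b1 = "soil", a2 = "climate",
                         b2 = "soil")
  y <- 2 * z + rnorm(n, sd = 0.3)
  vp <- variance_partitioning(X, y, fast_settings(ntree = 120, seed = 7))
  fr <- setNames(vp$fractions$fraction, vp$fractions$component)
  expect_gt(fr[["climate:soil"]], fr[["climate"]])
  expect_gt(fr[["climate:soil"]], fr[["soil"]])
})

test_that("a single predictor group carries the full model R2", {
  X <- rand_X(100, 3, seed = 51)
  attr(X, "groups") <- c(x01 = "climate", x02 = "climate", x03 = "climate")
  y <- X[, 1] + rnorm(100, sd = 0.4)
  vp <- variance_partitioning(X, y, fast_settings(ntree = 120, seed = 8))
  expect_equal(nrow(vp$fractions), 1L)
  expect_equal(vp$fractions$fraction, vp$full_r2)
})

test_that("bias correction matches hand values and round-trips the calibration", {
  surf <- raster_grid(matrix(c(7, 3, 0, 12), 2, 2), 0, 0, 20)
  out <- bias_correct(surf, a = 0.5, b = 2)
  expect_equal(out$values[1, 1], 10)            # (7 - 2) / 0.5
  expect_equal(out$values[2, 1], 2)
  expect_equal(bias_correct(surf, 1, 0)$values, surf$values)  # identity
  expect_equal(bias_correct(surf, 1, 5)$values[1, 2], 0)      # clamped
  expect_error(bias_correct(surf, 0, 1), "degenerate")

  # fitted (a, b) then the inverse correction: OLS of corrected on observed
  # recovers slope 1, intercept 0 when nothing clamps
  sf <- strong_fit()
  bias <- estimate_bias(sf$model)
  expect_gt(abs(bias$a), 1e-8)
  corrected <- (sf$model$cv_predictions - bias$b) / bias$a
  expect_true(all(corrected > 0))
  fit <- lm(corrected ~ sf$model$y)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-6)
})

test_that("surface prediction propagates nodata and honors training rows", {
  X <- rand_X(80, 3, seed = 52)
  y <- X[, 1] + rnorm(80, sd = 0.2)
  m <- fit_tuned_forest(X, y, fast_settings(ntree = 100, mtry = 2, seed = 9))
  # stack constant at training row 1 -> constant surface at that prediction
  mats <- lapply(colnames(X), function(nm) matrix(X[1, nm], 4, 5))
  names(mats) <- colnames(X)
  st <- stack_from_matrices(mats, setNames(rep("climate", 3), colnames(X)))
  surf <- predict_surface(m, st)
  expect_equal(surf$values,
               matrix(predict(m$forest, as.data.frame(X[1, , drop = FALSE])),
                      4, 5),
               tolerance = 1e-12)
  # nodata in one layer -> nodata in the output there
  mats$x02[2, 3] <- NA
  stna <- stack_from_matrices(mats, setNames(rep("climate", 3), colnames(X)))
  surfna <- predict_surface(m, stna)
  expect_true(is.na(surfna$values[2, 3]))
  expect_equal(sum(is.na(surfna$values)), 1L)
  st_missing <- stack_from_matrices(mats[1:2],
                                    setNames(rep("climate", 2), colnames(X)[1:2]))
  expect_error(predict_surface(m, st_missing), "x03")
})

test_that("uncertainty maps classify residual terciles and degenerate ties", {
  X <- rand_X(60, 3, seed = 53)
  y <- X[, 1] + rnorm(60, sd = 0.3)
  m <- fit_tuned_forest(X, y, fast_settings(ntree = 100, mtry = 2, seed = 10))
  set.seed(54)
  plots <- data.frame(x = runif(60, 0, 400), y = runif(60, 0, 400))
  tmpl <- raster_grid(matrix(0, 20, 20), 0, 0, 20)
  um <- uncertainty_map(m, plots, tmpl)
  counts <- table(um$classes$values)
  expect_equal(length(counts), 3L)
  expect_true(all(abs(counts / 400 - 1 / 3) < 0.05))
  expect_length(um$levels, 3L)

  # all residuals equal -> constant surface -> everything Strongly predictive
  m_const <- m
  m_const$cv_predictions <- m$y + 0.7
  um2 <- uncertainty_map(m_const, plots, tmpl)
  expect_true(all(um2$classes$values == 1))
  expect_error(uncertainty_map(m, plots[1:2, ], tmpl), "at least 3")
})
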