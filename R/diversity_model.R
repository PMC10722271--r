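#' Random-forest model settings
#'
#' @param ntree trees per forest (default 1000).
#' @param mtry integer vector of candidate values for the number of
#'   predictors tried at each split; `NULL` picks a small ladder spanning
#'   2 .. p at fit time. Candidates larger than the predictor count are
#'   skipped with a warning.
#' @param cv_folds folds for cross-validation (default 10).
#' @param seed integer seed controlling fold assignment and forest fitting.
#' @return an object of class `model_settings`.
#' @export
model_settings <- function(ntree = 1000, mtry = NULL, cv_folds = 10, seed = 1) {
  if (ntree < 1) stop("ntree must be >= 1")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "model_settings")
}

default_mtry_ladder <- function(p) {
  sort(unique(pmax(1L, pmin(p, c(2L, floor(p / 3), floor(p / 2),
                                 floor(2 * p / 3), p)))))
}

#' Cross-validation fold assignment stratified by response deciles
#'
#' Stratification keeps each fold's response distribution comparable, which
#' stabilizes CV metrics at moderate n.
#'
#' @param y response vector.
#' @param k number of folds.
#' @param seed integer seed; the assignment is a pure function of (y, k,
#'   seed).
#' @return integer vector of fold ids in 1..k.
#' @export
make_cv_folds <- function(y, k, seed) {
  set.seed(seed)
  n <- length(y)
  strata <- as.integer(cut(rank(y, ties.method = "first"),
                           breaks = min(10L, max(1L, n %/% k)),
                           labels = FALSE))
  folds <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

fit_forest <- function(X, y, mtry, ntree, seed, keep_inbag = TRUE) {
  set.seed(seed)
  randomForest::randomForest(x = as.data.frame(X), y = y, ntree = ntree,
                             mtry = mtry, keep.inbag = keep_inbag,
                             importance = TRUE)
}

#' Cross-validated metrics of one forest configuration
#'
#' Pools held-out predictions over all folds; R2 = 1 - SSE/SST of the
#' pooled predictions (can be negative for uninformative models).
#'
#' @param X predictor matrix; `y` response.
#' @param mtry predictors tried per split.
#' @param folds fold ids from [make_cv_folds()].
#' @param ntree trees per fold model.
#' @param seed integer seed.
#' @return list with `r2`, `mae`, `rmse` and the pooled CV `predictions`.
#' @export
cv_forest_metrics <- function(X, y, mtry, folds, ntree, seed) {
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit <- fit_forest(X[!hold, , drop = FALSE], y[!hold], mtry, ntree,
                      seed + f, keep_inbag = FALSE)
    pred[hold] <- stats::predict(fit, as.data.frame(X[hold, , drop = FALSE]))
  }
  res <- y - pred
  list(r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)),
       predictions = pred)
}

#' Fit a tuned random-forest diversity model
#'
#' Evaluates every candidate mtry by k-fold cross-validation under one
#' fixed fold assignment, picks the minimum-RMSE candidate, refits it on
#' all data, and records the CV table (the three best candidates are
#' flagged). The returned object carries the pooled CV predictions of the
#' chosen configuration, used later for bias calibration and the residual
#' uncertainty map.
#'
#' @param X numeric predictor matrix (plots x predictors) with optional
#'   `groups` attribute.
#' @param y response vector (plot diversity index).
#' @param settings a [model_settings()].
#' @return an object of class `divscape_model` with elements `forest`,
#'   `mtry`, `cv_table`, `cv_predictions`, `metrics` (chosen candidate),
#'   `X`, `y`, `groups`, `settings`.
#' @export
fit_tuned_forest <- function(X, y, settings = model_settings()) {
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (length(y) < 20) stop("need at least 20 observations")
  p <- ncol(X)
  cand <- if (is.null(settings$mtry)) default_mtry_ladder(p)
          else as.integer(settings$mtry)
  if (any(cand > p)) {
    warning("mtry candidates above the predictor count skipped: ",
            paste(cand[cand > p], collapse = ", "))
    cand <- cand[cand <= p]
  }
  if (length(cand) == 0) stop("no valid mtry candidate")
  folds <- make_cv_folds(y, settings$cv_folds, settings$seed)
  rows <- lapply(cand, function(m) {
    met <- cv_forest_metrics(X, y, m, folds, settings$ntree, settings$seed)
    list(met = met,
         row = data.frame(mtry = m, r2 = met$r2, mae = met$mae,
                          rmse = met$rmse))
  })
  cv_table <- do.call(rbind, lapply(rows, `[[`, "row"))
  cv_table$best3 <- rank(cv_table$rmse, ties.method = "first") <= 3
  best <- which.min(cv_table$rmse)
  forest <- fit_forest(X, y, cand[best], settings$ntree, settings$seed)
  structure(list(forest = forest, mtry = cand[best], cv_table = cv_table,
                 cv_predictions = rows[[best]]$met$predictions,
                 metrics = rows[[best]]$met[c("r2", "mae", "rmse")],
                 folds = folds, X = X, y = y,
                 groups = attr(X, "groups"), settings = settings),
            class = "divscape_model")
}

#' @export
print.divscape_model <- function(x, ...) {
  cat(sprintf("divscape_model: %d obs, %d predictors, ntree=%d, mtry=%d\n",
              nrow(x$X), ncol(x$X), x$settings$ntree, x$mtry))
  cat(sprintf("  %d-fold CV: R2=%.3f MAE=%.3f RMSE=%.3f\n",
              x$settings$cv_folds, x$metrics$r2, x$metrics$mae,
              x$metrics$rmse))
  invisible(x)
}

#' Out-of-bag permutation importance (%IncMSE)
#'
#' For each predictor: permute its column once (seeded), re-predict every
#' tree on its own out-of-bag samples, and report the percent increase of
#' the mean per-tree OOB MSE over the unpermuted baseline. Predictors above
#' the `threshold` (15% by convention) are flagged as crucial.
#'
#' @param forest a `randomForest` fitted with `keep.inbag = TRUE`.
#' @param X,y training data.
#' @param seed seed for the permutations.
#' @param threshold crucial-importance flag threshold in percent.
#' @return data.frame `predictor`, `inc_mse` (percent), `crucial`, sorted
#'   by decreasing importance.
#' @export
oob_permutation_importance <- function(forest, X, y, seed = 1, threshold = 15) {
  if (is.null(forest$inbag)) stop("forest must be fitted with keep.inbag = TRUE")
  Xd <- as.data.frame(X)
  base_pred <- stats::predict(forest, Xd, predict.all = TRUE)$individual
  oob <- forest$inbag == 0
  usable <- colSums(oob) > 0
  tree_mse <- function(pred) {
    err <- (pred - y)^2
    colSums(err * oob)[usable] / colSums(oob)[usable]
  }
  base_mse <- mean(tree_mse(base_pred))
  set.seed(seed)
  inc <- vapply(colnames(X), function(nm) {
    Xp <- Xd
    Xp[[nm]] <- Xp[[nm]][sample.int(nrow(Xp))]
    perm_pred <- stats::predict(forest, Xp, predict.all = TRUE)$individual
    100 * (mean(tree_mse(perm_pred)) - base_mse) / base_mse
  }, numeric(1))
  out <- data.frame(predictor = names(inc), inc_mse = unname(inc),
                    crucial = unname(inc) > threshold)
  out[order(-out$inc_mse), , drop = FALSE]
}

#' Permutation importance of a fitted diversity model
#'
#' @param result a `divscape_model`.
#' @param threshold crucial flag threshold in percent (default 15).
#' @return see [oob_permutation_importance()].
#' @export
permutation_importance <- function(result, threshold = 15) {
  oob_permutation_importance(result$forest, result$X, result$y,
                             seed = result$settings$seed,
                             threshold = threshold)
}

#' Univariate partial dependence
#'
#' Mean model prediction over the training rows with one predictor fixed
#' at each of `grid_size` values spanning its observed range.
#'
#' @param result a `divscape_model`.
#' @param predictor predictor name.
#' @param grid_size number of grid values.
#' @return data.frame with columns `value` and `prediction`.
#' @export
partial_dependence <- function(result, predictor, grid_size = 25) {
  if (!predictor %in% colnames(result$X))
    stop("unknown predictor: ", predictor)
  rng <- range(result$X[, predictor])
  Xd <- as.data.frame(result$X)
  if (grid_size == 1L) {
    # degenerate grid: no value to vary, report the mean training prediction
    return(data.frame(value = mean(result$X[, predictor]),
                      prediction = mean(stats::predict(result$forest, Xd))))
  }
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  pred <- vapply(grid, function(v) {
    Xd[[predictor]] <- v
    mean(stats::predict(result$forest, Xd))
  }, numeric(1))
  data.frame(value = grid, prediction = pred)
}

#' Variance partitioning over predictor groups
#'
#' Fits one cross-validated forest per nonempty subset of the predictor
#' groups (at most 15 models for 4 groups) and decomposes the full-model
#' CV R2 into unique and shared fractions by inclusion-exclusion over the
#' subset lattice. Fractions can be slightly negative (a known property of
#' this decomposition); they are retained in `fractions` and only hidden in
#' the reporting column `shown`, which mirrors the convention of displaying
#' fractions above 1% only.
#'
#' @param X predictor matrix with a `groups` attribute (or pass `groups`).
#' @param y response vector.
#' @param settings a [model_settings()]; subset forests use
#'   `floor(p/3)` mtry.
#' @param groups optional named group vector over columns of X.
#' @param show_threshold fractions at or below this are flagged hidden
#'   (default 0.01).
#' @return an object of class `variance_partition`: data.frame `fractions`
#'   (`component`, `fraction`, `shown`), `subset_r2` table, `full_r2`.
#' @export
variance_partitioning <- function(X, y, settings = model_settings(),
                                  groups = NULL, show_threshold = 0.01) {
  if (is.null(groups)) groups <- attr(X, "groups")
  if (is.null(groups)) stop("X needs a groups attribute (or pass groups)")
  groups <- groups[colnames(X)]
  gnames <- unique(unname(groups))
  k <- length(gnames)
  if (k < 1) stop("need at least one predictor group")
  folds <- make_cv_folds(y, settings$cv_folds, settings$seed)
  n_masks <- bitwShiftL(1L, k)
  group_in <- function(mask) gnames[bitwAnd(bitwShiftL(1L, seq_len(k) - 1L), mask) != 0]
  r2 <- numeric(n_masks)           # index mask + 1; empty set = 0
  subset_rows <- list()
  for (mask in seq_len(n_masks - 1L)) {
    cols <- names(groups)[groups %in% group_in(mask)]
    Xs <- X[, cols, drop = FALSE]
    m <- max(1L, floor(ncol(Xs) / 3))
    r2[mask + 1L] <- cv_forest_metrics(Xs, y, m, folds, settings$ntree,
                                       settings$seed)$r2
    subset_rows[[mask]] <- data.frame(
      subset = paste(group_in(mask), collapse = "+"),
      n_predictors = length(cols), r2 = r2[mask + 1L])
  }
  full_mask <- n_masks - 1L
  full_r2 <- r2[full_mask + 1L]
  # g(V) = R2(all) - R2(complement of V); Moebius inversion gives the
  # Venn-diagram atom for every nonempty group combination
  g <- vapply(0:full_mask, function(v)
    full_r2 - r2[bitwAnd(full_mask, bitwNot(v)) + 1L], numeric(1))
  atoms <- vapply(seq_len(full_mask), function(t_mask) {
    v <- t_mask; total <- 0
    repeat {
      sign <- (-1)^(bit_count(t_mask) - bit_count(v))
      total <- total + sign * g[v + 1L]
      if (v == 0L) break
      v <- bitwAnd(v - 1L, t_mask)
    }
    total
  }, numeric(1))
  comp <- vapply(seq_len(full_mask),
                 function(m) paste(group_in(m), collapse = ":"), character(1))
  fractions <- data.frame(component = comp, fraction = atoms,
                          shown = atoms > show_threshold)
  fractions$residual <- NULL
  structure(list(fractions = fractions,
                 residual = 1 - full_r2,
                 subset_r2 = do.call(rbind, subset_rows),
                 full_r2 = full_r2),
            class = "variance_partition")
}

bit_count <- function(x) {
  n <- 0L
  while (x > 0L) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  n
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("variance_partition: full-model CV R2 = %.3f\n", x$full_r2))
  shown <- x$fractions[x$fractions$shown, , drop = FALSE]
  for (i in seq_len(nrow(shown)))
    cat(sprintf("  %-40s %6.3f\n", shown$component[i], shown$fraction[i]))
  cat(sprintf("  %-40s %6.3f\n", "residual", x$residual))
  invisible(x)
}

#' Predict the diversity surface over a raster stack
#'
#' @param result a `divscape_model`.
#' @param stack `predictor_stack` containing every model predictor.
#' @return `raster_grid` of per-cell predictions; cells with nodata in any
#'   predictor are nodata.
#' @export
predict_surface <- function(result, stack) {
  need <- colnames(result$X)
  missing <- setdiff(need, names(stack$rasters))
  if (length(missing) > 0)
    stop("stack is missing model predictors: ", paste(missing, collapse = ", "))
  tmpl <- stack$rasters[[need[1]]]
  cols <- lapply(need, function(nm) as.vector(t(stack$rasters[[nm]]$values)))
  M <- do.call(cbind, cols)
  colnames(M) <- need
  ok <- stats::complete.cases(M)
  pred <- rep(NA_real_, nrow(M))
  if (any(ok)) {
    df <- as.data.frame(M[ok, , drop = FALSE])
    # chunked prediction keeps peak memory modest on large grids
    idx <- split(seq_len(nrow(df)), ceiling(seq_len(nrow(df)) / 100000))
    pred[ok] <- unlist(lapply(idx, function(ii)
      stats::predict(result$forest, df[ii, , drop = FALSE])),
      use.names = FALSE)
  }
  raster_grid(matrix(pred, nrow(tmpl$values), ncol(tmpl$values), byrow = TRUE),
              tmpl$xmin, tmpl$ymin, tmpl$cell_size, tmpl$crs)
}

#' Estimate linear bias-calibration parameters
#'
#' Ensemble-tree regressions pull predictions toward the sample mean
#' (overestimating low and underestimating high diversity). The calibration
#' line Sfit = a * Sobs + b is fitted by OLS of the model's cross-validated
#' predictions on the observations; inverting it spreads the predicted
#' surface back to the observed scale.
#'
#' @param result a `divscape_model`.
#' @return list with slope `a` and intercept `b`.
#' @export
estimate_bias <- function(result) {
  fit <- stats::lm(result$cv_predictions ~ result$y)
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
}

#' Bias-correct a predicted surface
#'
#' Applies the inverse calibration corrected = max((value - b) / a, 0) per
#' cell. Cells whose corrected value would be negative are clamped to 0
#' (keeping them in the raster so the hotspot quantile sees them).
#'
#' @param surface `raster_grid` of raw model predictions.
#' @param a,b calibration slope and intercept (from [estimate_bias()]).
#' @return corrected `raster_grid` with attributes `bias_a`, `bias_b`.
#' @export
bias_correct <- function(surface, a, b) {
  if (abs(a) < 1e-8) stop("degenerate bias calibration: |a| < 1e-8")
  out <- surface
  out$values <- pmax((surface$values - b) / a, 0)
  attr(out, "bias_a") <- a
  attr(out, "bias_b") <- b
  out
}

#' Inverse-distance-weighted interpolation of point values
#'
#' @param template `raster_grid` defining the output grid.
#' @param x,y,values point locations and values.
#' @param power IDW power (default 2).
#' @return `raster_grid`.
#' @export
idw_interpolate <- function(template, x, y, values, power = 2) {
  ctr <- cell_centers(template)
  out <- numeric(nrow(ctr))
  chunks <- split(seq_len(nrow(ctr)), ceiling(seq_len(nrow(ctr)) / 20000))
  for (ii in chunks) {
    d2 <- outer(ctr$x[ii], x, "-")^2 + outer(ctr$y[ii], y, "-")^2
    d <- sqrt(d2)
    w <- 1 / d^power
    exact <- d < 1e-9
    v <- (w %*% values) / rowSums(w)
    hit <- which(rowSums(exact) > 0)
    if (length(hit) > 0)
      v[hit] <- values[apply(exact[hit, , drop = FALSE], 1L, which.max)]
    out[ii] <- v
  }
  m <- matrix(out, nrow(template$values), ncol(template$values), byrow = TRUE)
  m[is.na(template$values)] <- NA_real_
  raster_grid(m, template$xmin, template$ymin, template$cell_size,
              template$crs)
}

#' Residual-based prediction uncertainty map
#'
#' Absolute cross-validated residuals at the plots are interpolated to the
#' full grid by inverse-distance weighting and classified into three levels
#' by terciles of the interpolated surface: low residual = "Strongly
#' predictive", high residual = "Less predictive". With a degenerate
#' (constant) residual surface every cell is "Strongly predictive".
#'
#' @param result a `divscape_model`.
#' @param plots plot table with `x`, `y` in model row order.
#' @param template `raster_grid` defining the output grid.
#' @param power IDW power (default 2).
#' @return list with `residual_surface` (`raster_grid`), `classes`
#'   (`raster_grid` of codes 1..3), `levels` (code labels) and the tercile
#'   `breaks`.
#' @export
uncertainty_map <- function(result, plots, template, power = 2) {
  if (nrow(plots) < 3) stop("need at least 3 plots for an uncertainty map")
  resid <- abs(result$y - result$cv_predictions)
  surf <- idw_interpolate(template, plots$x, plots$y, resid, power)
  v <- surf$values[!is.na(surf$values)]
  breaks <- stats::quantile(v, c(1, 2) / 3, names = FALSE)
  cls <- surf
  cls$values <- matrix(NA_real_, nrow(surf$values), ncol(surf$values))
  ok <- !is.na(surf$values)
  # epsilon guards against numerically-degenerate (near-constant) surfaces
  eps <- 1e-9 * max(abs(breaks), 1)
  cls$values[ok] <- 1 + (surf$values[ok] > breaks[1] + eps) +
    (surf$values[ok] > breaks[2] + eps)
  list(residual_surface = surf, classes = cls,
       levels = c("Strongly predictive", "Moderately predictive",
                  "Less predictive"),
       breaks = breaks)
}
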