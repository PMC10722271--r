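#' Extract predictor values at plot locations
#'
#' Value of the cell containing each plot center (plots are 20 m squares
#' aligned to the 20 m analysis grid, so no interpolation is involved).
#'
#' @param stack a `predictor_stack`.
#' @param plots data.frame with `plot_id`, `x`, `y`.
#' @return numeric matrix (plots x predictors) with plot ids as row names
#'   and a `groups` attribute carrying each column's predictor group.
#' @export
extract_at_plots <- function(stack, plots) {
  X <- vapply(stack$rasters,
              function(r) extract_xy(r, plots$x, plots$y),
              numeric(nrow(plots)))
  X <- matrix(X, nrow = nrow(plots),
              dimnames = list(plots$plot_id, names(stack$rasters)))
  if (anyNA(X)) {
    bad <- plots$plot_id[apply(is.na(X), 1L, any)]
    stop("plots on nodata cells: ", paste(bad, collapse = ", "))
  }
  attr(X, "groups") <- stack$groups
  X
}

new_selection_report <- function(variables) {
  structure(list(dropped_by_correlation = data.frame(variable = character(),
                                                     abs_r = numeric(),
                                                     partner = character()),
                 dropped_by_vif = data.frame(variable = character(),
                                             vif = numeric()),
                 elimination_path = data.frame(removed = character(),
                                               cv_rmse = numeric()),
                 final_variables = variables),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report\n")
  cat("  dropped by |r|:", paste(x$dropped_by_correlation$variable,
                                 collapse = ", "), "\n")
  cat("  dropped by VIF:", paste(x$dropped_by_vif$variable, collapse = ", "), "\n")
  cat("  eliminated:", paste(setdiff(x$elimination_path$removed, "(none)"),
                             collapse = ", "), "\n")
  cat("  final:", paste(x$final_variables, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise-correlation predictor filter
#'
#' Iteratively removes predictors until no pair has |Pearson r| above the
#' threshold. Of each offending pair, the member with the larger mean
#' absolute correlation to all remaining variables is dropped; ties break
#' alphabetically (the later name goes). Zero-variance columns are dropped
#' up front with a warning.
#'
#' @param X numeric predictor matrix with column names.
#' @param threshold maximum allowed |r| (default 0.85).
#' @param report optional `selection_report` to update.
#' @return list with `X` (filtered matrix) and `report`.
#' @export
correlation_filter <- function(X, threshold = 0.85, report = NULL) {
  if (is.null(report)) report <- new_selection_report(colnames(X))
  groups <- attr(X, "groups")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance predictors: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  repeat {
    if (ncol(X) < 2L) break
    r <- abs(stats::cor(X))
    diag(r) <- 0
    if (max(r) <= threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1L, ]
    pair <- colnames(X)[worst]
    mean_abs <- colMeans(r)[pair]
    drop <- if (abs(diff(mean_abs)) > 1e-12) pair[which.max(mean_abs)]
            else sort(pair)[2L]
    keep_partner <- setdiff(pair, drop)
    report$dropped_by_correlation <- rbind(
      report$dropped_by_correlation,
      data.frame(variable = drop, abs_r = max(r), partner = keep_partner))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  if (!is.null(groups)) attr(X, "groups") <- groups[colnames(X)]
  report$final_variables <- colnames(X)
  list(X = X, report = report)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), with R2_j from regressing predictor j on all
#' others; computed from the inverse correlation matrix. Exactly collinear
#' columns get VIF = Inf.
#'
#' @param X numeric matrix with >= 2 columns.
#' @return named numeric vector of VIFs.
#' @export
vif_values <- function(X) {
  if (ncol(X) < 2L) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  R <- stats::cor(X)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(inv) && all(diag(inv) > 0)) {
    return(stats::setNames(diag(inv), colnames(X)))
  }
  # singular correlation matrix: fall back to per-column regressions
  vapply(stats::setNames(seq_len(ncol(X)), colnames(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative VIF predictor filter
#'
#' Removes the predictor with the largest VIF while that VIF is at or above
#' the threshold, recomputing after each removal; the surviving set has all
#' VIF below threshold. Exact collinearity (infinite VIF) is removed
#' deterministically (alphabetically last among the infinite ones) with a
#' warning.
#'
#' @inheritParams correlation_filter
#' @param threshold maximum tolerated VIF (default 10).
#' @return list with `X` and `report`.
#' @export
vif_filter <- function(X, threshold = 10, report = NULL) {
  if (is.null(report)) report <- new_selection_report(colnames(X))
  groups <- attr(X, "groups")
  repeat {
    if (ncol(X) < 2L) break
    v <- vif_values(X)
    if (max(v) < threshold) break
    if (any(is.infinite(v))) {
      drop <- sort(names(v)[is.infinite(v)], decreasing = TRUE)[1L]
      warning("exactly collinear predictor removed: ", drop)
    } else {
      drop <- names(v)[which.max(v)]
    }
    report$dropped_by_vif <- rbind(report$dropped_by_vif,
                                   data.frame(variable = drop, vif = v[[drop]]))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  if (!is.null(groups)) attr(X, "groups") <- groups[colnames(X)]
  report$final_variables <- colnames(X)
  list(X = X, report = report)
}

#' Permutation-importance backward elimination
#'
#' Starting from the full predictor set, repeatedly drops the predictor
#' with the lowest %IncMSE (out-of-bag permutation importance) and refits,
#' accepting a removal only while the cross-validated RMSE does not worsen
#' by more than `tolerance` (relative). The first rejected removal restores
#' the previous set and stops the search. With `tolerance = -Inf` no
#' removal is ever accepted.
#'
#' @param X numeric predictor matrix (already correlation/VIF filtered).
#' @param y response vector (one diversity index over plots).
#' @param settings a [model_settings()]; the elimination uses its `ntree`,
#'   fold count and seed (fixed fold assignment across steps).
#' @param tolerance maximum tolerated relative CV-RMSE increase per
#'   removal (default 0.01).
#' @param min_predictors stop when this many predictors remain.
#' @param report optional `selection_report` to update.
#' @return list with `X`, `report`.
#' @export
backward_elimination <- function(X, y, settings = model_settings(),
                                 tolerance = 0.01, min_predictors = 2L,
                                 report = NULL) {
  if (is.null(report)) report <- new_selection_report(colnames(X))
  groups <- attr(X, "groups")
  if (ncol(X) < 2L) {
    report$final_variables <- colnames(X)
    return(list(X = X, report = report))
  }
  folds <- make_cv_folds(y, settings$cv_folds, settings$seed)
  mtry_for <- function(p) max(1L, min(floor(p / 3), p))
  cv_rmse <- function(Xc) {
    cv_forest_metrics(Xc, y, mtry = mtry_for(ncol(Xc)), folds = folds,
                      ntree = settings$ntree, seed = settings$seed)$rmse
  }
  current <- X
  rmse_cur <- cv_rmse(current)
  report$elimination_path <- data.frame(removed = "(none)", cv_rmse = rmse_cur)
  while (ncol(current) > min_predictors) {
    imp <- oob_permutation_importance(
      fit_forest(current, y, mtry_for(ncol(current)), settings$ntree,
                 settings$seed),
      current, y, seed = settings$seed)
    candidate <- imp$predictor[which.min(imp$inc_mse)]
    trial <- current[, setdiff(colnames(current), candidate), drop = FALSE]
    rmse_new <- cv_rmse(trial)
    if (!((rmse_new - rmse_cur) / rmse_cur <= tolerance)) break
    current <- trial
    rmse_cur <- rmse_new
    report$elimination_path <- rbind(report$elimination_path,
                                     data.frame(removed = candidate,
                                                cv_rmse = rmse_new))
  }
  if (!is.null(groups)) attr(current, "groups") <- groups[colnames(current)]
  report$final_variables <- colnames(current)
  list(X = current, report = report)
}

#' Full predictor-selection pass
#'
#' Correlation filter, VIF filter and backward elimination in sequence,
#' accumulating one report.
#'
#' @inheritParams backward_elimination
#' @param cor_threshold maximum pairwise |r| (default 0.85).
#' @param vif_threshold maximum VIF (default 10).
#' @return list with `X` (selected predictor matrix) and `report`.
#' @export
select_predictors <- function(X, y, settings = model_settings(),
                              cor_threshold = 0.85, vif_threshold = 10,
                              tolerance = 0.01) {
  s1 <- correlation_filter(X, cor_threshold)
  s2 <- vif_filter(s1$X, vif_threshold, s1$report)
  backward_elimination(s2$X, y, settings, tolerance, report = s2$report)
}
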