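#' Species richness of one plot
#'
#' Number of distinct woody-plant species with at least one stem.
#'
#' @param abundances named or unnamed vector of per-species stem counts
#'   (each >= 1).
#' @param plot_id optional id used in error messages.
#' @return integer richness S.
#' @export
species_richness <- function(abundances, plot_id = NULL) {
  check_abundances(abundances, plot_id)
  sum(abundances >= 1)
}

#' Shannon-Wiener diversity of one plot
#'
#' H = -sum(p_i * ln p_i) in nats, with p_i the proportion of stems
#' belonging to species i. Higher values mean more, and more evenly
#' distributed, species; H is 0 for a monoculture and ln(S) when all S
#' species are equally abundant.
#'
#' @inheritParams species_richness
#' @return nonnegative numeric H (nats).
#' @export
shannon_index <- function(abundances, plot_id = NULL) {
  check_abundances(abundances, plot_id)
  p <- abundances / sum(abundances)
  # 0 * log(0) treated as 0 (species with zero stems contribute nothing)
  p <- p[p > 0]
  max(0, -sum(p * log(p)))
}

check_abundances <- function(abundances, plot_id) {
  where <- if (is.null(plot_id)) "" else sprintf(" in plot %s", plot_id)
  if (length(abundances) == 0 || sum(abundances) <= 0)
    stop("no stems recorded", where)
  if (any(abundances < 0)) stop("negative abundance", where)
  invisible(TRUE)
}

#' Per-plot diversity table
#'
#' Computes species richness and the Shannon-Wiener index for every plot of
#' a long-format community table, carrying plot coordinates through when a
#' layout is supplied.
#'
#' @param community data.frame with columns `plot_id`, `species`,
#'   `abundance` (one row per plot-species pair).
#' @param plots optional plot table with `plot_id`, `x`, `y` (and any other
#'   columns to carry through, e.g. `tier`).
#' @return data.frame with one row per plot: `plot_id`, `richness`,
#'   `shannon`, plus the layout columns if given. Plots appear in first-
#'   occurrence order of the input.
#' @export
compute_diversity_table <- function(community, plots = NULL) {
  req <- c("plot_id", "species", "abundance")
  if (!all(req %in% names(community)))
    stop("community table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(community[, c("plot_id", "species")]))
    stop("duplicated (plot_id, species) pairs in community table")
  ids <- unique(community$plot_id)
  ab <- split(community$abundance, factor(community$plot_id, levels = ids))
  out <- data.frame(
    plot_id = ids,
    richness = vapply(ids, function(i) species_richness(ab[[i]], i), integer(1)),
    shannon = vapply(ids, function(i) shannon_index(ab[[i]], i), numeric(1))
  )
  if (!is.null(plots)) {
    keep <- plots[, c("plot_id", setdiff(names(plots), "plot_id")), drop = FALSE]
    out <- merge(out, keep, by = "plot_id", sort = FALSE)
    out <- out[match(ids, out$plot_id), ]
    rownames(out) <- NULL
  }
  out
}
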