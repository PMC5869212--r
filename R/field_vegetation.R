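#' Height classes of the cover-board protocol
#'
#' The ten vertical strata in which presence/absence of foliage is recorded
#' at each of the 17 measurement positions of a plot (centre point plus four
#' points at 5-m intervals along each cardinal direction).
#'
#' @return Character vector of the ten ordered class labels (metres).
#' @export
height_classes <- function() {
  c("0-0.5", "0.5-1", "1-1.5", "1.5-2", "2-3", "3-5", "5-7", "7-10", "10-15", ">15")
}

#' Number of cover-board measurement positions per plot
#' @return The integer 17.
#' @export
n_plot_positions <- function() 17L

.check_profile <- function(touches) {
  if (!is.matrix(touches) || nrow(touches) != 17L || ncol(touches) != 10L) {
    stop("a vegetation profile is a 17 x 10 matrix (positions x height classes); got ",
         paste(dim(touches), collapse = " x "))
  }
  if (anyNA(touches) || !all(touches %in% c(0, 1))) {
    stop("touches must be 0/1 presence-absence values")
  }
  invisible(touches)
}

#' Vegetation clutter per height class
#'
#' Clutter in a height class is the proportion of the 17 positions at which
#' foliage touches that class — a proxy for the obstacle density a bat must
#' navigate at that height.
#'
#' @param touches 17 x 10 binary matrix (positions x height classes).
#' @return Named numeric vector of length 10, values in `[0, 1]`.
#' @export
clutter_by_height <- function(touches) {
  .check_profile(touches)
  stats::setNames(colMeans(touches), height_classes())
}

#' Vertical heterogeneity of the vegetation profile
#'
#' Shannon diversity (natural log) over height classes, treating the number
#' of positions touched in a class as the class's "abundance":
#' `H = -sum(p_c * log(p_c))` with `p_c` the class's share of all touches.
#' An all-zero profile has no vegetation and hence no heterogeneity; it is
#' defined as `H = 0` with a warning.
#'
#' @param touches 17 x 10 binary matrix.
#' @return Shannon index in nats, in `[0, log(10)]`.
#' @export
vertical_heterogeneity <- function(touches) {
  .check_profile(touches)
  counts <- colSums(touches)
  total <- sum(counts)
  if (total == 0) {
    warning("profile has no vegetation touches; vertical heterogeneity defined as 0")
    return(0)
  }
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Summarize a plot's field measurements into vegetation descriptors
#'
#' Combines the cover-board touch matrix, the per-position ocular estimates
#' and the plot's tree list into the per-site descriptor set: clutter per
#' height class, vertical heterogeneity, mean ground cover, mean canopy
#' cover, mean vegetation height, tree density (stems with DBH > 0.16 m),
#' number of large trees (DBH > 0.30 m) and their mean DBH. Both DBH
#' thresholds are strict.
#'
#' @param touches 17 x 10 binary matrix.
#' @param ground_cover Numeric vector of 17 per-position ground-cover
#'   percentages in `[0, 100]`.
#' @param canopy_cover Numeric vector of 17 per-position canopy-cover
#'   percentages.
#' @param veg_height Numeric vector of 17 per-position vegetation heights (m).
#' @param dbh Numeric vector of tree DBH values in metres (may be empty).
#' @param per_hectare If `TRUE`, tree counts are additionally scaled from the
#'   20-m-radius plot (area 400*pi m^2) to stems per hectare.
#' @return A list of descriptors; `mean_dbh` is `NA` when no large tree is
#'   present.
#' @export
summarize_plot <- function(touches, ground_cover, canopy_cover, veg_height, dbh,
                           per_hectare = FALSE) {
  .check_profile(touches)
  for (v in list(ground_cover, canopy_cover, veg_height)) {
    if (length(v) != 17L) stop("per-position vectors must have length 17")
  }
  if (any(dbh < 0)) stop("negative DBH is not a valid tree measurement")
  large <- dbh > 0.30
  out <- list(
    clutter = clutter_by_height(touches),
    vertical_heterogeneity = suppressWarnings(vertical_heterogeneity(touches)),
    ground_cover = mean(ground_cover),
    canopy_cover = mean(canopy_cover),
    vegetation_height = mean(veg_height),
    tree_density = sum(dbh > 0.16),
    n_large_trees = sum(large),
    mean_dbh = if (any(large)) mean(dbh[large]) else NA_real_
  )
  if (per_hectare) {
    plot_area_ha <- 400 * pi / 1e4
    out$tree_density_ha <- out$tree_density / plot_area_ha
    out$n_large_trees_ha <- out$n_large_trees / plot_area_ha
  }
  out
}

#' Build the per-site vegetation descriptor table from raw field CSV records
#'
#' @param touch_df Data frame with columns `site_id`, `position_id` (1-17),
#'   `height_class` (a label from [height_classes()]), `touch` (0/1). Classes
#'   without a row for a position are treated as untouched.
#' @param position_df Data frame with columns `site_id`, `position_id`,
#'   `ground_cover`, `canopy_cover`, `veg_height`.
#' @param tree_df Data frame with columns `site_id`, `dbh_m`.
#' @return Data frame, one row per site, with the descriptors of
#'   [summarize_plot()] (clutter columns named `clutter_<class>`).
#' @export
vegetation_descriptor_table <- function(touch_df, position_df, tree_df) {
  hc <- height_classes()
  sites <- sort(unique(position_df$site_id))
  rows <- lapply(sites, function(s) {
    td <- touch_df[touch_df$site_id == s, , drop = FALSE]
    touches <- matrix(0, 17L, 10L)
    if (nrow(td)) {
      ci <- match(td$height_class, hc)
      if (anyNA(ci)) stop("site ", s, ": unknown height class ", td$height_class[which(is.na(ci))[1]])
      if (any(td$position_id < 1 | td$position_id > 17)) stop("site ", s, ": position_id outside 1..17")
      touches[cbind(td$position_id, ci)] <- td$touch
    }
    pd <- position_df[position_df$site_id == s, , drop = FALSE]
    pd <- pd[order(pd$position_id), , drop = FALSE]
    dbh <- tree_df$dbh_m[tree_df$site_id == s]
    d <- summarize_plot(touches, pd$ground_cover, pd$canopy_cover, pd$veg_height, dbh)
    cl <- as.list(d$clutter)
    names(cl) <- paste0("clutter_", gsub("[ >]", "", gsub("-", "_", hc)))
    data.frame(site_id = s, cl,
               vertical_heterogeneity = d$vertical_heterogeneity,
               ground_cover = d$ground_cover, canopy_cover = d$canopy_cover,
               vegetation_height = d$vegetation_height,
               tree_density = d$tree_density, n_large_trees = d$n_large_trees,
               mean_dbh = d$mean_dbh,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
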