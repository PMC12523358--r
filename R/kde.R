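# The adapted kernel density estimator: each yak observed in an hourly
# snapshot deposits one unit of mass (1 yak-hour) spread by a triangular
# kernel; weighted, adjustment-scaled sums of snapshot surfaces estimate the
# month's total grazing intensity in yak-hours per square metre.

#' Triangular kernel
#'
#' The radially symmetric 2D triangular (conical) kernel with unit mass:
#' `K(d) = 3 / (pi h^2) * (1 - d / h)` for `d < h`, else 0. The default
#' bandwidth of 300 m matches the hourly activity radius of grazing yaks.
#'
#' @param bandwidth_m kernel support radius h (m), `> 0`.
#' @return An object of class `triangular_kernel`.
#' @export
triangular_kernel <- function(bandwidth_m = 300) {
  if (!is.finite(bandwidth_m) || bandwidth_m <= 0) {
    stop("bandwidth_m must be > 0")
  }
  structure(list(bandwidth_m = bandwidth_m), class = "triangular_kernel")
}

#' Evaluate the triangular kernel
#'
#' @param distance_m non-negative distances (m); vectorised.
#' @param kernel a [triangular_kernel()].
#' @return Kernel density values (per square metre).
#' @examples
#' kernel_value(0, triangular_kernel(300))  # 3 / (pi * 300^2)
#' @export
kernel_value <- function(distance_m, kernel = triangular_kernel()) {
  stopifnot(inherits(kernel, "triangular_kernel"))
  if (any(distance_m < 0)) stop("distances must be >= 0")
  h <- kernel$bandwidth_m
  ifelse(distance_m < h, 3 / (pi * h^2) * (1 - distance_m / h), 0)
}

#' Construct a herd snapshot
#'
#' One aerial image of the herd: every individual's planar position at one
#' hour of one monitoring day.
#'
#' @param month,day,hour integer timestamp components.
#' @param positions numeric matrix (`herd_size` x 2) of yak positions (m);
#'   zero rows encode an empty snapshot.
#' @return An object of class `herd_snapshot`.
#' @export
herd_snapshot <- function(month, day, hour, positions) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  structure(
    list(month = as.integer(month), day = as.integer(day),
         hour = as.integer(hour), positions = positions,
         herd_size = nrow(positions)),
    class = "herd_snapshot"
  )
}

#' Rasterize one herd snapshot
#'
#' Each yak position deposits one yak-hour of mass spread by the kernel;
#' the raster value in a cell is the summed kernel density over the herd.
#' Kernels are evaluated at cell centres and are not renormalized near the
#' grid edge, so mass within the grid of an individual closer than one
#' bandwidth to the boundary is below 1 (documented truncation, see the
#' methods vignette).
#'
#' @param snapshot a [herd_snapshot()].
#' @param grid a grid specification (see [grid_from_pasture()]).
#' @param kernel a [triangular_kernel()].
#' @param weight mass deposited per individual (yak-hours; default 1).
#' @return An [intensity_raster()] in yak-hours per square metre.
#' @export
snapshot_intensity <- function(snapshot, grid, kernel = triangular_kernel(),
                               weight = 1) {
  stopifnot(inherits(snapshot, "herd_snapshot"),
            inherits(kernel, "triangular_kernel"))
  nr <- grid$n_rows; nc <- grid$n_cols
  if (nr < 1 || nc < 1) stop("grid must be non-empty")
  cell <- grid$cell_size_m
  pos <- snapshot$positions
  if (nrow(pos) > 0) {
    xmax <- grid$origin[1] + nc * cell; ymax <- grid$origin[2] + nr * cell
    outside <- pos[, 1] < grid$origin[1] | pos[, 1] > xmax |
      pos[, 2] < grid$origin[2] | pos[, 2] > ymax
    if (any(outside)) {
      warning(sprintf("%d position(s) outside the grid extent; kernels %s",
                      sum(outside), "evaluated where they overlap the grid"))
    }
  }
  values <- kde_accumulate(nr, nc, grid$origin[1], grid$origin[2], cell,
                           pos[, 1], pos[, 2], kernel$bandwidth_m,
                           rep(weight, nrow(pos)))
  intensity_raster(values, grid$origin, cell,
                   period = sprintf("m%02d-d%02d-h%02d", snapshot$month,
                                    snapshot$day, snapshot$hour),
                   meta = list(bandwidth_m = kernel$bandwidth_m,
                               herd_size = snapshot$herd_size))
}

#' Construct a monitoring plan
#'
#' Describes which days of a month were monitored and the grazing schedule,
#' so that snapshot surfaces can be scaled up to the full month.
#'
#' @param month integer month.
#' @param days_in_month number of days in the month.
#' @param monitored_days integer vector of monitored day numbers.
#' @param grazing_hours_per_day hours the herd grazes per day; either a
#'   scalar or a vector named by monitored day.
#' @return An object of class `monitoring_plan`.
#' @export
monitoring_plan <- function(month, days_in_month, monitored_days,
                            grazing_hours_per_day = 12) {
  monitored_days <- sort(unique(as.integer(monitored_days)))
  if (length(monitored_days) < 1L) stop("at least one monitored day required")
  if (any(monitored_days < 1L) || any(monitored_days > days_in_month)) {
    stop("monitored_days must lie within the month")
  }
  n <- length(monitored_days)
  if (n < 4L || n > 8L) {
    message(sprintf("month %d: %d monitored days is outside the 4-8 design range",
                    month, n))
  }
  structure(
    list(month = as.integer(month), days_in_month = as.integer(days_in_month),
         monitored_days = monitored_days,
         grazing_hours_per_day = grazing_hours_per_day),
    class = "monitoring_plan"
  )
}

plan_hours_for_day <- function(plan, day) {
  gh <- plan$grazing_hours_per_day
  if (!is.null(names(gh))) {
    h <- gh[[as.character(day)]]
    if (is.null(h)) stop("no grazing hours recorded for day ", day)
    h
  } else {
    gh
  }
}

#' Monthly grazing-intensity surface
#'
#' Combines the snapshot surfaces of the monitored days into an estimate of
#' the month's total grazing intensity. Each snapshot is weighted by
#' `grazing_hours / n_snapshots` for its day (so one monitored day's
#' weighted sum estimates that day's total yak-hours), and the sum over
#' monitored days is scaled by the adjustment factor
#' `A = days_in_month / n_monitored_days` to compensate for the limited
#' number of monitoring days.
#'
#' @param snapshots list of [herd_snapshot()]s, all from monitored days of
#'   the plan's month.
#' @param plan a [monitoring_plan()].
#' @param grid grid specification shared by all snapshots.
#' @param kernel a [triangular_kernel()].
#' @return An [intensity_raster()] estimating the month's total yak-hours
#'   per square metre.
#' @export
monthly_intensity <- function(snapshots, plan, grid,
                              kernel = triangular_kernel()) {
  stopifnot(inherits(plan, "monitoring_plan"), length(snapshots) > 0)
  days <- vapply(snapshots, function(s) s$day, integer(1))
  months <- vapply(snapshots, function(s) s$month, integer(1))
  if (any(months != plan$month)) stop("snapshot months disagree with the plan")
  if (!all(days %in% plan$monitored_days)) {
    stop("snapshots include days not in the monitoring plan")
  }
  n_snap <- table(days)
  adj <- plan$days_in_month / length(plan$monitored_days)
  acc <- NULL
  for (s in snapshots) {
    w <- plan_hours_for_day(plan, s$day) / n_snap[[as.character(s$day)]]
    r <- snapshot_intensity(s, grid, kernel, weight = w)
    acc <- if (is.null(acc)) r$values else acc + r$values
  }
  intensity_raster(acc * adj, grid$origin, grid$cell_size_m,
                   period = month_label(plan$month),
                   meta = list(bandwidth_m = kernel$bandwidth_m,
                               adjustment_factor = adj,
                               monitored_days = plan$monitored_days))
}

#' Cumulative grazing intensity over a window of months
#'
#' Cellwise sum of monthly surfaces sharing one grid; the period label spans
#' the window.
#'
#' @param rasters list of monthly [intensity_raster()]s on a common grid.
#' @return An [intensity_raster()].
#' @export
cumulative_intensity <- function(rasters) {
  stopifnot(length(rasters) >= 1)
  base <- rasters[[1]]
  acc <- base$values
  if (length(rasters) > 1) {
    for (r in rasters[-1]) {
      if (!same_grid(base, r)) stop("rasters do not share a common grid")
      acc <- acc + r$values
    }
  }
  labs <- vapply(rasters, function(r) r$period, character(1))
  period <- if (length(labs) == 1) labs else
    paste0(labs[which.min(match(labs, month.abb))], "-",
           labs[which.max(match(labs, month.abb))])
  intensity_raster(acc, base$origin, base$cell_size_m, period = period,
                   meta = base$meta)
}

#' Extract intensity at an image footprint
#'
#' @param raster an [intensity_raster()].
#' @param fp a [footprint()].
#' @param mode `"footprint_mean"` (mean of cells whose centres fall inside
#'   the footprint; default) or `"center"` (value of the cell containing the
#'   footprint centre). When the grid is coarser than the footprint so that
#'   no cell centre falls inside it, `"footprint_mean"` degrades to the
#'   containing cell's value (midpoint rule on a sub-cell window).
#' @return Intensity value (yak-hours per square metre).
#' @export
sample_intensity_at <- function(raster, fp, mode = c("footprint_mean", "center")) {
  stopifnot(inherits(raster, "intensity_raster"), inherits(fp, "footprint"))
  mode <- match.arg(mode)
  xc <- raster_xcenters(raster); yc <- raster_ycenters(raster)
  if (mode == "center") {
    ci <- findInterval(fp$center_xy[1], raster$origin[1] +
                         (0:raster$n_cols) * raster$cell_size_m,
                       rightmost.closed = TRUE)
    ri <- findInterval(fp$center_xy[2], raster$origin[2] +
                         (0:raster$n_rows) * raster$cell_size_m,
                       rightmost.closed = TRUE)
    if (ci < 1 || ci > raster$n_cols || ri < 1 || ri > raster$n_rows) {
      stop("footprint centre falls outside the raster")
    }
    return(raster$values[ri, ci])
  }
  in_x <- which(abs(xc - fp$center_xy[1]) <= fp$width_m / 2)
  in_y <- which(abs(yc - fp$center_xy[2]) <= fp$length_m / 2)
  if (length(in_x) == 0 || length(in_y) == 0) {
    # footprint smaller than a cell: fall back to the containing cell
    return(sample_intensity_at(raster, fp, mode = "center"))
  }
  mean(raster$values[in_y, in_x])
}

month_label <- function(m) month.abb[m]
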