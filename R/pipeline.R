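# Pipeline entry points binding the modules together: simulate a virtual
# study to disk, turn snapshot tables into intensity rasters, and run the
# calibration stage on count + intensity inputs. The thin command-line
# wrapper in inst/cli/grazeproxy.R dispatches to these functions.

#' Simulate a virtual study and write it to disk
#'
#' Runs [run_virtual_study()] and serializes the dataset: monitored-day
#' snapshots, monthly dung counts, waypoints, monthly and ground-truth
#' rasters (ESRI ASCII), the pasture GeoJSON, a config echo, and a run log.
#'
#' @param config a [sim_config()], or a path to a YAML run configuration.
#' @param outdir output directory (created if missing).
#' @return The `virtual_study`, invisibly.
#' @export
pipeline_simulate <- function(config, outdir) {
  kernel <- triangular_kernel()
  if (is.character(config)) {
    rc <- read_run_config(config)
    kernel <- rc$kernel
    config <- rc$sim
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- run_log_open(file.path(outdir, "run.log"))
  log_event(log, "simulate: seed ", config$seed, ", substreams ",
            paste(SIM_STREAMS, "=",
                  vapply(SIM_STREAMS, substream_seed, integer(1),
                         seed = config$seed), collapse = ", "))
  study <- run_virtual_study(config, kernel = kernel, keep_snapshots = TRUE)
  write_snapshots_csv(study$snapshots, file.path(outdir, "snapshots.csv"))
  write_counts_csv(study$counts, file.path(outdir, "counts.csv"))
  wp <- study$waypoints
  wp$route_kind <- "rectangle"; wp$height_m <- 20
  wp$width_m <- study$footprint_dims[["width_m"]]
  wp$length_m <- study$footprint_dims[["length_m"]]
  write_waypoints_csv(wp, file.path(outdir, "waypoints.csv"))
  write_pasture_geojson(study$pasture, file.path(outdir, "pasture.geojson"))
  for (lab in names(study$monthly_rasters)) {
    write_ascii_grid(study$monthly_rasters[[lab]],
                     file.path(outdir, sprintf("intensity_%s.asc", lab)))
  }
  write_ascii_grid(study$truth_raster, file.path(outdir, "truth_occupancy.asc"))
  write_config_echo(list(sim = config, kernel = kernel,
                         calibration = list(), output_dir = outdir),
                    file.path(outdir, "config_echo.yml"))
  for (f in list.files(outdir)) log_event(log, "wrote ", f)
  invisible(study)
}

#' Compute monthly and cumulative intensity rasters from snapshot tables
#'
#' Reads a snapshot CSV, infers a monitoring plan per month (monitored days
#' are the days present; grazed hours per day equal the number of hourly
#' images of that day), rasterizes at the requested resolution, and writes
#' monthly plus whole-period cumulative ASCII grids.
#'
#' @param snapshots_path snapshot CSV (see [write_snapshots_csv()]).
#' @param outdir output directory.
#' @param pasture_path optional pasture GeoJSON defining the grid extent;
#'   when NULL the extent is the bounding box of the positions padded by one
#'   bandwidth.
#' @param cell_size_m raster resolution (default 1 m).
#' @param bandwidth_m kernel bandwidth (default 300 m).
#' @return Named list of written rasters, invisibly.
#' @export
pipeline_intensity <- function(snapshots_path, outdir, pasture_path = NULL,
                               cell_size_m = 1, bandwidth_m = 300) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- run_log_open(file.path(outdir, "run.log"))
  snaps <- read_snapshots_csv(snapshots_path)
  kernel <- triangular_kernel(bandwidth_m)
  if (length(snaps) == 0) {
    warning("empty snapshot file: no rasters written")
    log_event(log, "intensity: empty snapshot input, nothing to do")
    return(invisible(list()))
  }
  if (!is.null(pasture_path)) {
    grid <- grid_from_pasture(read_pasture_geojson(pasture_path), cell_size_m)
  } else {
    pos <- do.call(rbind, lapply(snaps, function(s) s$positions))
    xr <- range(pos[, 1]) + c(-1, 1) * bandwidth_m
    yr <- range(pos[, 2]) + c(-1, 1) * bandwidth_m
    grid <- list(origin = c(xr[1], yr[1]), cell_size_m = cell_size_m,
                 n_rows = ceiling((yr[2] - yr[1]) / cell_size_m),
                 n_cols = ceiling((xr[2] - xr[1]) / cell_size_m))
  }
  months <- sort(unique(vapply(snaps, function(s) s$month, integer(1))))
  out <- list()
  for (m in months) {
    sm <- Filter(function(s) s$month == m, snaps)
    days <- vapply(sm, function(s) s$day, integer(1))
    hrs <- table(days)
    plan <- monitoring_plan(m, days_in_month(m), as.integer(names(hrs)),
                            grazing_hours_per_day =
                              stats::setNames(as.numeric(hrs), names(hrs)))
    r <- monthly_intensity(sm, plan, grid, kernel)
    out[[month_label(m)]] <- r
    write_ascii_grid(r, file.path(outdir, sprintf("intensity_%s.asc",
                                                  month_label(m))))
    log_event(log, "intensity: month ", month_label(m), ", adjustment ",
              format(r$meta$adjustment_factor), ", cell ", cell_size_m, " m")
  }
  cum <- cumulative_intensity(out)
  write_ascii_grid(cum, file.path(outdir, "intensity_cumulative.asc"))
  out$cumulative <- cum
  invisible(out)
}

#' Run the calibration stage from files
#'
#' Joins a dung-count table with per-waypoint intensities (either a
#' precomputed intensity CSV with columns `waypoint_id`, `window_start`,
#' `window_end`, `intensity`, or monthly rasters plus a waypoint table) and
#' fits the density-intensity relationship for every accumulation window,
#' the R^2-vs-k trend, and writes the report CSVs.
#'
#' @param counts_path dung count CSV (see [read_counts_csv()]).
#' @param outdir output directory.
#' @param intensity_path optional precomputed intensity CSV.
#' @param rasters_dir optional directory holding `intensity_<Mon>.asc`.
#' @param waypoints_path waypoint CSV (required with `rasters_dir`).
#' @param mode extraction mode, see [sample_intensity_at()].
#' @param exclude_months dung months excluded from every pairing.
#' @param k_range accumulation lengths (default all feasible).
#' @return List with `table` and `trend`, invisibly.
#' @export
pipeline_calibrate <- function(counts_path, outdir, intensity_path = NULL,
                               rasters_dir = NULL, waypoints_path = NULL,
                               mode = "footprint_mean", exclude_months = NULL,
                               k_range = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- run_log_open(file.path(outdir, "run.log"))
  counts <- read_counts_csv(counts_path)
  months <- sort(unique(counts$month))
  if (is.null(k_range)) k_range <- seq_along(months)
  get_intensity <- NULL
  if (!is.null(intensity_path)) {
    idf <- utils::read.csv(intensity_path)
    orphans <- setdiff(counts$waypoint_id, idf$waypoint_id)
    if (length(unique(counts$waypoint_id)) ==
        length(orphans)) {
      stop("no joinable waypoint ids; orphans: ",
           paste(utils::head(orphans, 20), collapse = ", "))
    }
    get_intensity <- function(ids, window) {
      sel <- idf[idf$window_start == window[1] &
                   idf$window_end == window[length(window)], ]
      sel$intensity[match(ids, sel$waypoint_id)]
    }
  } else {
    if (is.null(rasters_dir) || is.null(waypoints_path)) {
      stop("either intensity_path or rasters_dir + waypoints_path is required")
    }
    wps <- read_waypoints_csv(waypoints_path)
    orphans <- setdiff(counts$waypoint_id, wps$waypoint_id)
    if (length(orphans) == length(unique(counts$waypoint_id))) {
      stop("no joinable waypoint ids; orphans: ",
           paste(utils::head(orphans, 20), collapse = ", "))
    }
    rasters <- lapply(months, function(m) {
      read_ascii_grid(file.path(rasters_dir,
                                sprintf("intensity_%s.asc", month_label(m))))
    })
    names(rasters) <- month_label(months)
    get_intensity <- function(ids, window) {
      cum <- cumulative_intensity(rasters[month_label(window)])
      sel <- wps[match(ids, wps$waypoint_id), ]
      vapply(seq_len(nrow(sel)), function(i) {
        sample_intensity_at(cum, footprint(c(sel$x_m[i], sel$y_m[i]),
                                           sel$width_m[i], sel$length_m[i]),
                            mode)
      }, numeric(1))
    }
  }
  results <- list()
  for (k in k_range) {
    scheme <- enumerate_pairs(k, months, exclude = exclude_months)
    for (i in seq_len(nrow(scheme$pairs))) {
      pr <- scheme$pairs[i, ]
      cm <- counts[counts$month == pr$dung_month, ]
      if (nrow(cm) < 3) next
      dens <- dung_density(cm$observed_count, cm$footprint_area_m2)
      intens <- get_intensity(cm$waypoint_id, pr$window_start:pr$window_end)
      ok <- is.finite(intens)
      if (sum(ok) < 3) next
      res <- tryCatch(
        fit_relationship(dens[ok], intens[ok], k = k,
                         dung_month = pr$dung_month),
        error = function(e) NULL)
      if (is.null(res)) next
      if (res$degenerate) {
        log_event(log, "degenerate fit flagged: k=", k, " month=",
                  month_label(pr$dung_month))
      }
      results[[sprintf("k%d_%s", k, month_label(pr$dung_month))]] <- res
    }
  }
  if (length(results) == 0) stop("no fittable (month, window) pairs")
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(k = r$k, dung_month = month_label(r$dung_month), n = r$n,
               slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, p_value = r$p_value,
               degenerate = r$degenerate)
  }))
  rownames(tab) <- NULL
  utils::write.csv(tab, file.path(outdir, "calibration_table.csv"),
                   row.names = FALSE)
  ok <- vapply(results, function(r) !r$degenerate, logical(1))
  kk <- vapply(results[ok], function(r) r$k, numeric(1))
  trend <- NULL
  if (sum(ok) >= 3 && length(unique(kk)) >= 2) {
    trend <- r2_trend(results)
    utils::write.csv(
      data.frame(slope = trend$slope, intercept = trend$intercept,
                 r_squared = trend$r_squared, p_value = trend$p_value,
                 n = trend$n),
      file.path(outdir, "trend_summary.csv"), row.names = FALSE)
  }
  log_event(log, "calibrate: ", length(results), " fits over k in {",
            paste(sort(unique(vapply(results, function(r) r$k, numeric(1)))),
                  collapse = ","), "}; ", length(results),
            " significance tests run, no multiplicity correction applied")
  invisible(list(table = tab, trend = trend, results = results))
}
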