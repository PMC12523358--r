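# Readers and writers: snapshot/count/waypoint CSV tables, pasture GeoJSON,
# YAML run configuration with schema validation, and a plain-text run log.
# CSV dialect: UTF-8, comma-separated, header row, '.' decimal.

#' Write herd snapshots to CSV
#'
#' Long format with one row per yak per image: `month`, `day`, `hour`,
#' `yak_id`, `x_m`, `y_m`.
#'
#' @param snapshots list of [herd_snapshot()]s.
#' @param path output path.
#' @export
write_snapshots_csv <- function(snapshots, path) {
  rows <- lapply(snapshots, function(s) {
    if (s$herd_size == 0) return(NULL)
    data.frame(month = s$month, day = s$day, hour = s$hour,
               yak_id = seq_len(s$herd_size),
               x_m = s$positions[, 1], y_m = s$positions[, 2])
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) {
    df <- data.frame(month = integer(0), day = integer(0), hour = integer(0),
                     yak_id = integer(0), x_m = numeric(0), y_m = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read herd snapshots from CSV
#'
#' @param path a CSV written by [write_snapshots_csv()].
#' @return List of [herd_snapshot()]s (possibly empty).
#' @export
read_snapshots_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("month", "day", "hour", "x_m", "y_m")
  if (!all(need %in% names(df))) {
    stop("snapshot CSV lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0) return(list())
  key <- interaction(df$month, df$day, df$hour, drop = TRUE)
  lapply(split(df, key), function(g) {
    herd_snapshot(g$month[1], g$day[1], g$hour[1], cbind(g$x_m, g$y_m))
  })
}

#' Write dung count samples to CSV
#' @param counts data frame of count records.
#' @param path output path.
#' @export
write_counts_csv <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' Read dung count samples from CSV
#' @param path CSV with columns `waypoint_id`, `month`, `flight_height_m`
#'   (or `height_m`), `observed_count` (or `count`), `footprint_area_m2`
#'   (or `area_m2`).
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path)
  ren <- c(height_m = "flight_height_m", count = "observed_count",
           area_m2 = "footprint_area_m2")
  for (old in names(ren)) {
    if (old %in% names(df) && !(ren[[old]] %in% names(df))) {
      names(df)[names(df) == old] <- ren[[old]]
    }
  }
  need <- c("waypoint_id", "month", "observed_count", "footprint_area_m2")
  if (!all(need %in% names(df))) {
    stop("count CSV lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

#' Write a waypoint table to CSV
#'
#' Standard columns: `waypoint_id`, `route_kind`, `x_m`, `y_m`, `height_m`,
#' `width_m`, `length_m`, `excluded_flag`, `exclusion_reason`.
#'
#' @param waypoints data frame; missing standard columns are filled with NA.
#' @param path output path.
#' @export
write_waypoints_csv <- function(waypoints, path) {
  cols <- c("waypoint_id", "route_kind", "x_m", "y_m", "height_m",
            "width_m", "length_m", "excluded_flag", "exclusion_reason")
  for (cl in setdiff(cols, names(waypoints))) waypoints[[cl]] <- NA
  utils::write.csv(waypoints[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a waypoint table from CSV
#' @param path CSV written by [write_waypoints_csv()].
#' @export
read_waypoints_csv <- function(path) utils::read.csv(path)

#' Write a pasture geometry as GeoJSON
#'
#' A FeatureCollection with the boundary polygon (carrying the buffer widths
#' as properties), the campsite point, and the riverbed polygon if present.
#' Coordinates are metres of the declared local planar CRS.
#'
#' @param pasture a [pasture_geometry()].
#' @param path output path.
#' @export
write_pasture_geojson <- function(pasture, path) {
  stopifnot(inherits(pasture, "pasture_geometry"))
  close_ring <- function(p) rbind(p, p[1, , drop = FALSE])
  feat <- function(geom, props) list(type = "Feature", properties = props,
                                     geometry = geom)
  ring <- function(p) {
    p <- close_ring(as_poly(p))
    list(lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2])))
  }
  features <- list(
    feat(list(type = "Polygon", coordinates = ring(pasture$boundary)),
         list(role = "boundary", fence_buffer_m = pasture$fence_buffer_m,
              campsite_buffer_m = pasture$campsite_buffer_m)),
    feat(list(type = "Point",
              coordinates = c(pasture$campsite_xy[1], pasture$campsite_xy[2])),
         list(role = "campsite"))
  )
  if (!is.null(pasture$riverbed)) {
    features <- c(features, list(
      feat(list(type = "Polygon", coordinates = ring(pasture$riverbed)),
           list(role = "riverbed"))))
  }
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = "local-planar-metres")),
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pasture geometry from GeoJSON
#' @param path a file written by [write_pasture_geojson()].
#' @return A [pasture_geometry()].
#' @export
read_pasture_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  boundary <- NULL; campsite <- NULL; riverbed <- NULL
  fb <- 50; cb <- 150
  to_mat <- function(coords) {
    do.call(rbind, lapply(coords[[1]], function(p) c(p[[1]], p[[2]])))
  }
  for (f in obj$features) {
    role <- f$properties$role
    if (identical(role, "boundary")) {
      boundary <- to_mat(f$geometry$coordinates)
      fb <- f$properties$fence_buffer_m %||% fb
      cb <- f$properties$campsite_buffer_m %||% cb
    } else if (identical(role, "campsite")) {
      campsite <- c(f$geometry$coordinates[[1]], f$geometry$coordinates[[2]])
    } else if (identical(role, "riverbed")) {
      riverbed <- to_mat(f$geometry$coordinates)
    }
  }
  if (is.null(boundary) || is.null(campsite)) {
    stop("GeoJSON must contain boundary and campsite features")
  }
  pasture_geometry(boundary, campsite, riverbed = riverbed,
                   fence_buffer_m = fb, campsite_buffer_m = cb)
}

# --- run configuration -----------------------------------------------------

config_schema <- function() {
  list(
    sim = names(formals(sim_config)),
    grid = c("cell_size_m"),
    kernel = c("bandwidth_m"),
    calibration = c("mode", "exclude_months", "riverbed_threshold", "k_range"),
    output = c("dir"),
    seed = NULL
  )
}

#' Read and validate a run configuration
#'
#' YAML with top-level blocks `sim` (arguments of [sim_config()]), `grid`,
#' `kernel`, `calibration`, `output`, and a top-level `seed`. Unknown keys
#' at either level are rejected by name before any stage runs.
#'
#' @param path path to a YAML file.
#' @param overrides named list of top-level overrides (e.g. from CLI flags).
#' @return Validated configuration list with a `sim_config` in `$sim`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (blk in intersect(names(raw), names(schema))) {
    allowed <- schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(raw[[blk]]), allowed)
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in '%s' block: %s", blk,
                   paste(bad, collapse = ", ")))
    }
  }
  sim_args <- raw$sim %||% list()
  if (!is.null(raw$seed)) sim_args$seed <- raw$seed
  if (!is.null(raw$grid$cell_size_m)) sim_args$cell_size_m <- raw$grid$cell_size_m
  if (!is.null(sim_args$detection_prob_by_height)) {
    sim_args$detection_prob_by_height <-
      unlist(sim_args$detection_prob_by_height)
  }
  cfg <- do.call(sim_config, sim_args)
  list(sim = cfg,
       kernel = triangular_kernel(raw$kernel$bandwidth_m %||% 300),
       calibration = raw$calibration %||% list(),
       output_dir = raw$output$dir %||% ".",
       seed = cfg$seed)
}

#' Echo an effective configuration to YAML
#' @param run_config result of [read_run_config()] (or a compatible list).
#' @param path output path.
#' @export
write_config_echo <- function(run_config, path) {
  sim <- run_config$sim
  yaml::write_yaml(list(
    seed = sim$seed,
    sim = unclass(sim),
    kernel = list(bandwidth_m = run_config$kernel$bandwidth_m),
    calibration = run_config$calibration,
    output = list(dir = run_config$output_dir)
  ), path)
  invisible(path)
}

# --- run log ---------------------------------------------------------------

#' Open an append-only run log
#' @param path log file path.
#' @return A `run_log` handle.
#' @export
run_log_open <- function(path) {
  structure(list(path = path), class = "run_log")
}

#' Append a timestamped record to a run log
#' @param log a [run_log_open()] handle.
#' @param ... message parts pasted together.
#' @export
log_event <- function(log, ...) {
  stopifnot(inherits(log, "run_log"))
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ",
                 paste0(..., collapse = ""))
  cat(line, "\n", sep = "", file = log$path, append = TRUE)
  invisible(log)
}
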