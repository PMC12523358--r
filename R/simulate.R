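# Virtual-pasture study generator: campsite-centred herd movement, dung
# deposition and decay (with riverbed washout), and flight-height-dependent
# detection, so the full estimation pipeline can be exercised end to end on
# data with a known ground truth.

#' Configuration of a virtual grazing study
#'
#' Defaults reproduce the monitored household-pasture setting: 278 yaks on a
#' 113.64 ha pasture grazed May-October, 4-8 randomly chosen monitoring days
#' per month, 12-14 hourly herd images per day, a campsite concentrator
#' producing a radial gradient of grazing intensity, and detection
#' probabilities of 1.0 at 2 m and 0.9316 at 20 m flight height.
#'
#' @param seed integer seed; all stage substreams derive from it.
#' @param herd_size number of yaks (default 278).
#' @param pasture_area_ha pasture area (default 113.64 ha, square).
#' @param months integer months of the grazing season (default May-October).
#' @param monitored_days_range inclusive range of monitored days per month.
#' @param snapshots_per_day_range inclusive range of hourly images (equal to
#'   grazed hours) per day.
#' @param lambda_m e-folding length (m) of the distance-decay movement field
#'   `p(x) ~ exp(-dist(x, campsite) / lambda)`; default 300 m, the hourly
#'   activity radius.
#' @param rho hourly autocorrelation weight in `[0, 1)` of the herd centre:
#'   each hour's centre is `rho * previous + (1 - rho) * fresh draw`.
#' @param herd_spread_m s.d. (m) of individual positions around the herd
#'   centre (default 30 m: the herd is a cohesive group small enough to fit
#'   in a single high-altitude aerial image; 0 collapses the herd onto its
#'   centre).
#' @param day_edge_contraction if TRUE the first and last hour of each day
#'   use `lambda / 2`, so days start and end nearer the campsite.
#' @param deposition_rate expected dung pats per yak per hour (default 1).
#' @param dung_jitter_sd_m s.d. of the pat position around the yak (m).
#' @param decay_rate monthly decay rate delta: month-to-month pat survival
#'   is `exp(-delta)` (default 0.2).
#' @param riverbed_enabled include a riverbed strip in the pasture.
#' @param riverbed_decay_multiplier factor applied to `decay_rate` for pats
#'   lying in the riverbed (washout).
#' @param detection_prob_by_height named numeric vector of detection
#'   probabilities keyed by flight height in metres; no interpolation is
#'   performed between the configured heights.
#' @param false_positive_rate expected spurious detections per footprint.
#' @param gps_drift_max_m footprint centres drift uniformly in a disc of
#'   this radius at each visit (default 2 m).
#' @param campsite_frac campsite location as fractions of the pasture side.
#' @param fence_buffer_m,campsite_buffer_m exclusion buffers (m).
#' @param cell_size_m raster resolution used by [run_virtual_study()]
#'   (default 10 m; with a 300 m bandwidth the surface is smooth at this
#'   scale, see the methods vignette).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       herd_size = 278L,
                       pasture_area_ha = 113.64,
                       months = 5:10,
                       monitored_days_range = c(4L, 8L),
                       snapshots_per_day_range = c(12L, 14L),
                       lambda_m = 300,
                       rho = 0.5,
                       herd_spread_m = 30,
                       day_edge_contraction = TRUE,
                       deposition_rate = 1.0,
                       dung_jitter_sd_m = 0.5,
                       decay_rate = 0.2,
                       riverbed_enabled = FALSE,
                       riverbed_decay_multiplier = 5,
                       detection_prob_by_height = c("2" = 1.0, "20" = 0.9316),
                       false_positive_rate = 0,
                       gps_drift_max_m = 2,
                       campsite_frac = c(0.35, 0.35),
                       fence_buffer_m = 50,
                       campsite_buffer_m = 150,
                       cell_size_m = 10) {
  cfg <- as.list(environment())
  if (herd_size < 0) stop("herd_size must be >= 0")
  if (pasture_area_ha <= 0) stop("pasture_area_ha must be > 0")
  rates <- c(deposition_rate, decay_rate, riverbed_decay_multiplier,
             false_positive_rate, gps_drift_max_m, dung_jitter_sd_m,
             herd_spread_m)
  if (any(rates < 0)) stop("rates and radii must be >= 0")
  if (any(detection_prob_by_height < 0 | detection_prob_by_height > 1)) {
    stop("detection probabilities must lie in [0, 1]")
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  cfg$seed <- as.integer(seed)
  cfg$herd_size <- as.integer(herd_size)
  structure(cfg, class = "sim_config")
}

# independent named substreams derived from the master seed
SIM_STREAMS <- c("design", "movement", "deposition", "decay", "detection")

substream_seed <- function(seed, stream) {
  i <- match(stream, SIM_STREAMS)
  if (is.na(i)) stop("unknown substream: ", stream)
  as.integer((as.numeric(seed) + i * 1000003) %% 2147483647)
}

set_substream <- function(config, stream) {
  set.seed(substream_seed(config$seed, stream))
}

days_in_month <- function(month) c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month]

#' Generate the virtual pasture
#'
#' A square pasture of the configured area with the campsite offset from the
#' centre, and (optionally) a riverbed strip crossing the pasture.
#'
#' @param config a [sim_config()].
#' @return A [pasture_geometry()].
#' @export
simulate_pasture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  side <- sqrt(config$pasture_area_ha * 1e4)
  boundary <- rect_poly(0, 0, side, side)
  campsite <- config$campsite_frac * side
  riverbed <- NULL
  if (isTRUE(config$riverbed_enabled)) {
    riverbed <- rect_poly(0.70 * side, 0, 0.74 * side, side)
  }
  p <- pasture_geometry(boundary, campsite, riverbed = riverbed,
                        fence_buffer_m = config$fence_buffer_m,
                        campsite_buffer_m = config$campsite_buffer_m)
  if (2 * config$fence_buffer_m >= side) {
    stop("fence buffer exceeds the pasture span")
  }
  p
}

# rejection-sample n positions from p(x) ~ exp(-dist(x, campsite)/lambda)
sample_field_positions <- function(n, pasture, lambda) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  xr <- range(pasture$boundary[, 1]); yr <- range(pasture$boundary[, 2])
  out <- matrix(NA_real_, nrow = n, ncol = 2)
  filled <- 0L
  for (it in 1:1000) {
    m <- max(4L * (n - filled), 64L)
    cx <- runif(m, xr[1], xr[2]); cy <- runif(m, yr[1], yr[2])
    ok <- point_in_poly(cx, cy, pasture$boundary)
    d <- sqrt((cx - pasture$campsite_xy[1])^2 + (cy - pasture$campsite_xy[2])^2)
    ok <- ok & (runif(m) < exp(-d / lambda))
    k <- which(ok)
    if (length(k) > 0) {
      take <- k[seq_len(min(length(k), n - filled))]
      out[filled + seq_along(take), ] <- cbind(cx[take], cy[take])
      filled <- filled + length(take)
    }
    if (filled >= n) return(out)
  }
  stop("rejection sampling failed: lambda too small for this pasture")
}

#' Simulate one monitoring day of herd movement
#'
#' The herd grazes as a cohesive group: each hour a fresh herd-centre
#' location is drawn from the campsite-centred distance-decay field and
#' blended with the previous hour's centre (weight `rho`) for positional
#' autocorrelation; individual yaks scatter around the centre with s.d.
#' `herd_spread_m`, clipped to the pasture. The first and last hour of the
#' day optionally use a halved decay length so the day starts and ends
#' nearer the campsite. The marginal position distribution retains the
#' radial gradient of the field.
#'
#' @param config a [sim_config()].
#' @param pasture a [pasture_geometry()].
#' @param month,day integer date.
#' @param n_hours number of hourly snapshots; drawn from
#'   `snapshots_per_day_range` when NULL.
#' @return List of [herd_snapshot()]s, one per grazed hour.
#' @export
simulate_day <- function(config, pasture, month, day, n_hours = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(pasture, "pasture_geometry"))
  if (config$lambda_m <= 0) stop("lambda_m must be > 0")
  if (is.null(n_hours)) {
    r <- config$snapshots_per_day_range
    n_hours <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  }
  n <- config$herd_size
  xr <- range(pasture$boundary[, 1]); yr <- range(pasture$boundary[, 2])
  snaps <- vector("list", n_hours)
  prev_centre <- NULL
  for (h in seq_len(n_hours)) {
    lam <- config$lambda_m
    if (isTRUE(config$day_edge_contraction) && (h == 1L || h == n_hours)) {
      lam <- lam / 2
    }
    fresh <- sample_field_positions(1L, pasture, lam)[1, ]
    centre <- if (is.null(prev_centre) || config$rho == 0) fresh else
      config$rho * prev_centre + (1 - config$rho) * fresh
    if (n > 0) {
      pos <- cbind(centre[1] + stats::rnorm(n, 0, config$herd_spread_m),
                   centre[2] + stats::rnorm(n, 0, config$herd_spread_m))
      # cohesive scatter clipped to the pasture (rectangular boundary)
      pos[, 1] <- pmin(pmax(pos[, 1], xr[1]), xr[2])
      pos[, 2] <- pmin(pmax(pos[, 2], yr[1]), yr[2])
    } else {
      pos <- matrix(numeric(0), ncol = 2)
    }
    snaps[[h]] <- herd_snapshot(month, day, 7L + h, pos)
    prev_centre <- centre
  }
  snaps
}

#' Deposit dung pats along the herd's hourly positions
#'
#' Per yak-hour the pat count is Poisson(`deposition_rate`); each pat lands
#' at the yak's position plus Gaussian jitter, clipped to the pasture.
#'
#' @param snapshots list of [herd_snapshot()]s (any mix of days/months).
#' @param config a [sim_config()].
#' @param pasture a [pasture_geometry()].
#' @return Data frame of pats: `id`, `x_m`, `y_m`, `month`, `day`, `hour`,
#'   `in_riverbed`, `survived_until` (Inf until decayed).
#' @export
deposit_dung <- function(snapshots, config, pasture) {
  stopifnot(inherits(config, "sim_config"))
  rate <- config$deposition_rate
  pieces <- vector("list", length(snapshots))
  for (i in seq_along(snapshots)) {
    s <- snapshots[[i]]
    if (s$herd_size == 0 || rate == 0) next
    counts <- stats::rpois(s$herd_size, rate)
    tot <- sum(counts)
    if (tot == 0) next
    idx <- rep.int(seq_len(s$herd_size), counts)
    x <- s$positions[idx, 1] + stats::rnorm(tot, 0, config$dung_jitter_sd_m)
    y <- s$positions[idx, 2] + stats::rnorm(tot, 0, config$dung_jitter_sd_m)
    pieces[[i]] <- data.frame(x_m = x, y_m = y, month = s$month,
                              day = s$day, hour = s$hour)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) {
    return(data.frame(id = integer(0), x_m = numeric(0), y_m = numeric(0),
                      month = integer(0), day = integer(0), hour = integer(0),
                      in_riverbed = logical(0), survived_until = numeric(0)))
  }
  pats <- do.call(rbind, pieces)
  # clip jitter to the pasture (rectangular boundary: clamp to the box)
  xr <- range(pasture$boundary[, 1]); yr <- range(pasture$boundary[, 2])
  pats$x_m <- pmin(pmax(pats$x_m, xr[1]), xr[2])
  pats$y_m <- pmin(pmax(pats$y_m, yr[1]), yr[2])
  pats$in_riverbed <- if (is.null(pasture$riverbed)) FALSE else
    point_in_poly(pats$x_m, pats$y_m, pasture$riverbed)
  pats$survived_until <- Inf
  data.frame(id = seq_len(nrow(pats)), pats)
}

#' Advance dung decay by one month
#'
#' Pats alive in `current_month` survive into the next month with
#' probability `exp(-decay_rate)` (`exp(-decay_rate *
#' riverbed_decay_multiplier)` in the riverbed); pats that fail get
#' `survived_until = current_month`, i.e. the standing crop of
#' `current_month` still includes them. Freshly deposited pats (age 0) are
#' always present in their deposition month.
#'
#' @param pats pat data frame from [deposit_dung()].
#' @param current_month month whose end is being crossed.
#' @param config a [sim_config()].
#' @return The pat data frame with updated `survived_until`.
#' @export
decompose <- function(pats, current_month, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(pats) == 0 || config$decay_rate == 0) return(pats)
  at_risk <- is.infinite(pats$survived_until) & pats$month <= current_month
  if (!any(at_risk)) return(pats)
  delta <- config$decay_rate *
    ifelse(pats$in_riverbed[at_risk], config$riverbed_decay_multiplier, 1)
  dies <- stats::runif(sum(at_risk)) > exp(-delta)
  idx <- which(at_risk)[dies]
  pats$survived_until[idx] <- current_month
  pats
}

#' Standing crop of dung in a given month
#'
#' Pats deposited in or before `month` that have not decayed before it.
#'
#' @param pats pat data frame.
#' @param month survey month.
#' @return Subset of `pats`.
#' @export
standing_crop <- function(pats, month) {
  pats[pats$month <= month & pats$survived_until >= month, , drop = FALSE]
}

#' Observe dung within one image footprint
#'
#' The footprint centre is displaced by a uniform draw in a disc of radius
#' `gps_drift_max_m` (per visit), the surviving pats inside the displaced
#' footprint are counted (`true_count`), and the observed count is
#' `Binomial(true_count, p(height)) + Poisson(false_positive_rate)`. Only
#' the configured flight heights are valid; there is no interpolation.
#'
#' @param pats surviving pats (e.g. from [standing_crop()]).
#' @param fp a [footprint()].
#' @param flight_height_m flight height; must have a configured detection
#'   probability.
#' @param config a [sim_config()].
#' @return One-row data frame: `flight_height_m`, `true_count`,
#'   `observed_count`, `footprint_area_m2`.
#' @export
observe_dung <- function(pats, fp, flight_height_m, config) {
  stopifnot(inherits(config, "sim_config"), inherits(fp, "footprint"))
  p <- detection_prob(config, flight_height_m)
  ctr <- fp$center_xy
  if (config$gps_drift_max_m > 0) {
    r <- config$gps_drift_max_m * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    ctr <- ctr + r * c(cos(th), sin(th))
  }
  inside <- abs(pats$x_m - ctr[1]) <= fp$width_m / 2 &
    abs(pats$y_m - ctr[2]) <= fp$length_m / 2
  true_count <- sum(inside)
  observed <- stats::rbinom(1, true_count, p)
  if (config$false_positive_rate > 0) {
    observed <- observed + stats::rpois(1, config$false_positive_rate)
  }
  data.frame(flight_height_m = flight_height_m, true_count = true_count,
             observed_count = observed, footprint_area_m2 = fp$area_m2)
}

detection_prob <- function(config, flight_height_m) {
  tab <- config$detection_prob_by_height
  p <- unname(tab[match(as.character(flight_height_m), names(tab))])
  if (length(p) != 1L || is.na(p)) {
    stop("no detection probability configured for height ", flight_height_m,
         " m (heights are not interpolated)")
  }
  p
}

# fast batched counting of points in many equally sized rectangles
count_in_rects <- function(px, py, cx, cy, half_w, half_l) {
  n <- length(cx)
  counts <- integer(n)
  if (length(px) == 0) return(counts)
  ord <- order(px)
  sx <- px[ord]; sy <- py[ord]
  lo <- findInterval(cx - half_w, sx) + 1L
  hi <- findInterval(cx + half_w, sx)
  for (i in seq_len(n)) {
    if (hi[i] < lo[i]) next
    yy <- sy[lo[i]:hi[i]]
    counts[i] <- sum(abs(yy - cy[i]) <= half_l)
  }
  counts
}

#' Run the full virtual study
#'
#' Simulates the whole grazing season: herd movement for every day of every
#' month (the ground truth accumulates ALL grazed hours, not only monitored
#' days), monthly grazing-intensity estimation from the monitored days'
#' snapshots, dung deposition, monthly decay, and monthly dung counts at the
#' retained waypoints at 20 m flight height. Deterministic given the
#' config's seed: each stage (design, movement, deposition, decay,
#' detection) draws from its own named substream.
#'
#' @param config a [sim_config()].
#' @param kernel a [triangular_kernel()].
#' @param n_routes_xy integer length-2: grid of rectangle-route anchors laid
#'   over the pasture (default `c(3, 4)`, i.e. 12 routes of 12 waypoints).
#' @param keep_pats keep the full pat table in the result (default FALSE).
#' @param keep_snapshots keep the monitored days' snapshots (default FALSE).
#' @return An object of class `virtual_study`: `config`, `pasture`, `grid`,
#'   `waypoints` (retained, with footprint dims), `plans`,
#'   `monthly_rasters` (named by month label), `truth_raster` (cumulative
#'   yak-hours per square metre from all simulated hours), `counts` (one row
#'   per waypoint x month).
#' @export
run_virtual_study <- function(config, kernel = triangular_kernel(),
                              n_routes_xy = c(3L, 4L), keep_pats = FALSE,
                              keep_snapshots = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  pasture <- simulate_pasture(config)
  grid <- grid_from_pasture(pasture, config$cell_size_m)
  side <- diff(range(pasture$boundary[, 1]))

  # -- design: monitored days and per-day grazed hours --------------------
  set_substream(config, "design")
  plans <- list(); hours_by_month <- list()
  for (m in config$months) {
    dim_m <- days_in_month(m)
    r <- config$monitored_days_range
    n_mon <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
    mon_days <- sort(sample(seq_len(dim_m), n_mon))
    sr <- config$snapshots_per_day_range
    hrs <- if (sr[1] == sr[2]) rep(sr[1], dim_m) else
      sample(sr[1]:sr[2], dim_m, replace = TRUE)
    names(hrs) <- seq_len(dim_m)
    plans[[month_label(m)]] <- monitoring_plan(
      m, dim_m, mon_days, grazing_hours_per_day = hrs[as.character(mon_days)])
    hours_by_month[[month_label(m)]] <- hrs
  }

  # -- movement: every day of every month ---------------------------------
  set_substream(config, "movement")
  all_snaps <- list()
  for (m in config$months) {
    hrs <- hours_by_month[[month_label(m)]]
    for (d in seq_len(days_in_month(m))) {
      all_snaps[[sprintf("m%02d_d%02d", m, d)]] <-
        simulate_day(config, pasture, m, d, n_hours = hrs[[d]])
    }
  }

  # ground truth: binned occupancy of every simulated yak-hour
  flat <- unlist(all_snaps, recursive = FALSE)
  pos <- do.call(rbind, lapply(flat, function(s) s$positions))
  if (is.null(pos)) pos <- matrix(numeric(0), ncol = 2)
  truth <- intensity_raster(
    bin_accumulate(grid$n_rows, grid$n_cols, grid$origin[1], grid$origin[2],
                   grid$cell_size_m, pos[, 1], pos[, 2],
                   rep(1, nrow(pos))),
    grid$origin, grid$cell_size_m,
    period = paste0(month_label(config$months[1]), "-",
                    month_label(config$months[length(config$months)])),
    meta = list(kind = "true_occupancy"))

  # monthly KDE surfaces from the monitored days only
  monthly_rasters <- list()
  for (m in config$months) {
    plan <- plans[[month_label(m)]]
    snaps_m <- unlist(lapply(plan$monitored_days, function(d) {
      all_snaps[[sprintf("m%02d_d%02d", m, d)]]
    }), recursive = FALSE)
    monthly_rasters[[month_label(m)]] <-
      monthly_intensity(snaps_m, plan, grid, kernel)
  }

  # -- deposition ---------------------------------------------------------
  set_substream(config, "deposition")
  pats <- deposit_dung(flat, config, pasture)

  # -- decay: settle every pat's survival before any observation ----------
  set_substream(config, "decay")
  for (m in config$months) pats <- decompose(pats, m, config)

  # -- waypoints: rectangle routes tiled over the pasture -----------------
  anchors <- generate_route("rectangle", c(side / 2, side / 2),
                            extent_m = c(side, side),
                            grid_dim = n_routes_xy, flight_height_m = 20)
  wp_list <- lapply(seq_len(nrow(anchors$waypoints)), function(i) {
    rt <- generate_route("rectangle",
                         c(anchors$waypoints$x_m[i], anchors$waypoints$y_m[i]))
    rt$waypoints$route_id <- i
    rt$waypoints
  })
  wps <- do.call(rbind, wp_list)
  wps$waypoint_id <- seq_len(nrow(wps))
  excl <- apply_exclusion_zones(pasture, wps)
  wps <- excl$waypoints[!excl$waypoints$excluded_flag, , drop = FALSE]
  cam <- camera_profile("phantom3pro")
  dims <- footprint_dimensions(cam, 20)

  # -- detection: monthly counts at every retained waypoint ---------------
  set_substream(config, "detection")
  p20 <- detection_prob(config, 20)
  counts <- list()
  for (m in config$months) {
    crop <- standing_crop(pats, m)
    nw <- nrow(wps)
    ctr_x <- wps$x_m; ctr_y <- wps$y_m
    if (config$gps_drift_max_m > 0) {
      r <- config$gps_drift_max_m * sqrt(stats::runif(nw))
      th <- stats::runif(nw, 0, 2 * pi)
      ctr_x <- ctr_x + r * cos(th); ctr_y <- ctr_y + r * sin(th)
    }
    tc <- count_in_rects(crop$x_m, crop$y_m, ctr_x, ctr_y,
                         dims[["width_m"]] / 2, dims[["length_m"]] / 2)
    obs <- stats::rbinom(nw, tc, p20)
    if (config$false_positive_rate > 0) {
      obs <- obs + stats::rpois(nw, config$false_positive_rate)
    }
    counts[[month_label(m)]] <- data.frame(
      waypoint_id = wps$waypoint_id, month = m, flight_height_m = 20,
      true_count = tc, observed_count = obs,
      footprint_area_m2 = dims[["width_m"]] * dims[["length_m"]])
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL

  out <- list(config = config, pasture = pasture, grid = grid,
              waypoints = wps, footprint_dims = dims, plans = plans,
              monthly_rasters = monthly_rasters, truth_raster = truth,
              counts = counts)
  if (keep_pats) out$pats <- pats
  if (keep_snapshots) {
    out$snapshots <- unlist(lapply(config$months, function(m) {
      unlist(lapply(plans[[month_label(m)]]$monitored_days, function(d) {
        all_snaps[[sprintf("m%02d_d%02d", m, d)]]
      }), recursive = FALSE)
    }), recursive = FALSE)
  }
  structure(out, class = "virtual_study")
}

#' @export
print.virtual_study <- function(x, ...) {
  cat(sprintf("<virtual_study> %d yaks, %.2f ha, months %s, seed %d\n",
              x$config$herd_size, x$config$pasture_area_ha,
              paste(month_label(x$config$months), collapse = " "),
              x$config$seed))
  cat(sprintf("  %d retained waypoints, %d count records, grid %d x %d @ %g m\n",
              nrow(x$waypoints), nrow(x$counts), x$grid$n_rows, x$grid$n_cols,
              x$grid$cell_size_m))
  invisible(x)
}
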