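# UAV footprint geometry: camera models, ground coverage, ground sampling
# distance, fixed-point waypoint routes, and spatial exclusion rules.

#' Create a camera model
#'
#' Describes the onboard sensor and lens used to map flight height to ground
#' coverage. All dimensions are physical sensor dimensions in millimetres and
#' the focal length is the true (not 35 mm-equivalent) focal length.
#'
#' @param sensor_width_mm,sensor_length_mm physical sensor dimensions (mm).
#' @param focal_length_mm true focal length of the lens (mm).
#' @param image_width_px,image_height_px image size in pixels.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(6.17, 4.63, 3.61, 4000, 3000)
#' footprint_dimensions(cam, 20)
#' @export
camera_model <- function(sensor_width_mm, sensor_length_mm, focal_length_mm,
                         image_width_px, image_height_px) {
  vals <- c(sensor_width_mm, sensor_length_mm, focal_length_mm,
            image_width_px, image_height_px)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid camera: all camera parameters must be strictly positive")
  }
  structure(
    list(sensor_width_mm = sensor_width_mm,
         sensor_length_mm = sensor_length_mm,
         focal_length_mm = focal_length_mm,
         image_width_px = as.integer(image_width_px),
         image_height_px = as.integer(image_height_px)),
    class = "camera_model"
  )
}

#' Built-in camera profiles
#'
#' Profiles for the two consumer quadcopter cameras used in fixed-point
#' pasture monitoring, both with 1/2.3 inch sensors (6.17 x 4.63 mm). The
#' true focal lengths are chosen so that the 20 m footprints match the
#' published coverage of roughly 35 m x 26 m (phantom3pro-like) and
#' 29 m x 21 m (mavicpro-like); manufacturers publish 35 mm-equivalent
#' focal lengths only.
#'
#' @param profile one of `"phantom3pro"`, `"mavicpro"`.
#' @return A `camera_model`.
#' @export
camera_profile <- function(profile = c("phantom3pro", "mavicpro")) {
  profile <- match.arg(profile)
  switch(profile,
    phantom3pro = camera_model(6.17, 4.63, 3.61, 4000, 3000),
    mavicpro    = camera_model(6.17, 4.63, 4.30, 3000, 4000)
  )
}

#' Ground coverage of one aerial image
#'
#' Width and length (m) of the ground rectangle covered by a single nadir
#' image: `width = S_w * H / f` and `length = S_l * H / f`, with the flight
#' height H converted to millimetres and the result to metres (the two
#' factor-1000 conversions cancel).
#'
#' @param camera a [camera_model()].
#' @param flight_height_m flight height above ground (m), `>= 0`.
#' @return Named numeric vector `c(width_m, length_m)`.
#' @examples
#' footprint_dimensions(camera_profile("phantom3pro"), 20)
#' @export
footprint_dimensions <- function(camera, flight_height_m) {
  stopifnot(inherits(camera, "camera_model"))
  if (!is.finite(flight_height_m) || flight_height_m < 0) {
    stop("flight_height_m must be a non-negative number")
  }
  h_mm <- flight_height_m * 1000
  c(width_m  = camera$sensor_width_mm  * h_mm / camera$focal_length_mm / 1000,
    length_m = camera$sensor_length_mm * h_mm / camera$focal_length_mm / 1000)
}

#' Ground sampling distance
#'
#' Ground length represented by one image pixel, in cm per pixel:
#' footprint width divided by image width in pixels.
#'
#' @inheritParams footprint_dimensions
#' @return GSD in cm/pixel.
#' @export
ground_sampling_distance <- function(camera, flight_height_m) {
  stopifnot(inherits(camera, "camera_model"))
  if (camera$image_width_px <= 0) stop("invalid camera: zero pixel count")
  if (!is.finite(flight_height_m) || flight_height_m <= 0) {
    stop("flight_height_m must be positive")
  }
  dims <- footprint_dimensions(camera, flight_height_m)
  unname(dims["width_m"] * 100 / camera$image_width_px)
}

#' Construct an image footprint
#'
#' An axis-aligned ground rectangle centred on a waypoint (UAV yaw is
#' ignored: no heading data are recorded by the fixed-point protocol).
#'
#' @param center_xy numeric length-2, footprint centre (m).
#' @param width_m,length_m footprint dimensions (m); width spans x, length y.
#' @return An object of class `footprint` with an `area_m2` field.
#' @export
footprint <- function(center_xy, width_m, length_m) {
  stopifnot(length(center_xy) == 2, is.numeric(center_xy))
  if (width_m < 0 || length_m < 0) stop("footprint dimensions must be >= 0")
  structure(
    list(center_xy = as.numeric(center_xy), width_m = width_m,
         length_m = length_m, area_m2 = width_m * length_m),
    class = "footprint"
  )
}

footprint_poly <- function(fp) {
  rect_poly(fp$center_xy[1] - fp$width_m / 2, fp$center_xy[2] - fp$length_m / 2,
            fp$center_xy[1] + fp$width_m / 2, fp$center_xy[2] + fp$length_m / 2)
}

#' Footprint for a camera at a waypoint
#'
#' @param camera a [camera_model()].
#' @param center_xy waypoint centre (m).
#' @param flight_height_m flight height (m).
#' @export
camera_footprint <- function(camera, center_xy, flight_height_m) {
  dims <- footprint_dimensions(camera, flight_height_m)
  footprint(center_xy, dims[["width_m"]], dims[["length_m"]])
}

#' Generate a fixed-point waypoint route
#'
#' Waypoints are laid out as an evenly spaced grid of cell centres over a
#' rectangular extent centred on `anchor_xy`. Defaults follow the two
#' standard designs: a `"rectangle"` route of 12 waypoints (3 x 4 grid over
#' 100 m x 200 m, flown at 20 m) and a `"belt"` route of 16 waypoints
#' (4 x 4 grid over 40 m x 40 m, flown at 2 m).
#'
#' @param kind `"rectangle"` or `"belt"`.
#' @param anchor_xy centre of the routed area (m).
#' @param extent_m numeric length-2 `c(width, length)` of the routed area;
#'   defaults depend on `kind`.
#' @param grid_dim integer length-2 `c(nx, ny)` waypoint grid; defaults
#'   depend on `kind`.
#' @param flight_height_m flight height (m); defaults depend on `kind`.
#' @return A `flight_route`: list with `route_kind`, `waypoints` (data frame
#'   of `waypoint_id`, `x_m`, `y_m`), `flight_height_m`, `extent_m`.
#' @examples
#' nrow(generate_route("rectangle", c(500, 500))$waypoints)  # 12
#' nrow(generate_route("belt", c(500, 500))$waypoints)       # 16
#' @export
generate_route <- function(kind = c("rectangle", "belt"), anchor_xy,
                           extent_m = NULL, grid_dim = NULL,
                           flight_height_m = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    rectangle = list(extent = c(100, 200), grid = c(3L, 4L), height = 20),
    belt      = list(extent = c(40, 40),  grid = c(4L, 4L), height = 2)
  )
  if (is.null(extent_m)) extent_m <- defaults$extent
  if (is.null(grid_dim)) grid_dim <- defaults$grid
  if (is.null(flight_height_m)) flight_height_m <- defaults$height
  stopifnot(length(anchor_xy) == 2, length(extent_m) == 2, length(grid_dim) == 2)
  nx <- as.integer(grid_dim[1]); ny <- as.integer(grid_dim[2])
  if (nx < 1L || ny < 1L) stop("grid_dim entries must be >= 1")
  xs <- anchor_xy[1] - extent_m[1] / 2 + (seq_len(nx) - 0.5) * extent_m[1] / nx
  ys <- anchor_xy[2] - extent_m[2] / 2 + (seq_len(ny) - 0.5) * extent_m[2] / ny
  wp <- expand.grid(x_m = xs, y_m = ys, KEEP.OUT.ATTRS = FALSE)
  wp <- data.frame(waypoint_id = seq_len(nrow(wp)), wp)
  structure(
    list(route_kind = kind, waypoints = wp,
         flight_height_m = flight_height_m, extent_m = extent_m,
         anchor_xy = as.numeric(anchor_xy)),
    class = "flight_route"
  )
}

#' Pasture geometry with exclusion buffers
#'
#' A fenced pasture polygon, the campsite (night-pen concentrator), an
#' optional riverbed polygon, and the two exclusion buffers: a fence buffer
#' along the boundary (edge effects and fuel collection along the fence) and
#' a campsite buffer around the enclosure (dung collection and drying area).
#'
#' @param boundary polygon vertex matrix (m).
#' @param campsite_xy numeric length-2, campsite location; must lie inside
#'   the boundary.
#' @param riverbed optional polygon vertex matrix.
#' @param fence_buffer_m buffer width along the fence (m, default 50).
#' @param campsite_buffer_m radius excluded around the campsite (m,
#'   default 150).
#' @return An object of class `pasture_geometry`.
#' @export
pasture_geometry <- function(boundary, campsite_xy, riverbed = NULL,
                             fence_buffer_m = 50, campsite_buffer_m = 150) {
  boundary <- as_poly(boundary)
  stopifnot(length(campsite_xy) == 2)
  if (fence_buffer_m < 0 || campsite_buffer_m < 0) stop("buffers must be >= 0")
  if (!point_in_poly(campsite_xy[1], campsite_xy[2], boundary)) {
    stop("campsite must lie inside the pasture boundary")
  }
  if (!is.null(riverbed)) riverbed <- as_poly(riverbed)
  structure(
    list(boundary = boundary, campsite_xy = as.numeric(campsite_xy),
         riverbed = riverbed, fence_buffer_m = fence_buffer_m,
         campsite_buffer_m = campsite_buffer_m),
    class = "pasture_geometry"
  )
}

#' Apply fence and campsite exclusion zones to waypoints
#'
#' Waypoints whose footprint centre falls within `fence_buffer_m` of the
#' boundary (or outside it) or within `campsite_buffer_m` of the campsite are
#' flagged as excluded. The effective sampling region is the boundary shrunk
#' by the fence buffer minus the campsite disc.
#'
#' @param pasture a [pasture_geometry()].
#' @param waypoints data frame with columns `x_m`, `y_m` (e.g. from
#'   [generate_route()]).
#' @return List with `waypoints` (input plus `excluded_flag`,
#'   `exclusion_reason`), `region` (effective region polygon, or NULL when
#'   the boundary is not an axis-aligned rectangle), and `area_m2`.
#' @export
apply_exclusion_zones <- function(pasture, waypoints) {
  stopifnot(inherits(pasture, "pasture_geometry"))
  wp <- as.data.frame(waypoints)
  stopifnot(all(c("x_m", "y_m") %in% names(wp)))
  inside <- point_in_poly(wp$x_m, wp$y_m, pasture$boundary)
  d_fence <- dist_to_poly_boundary(wp$x_m, wp$y_m, pasture$boundary)
  d_camp <- sqrt((wp$x_m - pasture$campsite_xy[1])^2 +
                 (wp$y_m - pasture$campsite_xy[2])^2)
  fence_hit <- !inside | d_fence < pasture$fence_buffer_m
  camp_hit <- d_camp < pasture$campsite_buffer_m
  wp$excluded_flag <- fence_hit | camp_hit
  wp$exclusion_reason <- ifelse(fence_hit, "fence_buffer",
                         ifelse(camp_hit, "campsite_buffer", ""))
  eff <- effective_region(pasture)
  if (eff$area_m2 <= 0) stop("effective sampling region is empty")
  list(waypoints = wp, region = eff$region, area_m2 = eff$area_m2)
}

# shrink the boundary by the fence buffer and subtract the campsite disc
effective_region <- function(pasture) {
  b <- pasture$boundary
  fb <- pasture$fence_buffer_m
  if (is_axis_rect(b)) {
    xr <- range(b[, 1]); yr <- range(b[, 2])
    if (2 * fb >= diff(xr) || 2 * fb >= diff(yr)) {
      return(list(region = NULL, area_m2 = 0))
    }
    shrunk <- rect_poly(xr[1] + fb, yr[1] + fb, xr[2] - fb, yr[2] - fb)
    area <- poly_area(shrunk)
    if (pasture$campsite_buffer_m > 0) {
      disc <- disc_poly(pasture$campsite_xy[1], pasture$campsite_xy[2],
                        pasture$campsite_buffer_m)
      cut <- clip_poly(disc, shrunk)
      if (!is.null(cut)) area <- area - poly_area(cut)
    }
    return(list(region = shrunk, area_m2 = area))
  }
  # generic polygon: area by fine-grid counting, no region polygon
  xr <- range(b[, 1]); yr <- range(b[, 2])
  step <- max(diff(xr), diff(yr)) / 400
  gx <- seq(xr[1] + step / 2, xr[2], by = step)
  gy <- seq(yr[1] + step / 2, yr[2], by = step)
  g <- expand.grid(x = gx, y = gy)
  keep <- point_in_poly(g$x, g$y, b)
  keep <- keep & dist_to_poly_boundary(g$x, g$y, b) >= fb
  keep <- keep & (sqrt((g$x - pasture$campsite_xy[1])^2 +
                       (g$y - pasture$campsite_xy[2])^2) >=
                    pasture$campsite_buffer_m)
  warning("non-rectangular boundary: effective area estimated by grid counting")
  list(region = NULL, area_m2 = sum(keep) * step^2)
}

#' Riverbed overlap filter for aerial images
#'
#' Excludes an image whose footprint is dominated by riverbed: the image is
#' excluded when the intersection area divided by the footprint area is
#' greater than or equal to `threshold`. The tie at exactly the threshold is
#' excluded, matching the rule that near-half riverbed coverage already
#' biases dung counts.
#'
#' @param fp a [footprint()].
#' @param riverbed riverbed polygon vertex matrix (may be NULL: keep).
#' @param threshold exclusion threshold on the overlap fraction (default 0.5).
#' @return List with `keep` (logical), `overlap_fraction`.
#' @export
riverbed_image_filter <- function(fp, riverbed, threshold = 0.5) {
  stopifnot(inherits(fp, "footprint"))
  if (fp$area_m2 <= 0) stop("degenerate footprint with zero area")
  if (is.null(riverbed)) return(list(keep = TRUE, overlap_fraction = 0))
  inter <- clip_poly(as_poly(riverbed), footprint_poly(fp))
  frac <- if (is.null(inter)) 0 else poly_area(inter) / fp$area_m2
  list(keep = frac < threshold, overlap_fraction = frac)
}
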