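# Independent oracles used across the suite.

# area fraction of `poly` inside the axis-aligned rectangle of a footprint,
# by brute-force fine-grid counting over the footprint
grid_overlap_fraction <- function(fp, poly, n = 200L) {
  xs <- seq(fp$center_xy[1] - fp$width_m / 2, fp$center_xy[1] + fp$width_m / 2,
            length.out = n + 1L)
  ys <- seq(fp$center_xy[2] - fp$length_m / 2,
            fp$center_xy[2] + fp$length_m / 2, length.out = n + 1L)
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  g <- expand.grid(x = cx, y = cy)
  mean(grazeproxy:::point_in_poly(g$x, g$y, poly))
}

# hand-rolled OLS via the normal equations
ols_normal_equations <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  n <- length(y)
  sigma2 <- ss_res / (n - 2)
  f <- ((ss_tot - ss_res) / 1) / sigma2
  list(intercept = beta[1], slope = beta[2], r_squared = 1 - ss_res / ss_tot,
       p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE),
       resid_sd = sqrt(sigma2))
}

# small square pasture helper (side in metres)
square_pasture <- function(side, campsite = c(side / 2, side / 2),
                           fence_buffer_m = 0, campsite_buffer_m = 0,
                           riverbed = NULL) {
  pasture_geometry(grazeproxy:::rect_poly(0, 0, side, side), campsite,
                   riverbed = riverbed, fence_buffer_m = fence_buffer_m,
                   campsite_buffer_m = campsite_buffer_m)
}

# fast sim_config for pipeline-level tests: small herd, short season,
# coarse grid, fixed design draws
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, herd_size = 15L, months = 5:7,
             monitored_days_range = c(4L, 4L),
             snapshots_per_day_range = c(4L, 4L),
             cell_size_m = 50, ...)
}
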