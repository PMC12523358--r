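test_that("triangular kernel has the conical closed form and unit mass", {
  k <- triangular_kernel(300)
  expect_equal(kernel_value(0, k), 3 / (pi * 300^2), tolerance = 1e-12)
  expect_equal(kernel_value(150, k), 3 / (pi * 300^2) * 0.5, tolerance = 1e-12)
  expect_equal(kernel_value(300, k), 0)
  expect_equal(kernel_value(1e6, k), 0)
  expect_error(kernel_value(-1, k), ">= 0")
  expect_error(triangular_kernel(0), "> 0")
  # polar quadrature oracle: integral of 2*pi*r*K(r) over [0, h] equals 1
  for (h in c(50, 300, 1234)) {
    kk <- triangular_kernel(h)
    mass <- stats::integrate(function(r) 2 * pi * r * kernel_value(r, kk),
                             0, h, rel.tol = 1e-10)$value
    expect_lt(abs(mass - 1), 1e-3)
  }
})

test_that("one interior individual deposits one yak-hour of raster mass", {
  grid <- list(origin = c(0, 0), cell_size_m = 1, n_rows = 700, n_cols = 700)
  s <- herd_snapshot(5, 1, 8, cbind(350, 350))
  r <- snapshot_intensity(s, grid, triangular_kernel(300))
  expect_lt(abs(raster_total(r) - 1), 0.01)
  # empty snapshot: all-zero raster
  e <- herd_snapshot(5, 1, 8, matrix(numeric(0), ncol = 2))
  expect_equal(raster_total(snapshot_intensity(e, grid)), 0)
  # boundary truncation: mass within the grid of an edge-near kernel is < 1
  edge <- snapshot_intensity(herd_snapshot(5, 1, 8, cbind(50, 350)), grid,
                             triangular_kernel(300))
  expect_lt(raster_total(edge), 1)
  expect_gt(raster_total(edge), 0.4)
})

test_that("snapshot rasterization is additive and warns on outside positions", {
  grid <- list(origin = c(0, 0), cell_size_m = 5, n_rows = 100, n_cols = 100)
  k <- triangular_kernel(120)
  set.seed(9)
  pos <- cbind(runif(12, 0, 500), runif(12, 0, 500))
  merged <- snapshot_intensity(herd_snapshot(5, 1, 8, pos), grid, k)
  a <- snapshot_intensity(herd_snapshot(5, 1, 8, pos[1:5, ]), grid, k)
  b <- snapshot_intensity(herd_snapshot(5, 1, 8, pos[6:12, ]), grid, k)
  expect_equal(merged$values, a$values + b$values, tolerance = 1e-12)
  expect_warning(
    snapshot_intensity(herd_snapshot(5, 1, 8, cbind(-50, 250)), grid, k),
    "outside the grid")
})

test_that("raster mass is stable under grid refinement", {
  k <- triangular_kernel(120)
  s <- herd_snapshot(6, 2, 9, cbind(c(200, 260, 310), c(250, 240, 300)))
  tot <- vapply(c(0.5, 2), function(cs) {
    grid <- list(origin = c(0, 0), cell_size_m = cs,
                 n_rows = 500 / cs, n_cols = 500 / cs)
    raster_total(snapshot_intensity(s, grid, k))
  }, numeric(1))
  expect_lt(abs(tot[1] - tot[2]) / tot[2], 0.02)
})

test_that("monthly intensity applies snapshot weights and the monitoring-day adjustment", {
  grid <- list(origin = c(0, 0), cell_size_m = 2, n_rows = 250, n_cols = 250)
  k <- triangular_kernel(100)
  n_yak <- 7
  set.seed(31)
  pos <- cbind(runif(n_yak, 200, 300), runif(n_yak, 200, 300))
  # 4 monitored of 30 days, stationary herd, 12 snapshots over 12 grazed
  # hours: expected month total N * 12 * 30 yak-hours
  snaps <- list()
  for (d in c(3, 9, 17, 25)) for (h in 1:12) {
    snaps[[length(snaps) + 1]] <- herd_snapshot(6, d, 7 + h, pos)
  }
  plan <- monitoring_plan(6, 30, c(3, 9, 17, 25), grazing_hours_per_day = 12)
  r <- monthly_intensity(snaps, plan, grid, k)
  expect_lt(abs(raster_total(r) - n_yak * 12 * 30) / (n_yak * 12 * 30), 0.01)
  expect_equal(r$meta$adjustment_factor, 30 / 4)
  # all days monitored, one snapshot per grazed hour: plain sum of snapshots
  snaps1 <- lapply(1:3, function(d) herd_snapshot(6, d, 8, pos))
  plan1 <- suppressMessages(monitoring_plan(6, 3, 1:3, grazing_hours_per_day = 1))
  r1 <- monthly_intensity(snaps1, plan1, grid, k)
  plain <- Reduce(`+`, lapply(snaps1, function(s)
    snapshot_intensity(s, grid, k)$values))
  expect_equal(r1$values, plain, tolerance = 1e-12)
  # duplicating every monitored day's snapshots under new day labels while
  # doubling the monitored-day count leaves the estimate unchanged
  planA <- monitoring_plan(6, 30, c(3, 9, 17, 25), grazing_hours_per_day = 1)
  snapsA <- lapply(c(3, 9, 17, 25), function(d) herd_snapshot(6, d, 8, pos))
  rA <- monthly_intensity(snapsA, planA, grid, k)
  dup_days <- c(3, 9, 17, 25, 4, 10, 18, 26)
  planB <- monitoring_plan(6, 30, dup_days, grazing_hours_per_day = 1)
  snapsB <- lapply(dup_days, function(d) herd_snapshot(6, d, 8, pos))
  rB <- monthly_intensity(snapsB, planB, grid, k)
  expect_equal(rB$values, rA$values, tolerance = 1e-9)
  # plan violations
  expect_error(monthly_intensity(snaps1, plan, grid, k), "plan")
  expect_error(monitoring_plan(6, 30, integer(0)), "at least one")
})

test_that("cumulative intensity is a commutative cellwise sum with mass additivity", {
  grid <- list(origin = c(0, 0), cell_size_m = 2, n_rows = 100, n_cols = 100)
  k <- triangular_kernel(60)
  mk <- function(m, seed) {
    set.seed(seed)
    r <- snapshot_intensity(
      herd_snapshot(m, 1, 8, cbind(runif(5, 50, 150), runif(5, 50, 150))),
      grid, k)
    intensity_raster(r$values, grid$origin, grid$cell_size_m,
                     period = month.abb[m])
  }
  may <- mk(5, 1); jun <- mk(6, 2)
  expect_identical(cumulative_intensity(list(may))$values, may$values)
  ab <- cumulative_intensity(list(may, jun))
  ba <- cumulative_intensity(list(jun, may))
  expect_identical(ab$values, ba$values)
  expect_lt(abs(raster_total(ab) - (raster_total(may) + raster_total(jun))) /
              raster_total(ab), 1e-9)
  other <- intensity_raster(matrix(0, 10, 10), c(0, 0), 2, period = "Jul")
  expect_error(cumulative_intensity(list(may, other)), "common grid")
})

test_that("footprint extraction returns means and centre values correctly", {
  # uniform raster: the mean is the constant
  u <- intensity_raster(matrix(3.5, 50, 50), c(0, 0), 1, period = "May")
  fp <- footprint(c(25, 25), 10, 6)
  expect_equal(sample_intensity_at(u, fp), 3.5)
  # linear-gradient plane: centred footprint mean equals the centre value
  # (analytic integral of a plane over a symmetric window)
  vals <- outer(seq_len(50), seq_len(50), function(r, c) 2 * c + 3 * r)
  g <- intensity_raster(vals, c(0, 0), 1, period = "May")
  centre_val <- sample_intensity_at(g, fp, mode = "center")
  expect_lt(abs(sample_intensity_at(g, fp) - centre_val), 2 + 3)
  # centre mode picks the containing cell
  expect_equal(centre_val, vals[25 + 1, 25 + 1])
  expect_error(sample_intensity_at(g, footprint(c(500, 500), 4, 4)),
               "outside|inside")
})
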