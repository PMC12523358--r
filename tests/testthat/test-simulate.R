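test_that("the virtual pasture has the configured area, campsite and riverbed", {
  p <- simulate_pasture(sim_config())
  expect_lt(abs(grazeproxy:::poly_area(p$boundary) - 113.64e4), 1e-6 * 113.64e4)
  expect_null(p$riverbed)
  # 100 ha square -> 1000 m side
  p100 <- simulate_pasture(sim_config(pasture_area_ha = 100))
  expect_equal(diff(range(p100$boundary[, 1])), 1000, tolerance = 1e-9)
  pr <- simulate_pasture(sim_config(riverbed_enabled = TRUE))
  expect_false(is.null(pr$riverbed))
  expect_error(simulate_pasture(sim_config(pasture_area_ha = 0.5)),
               "fence buffer")
})

test_that("config validation rejects impossible rates and probabilities", {
  expect_error(sim_config(deposition_rate = -1), ">= 0")
  expect_error(sim_config(detection_prob_by_height = c("2" = 1.2)), "\\[0, 1\\]")
  expect_error(sim_config(rho = 1), "rho")
})

test_that("daily movement has the right snapshot count and a campsite-decay field", {
  cfg <- sim_config(seed = 3, herd_size = 40)
  p <- simulate_pasture(cfg)
  set.seed(11)
  day <- simulate_day(cfg, p, 5, 1)
  expect_gte(length(day), 12); expect_lte(length(day), 14)
  expect_true(all(vapply(day, function(s) s$herd_size == 40, logical(1))))
  # empty herd yields empty snapshots
  cfg0 <- sim_config(herd_size = 0)
  day0 <- simulate_day(cfg0, p, 5, 1, n_hours = 12)
  expect_true(all(vapply(day0, function(s) s$herd_size == 0, logical(1))))
  expect_error(simulate_day(sim_config(lambda_m = -5), p, 5, 1),
               "lambda_m|>= 0")
  # near-flat field (huge lambda, no autocorrelation, no edge contraction,
  # herd collapsed on its centre): mean distance to campsite matches the
  # uniform-over-pasture Monte Carlo oracle within 3 SE
  cfgU <- sim_config(seed = 3, herd_size = 1, lambda_m = 1e9, rho = 0,
                     day_edge_contraction = FALSE, herd_spread_m = 0)
  set.seed(12)
  n_days <- 40
  d_obs <- unlist(lapply(seq_len(n_days), function(d) {
    vapply(simulate_day(cfgU, p, 5, d, n_hours = 12), function(s) {
      sqrt(sum((s$positions[1, ] - p$campsite_xy)^2))
    }, numeric(1))
  }))
  set.seed(13)
  side <- sqrt(113.64e4)
  ux <- runif(2e5, 0, side); uy <- runif(2e5, 0, side)
  d_unif <- sqrt((ux - p$campsite_xy[1])^2 + (uy - p$campsite_xy[2])^2)
  se <- sd(d_obs) / sqrt(length(d_obs))
  expect_lt(abs(mean(d_obs) - mean(d_unif)), 3 * se)
  # the default field concentrates the herd towards the campsite
  cfgC <- sim_config(seed = 3, herd_size = 1, rho = 0, herd_spread_m = 0)
  set.seed(14)
  d_camp <- unlist(lapply(seq_len(20), function(d) {
    vapply(simulate_day(cfgC, p, 5, d, n_hours = 12), function(s) {
      sqrt(sum((s$positions[1, ] - p$campsite_xy)^2))
    }, numeric(1))
  }))
  expect_lt(mean(d_camp), mean(d_unif))
})

test_that("dung deposition is Poisson in rate and stays inside the pasture", {
  cfg <- sim_config(seed = 5, herd_size = 30, deposition_rate = 0.8)
  p <- simulate_pasture(cfg)
  set.seed(21)
  snaps <- simulate_day(cfg, p, 5, 1, n_hours = 12)
  # rate 0: no pats
  cfg0 <- sim_config(deposition_rate = 0)
  expect_equal(nrow(deposit_dung(snaps, cfg0, p)), 0)
  # expected count N yak-hours * rate within 3 * sqrt(N * r)
  set.seed(22)
  pats <- deposit_dung(snaps, cfg, p)
  n_yh <- 30 * 12
  expect_lt(abs(nrow(pats) - n_yh * 0.8), 3 * sqrt(n_yh * 0.8))
  # clipped jitter keeps pats inside the pasture
  xr <- range(p$boundary[, 1]); yr <- range(p$boundary[, 2])
  expect_true(all(pats$x_m >= xr[1] & pats$x_m <= xr[2]))
  expect_true(all(pats$y_m >= yr[1] & pats$y_m <= yr[2]))
  # totals scale linearly with deposition rate (slope recovery within MC error)
  set.seed(23)
  cfg2 <- sim_config(seed = 5, herd_size = 30, deposition_rate = 1.6)
  pats2 <- deposit_dung(snaps, cfg2, p)
  ratio <- nrow(pats2) / nrow(pats)
  expect_lt(abs(ratio - 2), 6 * sqrt(1 / (n_yh * 0.8)))
})

test_that("decay thins month to month at exp(-delta) with riverbed washout", {
  cfg <- sim_config(decay_rate = 0)
  pats <- data.frame(id = 1:100, x_m = runif(100, 0, 10), y_m = runif(100, 0, 10),
                     month = 5L, day = 1L, hour = 8L, in_riverbed = FALSE,
                     survived_until = Inf)
  # delta = 0: all survive
  expect_true(all(is.infinite(decompose(pats, 5, cfg)$survived_until)))
  # monthly survival 0.5: about 25% remain after two month transitions
  cfg5 <- sim_config(decay_rate = -log(0.5))
  set.seed(31)
  n <- 4000
  big <- data.frame(id = 1:n, x_m = 0, y_m = 0, month = 5L, day = 1L,
                    hour = 8L, in_riverbed = FALSE, survived_until = Inf)
  big <- decompose(big, 5, cfg5)
  big <- decompose(big, 6, cfg5)
  surv <- nrow(standing_crop(big, 7))
  se <- sqrt(n * 0.25 * 0.75)
  expect_lt(abs(surv - n * 0.25), 3 * se)
  # age 0: a pat deposited in the survey month is always present
  expect_equal(nrow(standing_crop(big, 5)), n)
  # survival is non-increasing in age
  counts <- vapply(5:7, function(m) nrow(standing_crop(big, m)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # riverbed multiplier accelerates decay
  set.seed(32)
  riv <- data.frame(id = 1:n, x_m = 0, y_m = 0, month = 5L, day = 1L,
                    hour = 8L, in_riverbed = TRUE, survived_until = Inf)
  cfgr <- sim_config(decay_rate = -log(0.5), riverbed_decay_multiplier = 3)
  riv <- decompose(riv, 5, cfgr)
  expect_lt(nrow(standing_crop(riv, 6)), n * 0.25)
})

test_that("the observation model detects, drifts and refuses unknown heights", {
  cfg <- sim_config(detection_prob_by_height = c("2" = 1, "20" = 0.9316),
                    false_positive_rate = 0, gps_drift_max_m = 0)
  set.seed(41)
  pats <- data.frame(id = 1:500, x_m = runif(500, -10, 10),
                     y_m = runif(500, -8, 8), month = 5L, day = 1L, hour = 8L,
                     in_riverbed = FALSE, survived_until = Inf)
  fp <- footprint(c(0, 0), 20, 16)
  # perfect detection, no drift, no false positives: observed equals truth
  obs <- observe_dung(pats, fp, 2, cfg)
  expect_equal(obs$observed_count, obs$true_count)
  expect_equal(obs$true_count, 500L)
  # p = 0: only false positives remain
  cfg0 <- sim_config(detection_prob_by_height = c("20" = 0),
                     false_positive_rate = 2, gps_drift_max_m = 0)
  set.seed(42)
  obs0 <- observe_dung(pats, fp, 20, cfg0)
  expect_lt(obs0$observed_count, 15)
  expect_equal(obs0$true_count, 500L)
  # unknown heights are never interpolated
  expect_error(observe_dung(pats, fp, 10, cfg), "no detection probability")
  # without false positives, observed is stochastically below truth
  set.seed(43)
  reps <- replicate(50, observe_dung(pats, fp, 20, cfg)$observed_count)
  expect_true(all(reps <= 500))
  expect_gt(mean(reps), 0.9316 * 500 - 3 * sqrt(500 * 0.9316 * 0.0684))
})

test_that("the full virtual study is seed-reproducible with named substreams", {
  cfg <- tiny_config(seed = 17)
  a <- run_virtual_study(cfg)
  b <- run_virtual_study(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth_raster$values, b$truth_raster$values)
  expect_identical(lapply(a$monthly_rasters, `[[`, "values"),
                   lapply(b$monthly_rasters, `[[`, "values"))
  d <- run_virtual_study(tiny_config(seed = 18))
  expect_false(identical(a$counts$observed_count, d$counts$observed_count))
  # months produced span the configured season
  expect_equal(sort(unique(a$counts$month)), 5:7)
  full <- sim_config()
  expect_equal(full$months, 5:10)
  # substream seeds are distinct per stage
  seeds <- vapply(grazeproxy:::SIM_STREAMS, grazeproxy:::substream_seed,
                  integer(1), seed = 17)
  expect_equal(anyDuplicated(seeds), 0L)
})

test_that("with no decay and perfect detection dung density tracks true intensity", {
  cfg <- sim_config(seed = 23, decay_rate = 0,
                    detection_prob_by_height = c("2" = 1, "20" = 1),
                    false_positive_rate = 0, gps_drift_max_m = 0,
                    months = 5:7)
  st <- run_virtual_study(cfg)
  oct <- st$counts[st$counts$month == 7, ]
  expect_gte(mean(oct$observed_count), 20)
  dims <- st$footprint_dims
  intens <- vapply(seq_len(nrow(st$waypoints)), function(i) {
    sample_intensity_at(st$truth_raster,
                        footprint(c(st$waypoints$x_m[i], st$waypoints$y_m[i]),
                                  dims[["width_m"]], dims[["length_m"]]))
  }, numeric(1))
  dens <- dung_density(oct$observed_count, oct$footprint_area_m2)
  expect_gt(cor(dens, intens), 0.95)
})
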