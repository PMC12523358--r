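test_that("dung density divides counts by validation-area size", {
  expect_equal(dung_density(0, 6), 0)
  expect_equal(dung_density(18, 6), 3)
  # both standard validation areas are supported
  expect_equal(dung_density(1, 0.25), 4)
  expect_equal(dung_density(12, 6), 2)
  expect_error(dung_density(3, 0), "> 0")
  expect_error(dung_density(-1, 6), ">= 0")
})

test_that("accumulation pairing enumerates all windows ending at feasible months", {
  # k = 6 over May-Oct: exactly October with the full season
  p6 <- enumerate_pairs(6)
  expect_equal(nrow(p6$pairs), 1L)
  expect_equal(p6$pairs$dung_month, 10L)
  expect_equal(p6$pairs$window_start, 5L)
  # k = 2: June&May-June ... October&September-October
  p2 <- enumerate_pairs(2)
  expect_equal(nrow(p2$pairs), 5L)
  expect_equal(p2$pairs$dung_month, 6:10)
  expect_equal(p2$pairs$window_start, 5:9)
  # full enumeration counts 6,5,4,3,2,1; with June dropped at k = 1 the
  # same-month list has 5 entries
  expect_equal(vapply(1:6, function(k) nrow(enumerate_pairs(k)$pairs),
                      numeric(1)), c(6, 5, 4, 3, 2, 1))
  expect_equal(nrow(enumerate_pairs(1, exclude = 6)$pairs), 5L)
  # single-month season pairs the month with itself
  p1 <- enumerate_pairs(1, months = 7)
  expect_equal(p1$pairs$dung_month, 7L)
  expect_equal(p1$pairs$window_start, 7L)
  expect_error(enumerate_pairs(0), "between")
  expect_error(enumerate_pairs(7), "between")
  expect_error(enumerate_pairs(2, months = c(5, 7)), "consecutive")
})

test_that("the density-intensity fit matches hand-computed normal equations", {
  # 5-point hand dataset
  x <- c(0.1, 0.4, 0.9, 1.3, 2.0)
  y <- c(0.05, 0.30, 0.65, 1.10, 1.55)
  fit <- fit_relationship(y, x)
  want <- ols_normal_equations(y, x)
  expect_equal(fit$slope, want$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, want$intercept, tolerance = 1e-9)
  expect_equal(fit$r_squared, want$r_squared, tolerance = 1e-9)
  expect_equal(fit$p_value, want$p_value, tolerance = 1e-9)
  expect_equal(fit$resid_sd, want$resid_sd, tolerance = 1e-9)
  # exactly collinear points
  col <- fit_relationship(2 * x + 1, x)
  expect_equal(col$r_squared, 1, tolerance = 1e-12)
  # degenerate and error paths
  dg <- fit_relationship(rep(0.2, 5), x)
  expect_true(dg$degenerate)
  expect_equal(dg$r_squared, 0)
  expect_true(is.na(dg$p_value))
  expect_error(fit_relationship(y, rep(1, 5)), "zero variance")
  expect_error(fit_relationship(y[1:2], x[1:2]), "at least 3")
  expect_error(fit_relationship(y, x[1:4]), "equal length")
})

test_that("OLS agrees with the normal-equations oracle on random datasets", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 5))
    y <- runif(1, -2, 2) + runif(1, -3, 3) * x + rnorm(n, sd = 0.3)
    fit <- fit_relationship(y, x)
    want <- ols_normal_equations(y, x)
    expect_equal(fit$slope, want$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, want$r_squared, tolerance = 1e-9)
  }
})

test_that("the R2 trend regression behaves on constructed inputs", {
  mk <- function(k, r2) structure(list(k = k, r_squared = r2, degenerate = FALSE),
                                  class = "calibration_result")
  # identical R2 at all k: zero slope
  flat <- r2_trend(list(mk(1, 0.5), mk(2, 0.5), mk(3, 0.5)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  # R2 exactly linear in k: perfect trend
  lin <- r2_trend(lapply(1:5, function(k) mk(k, 0.1 * k)))
  expect_equal(lin$r_squared, 1, tolerance = 1e-9)
  expect_equal(lin$slope, 0.1, tolerance = 1e-9)
  # degenerate fits are excluded, identical-k inputs refused
  dg <- structure(list(k = 4, r_squared = 0, degenerate = TRUE),
                  class = "calibration_result")
  expect_equal(r2_trend(list(mk(1, 0.2), mk(2, 0.4), mk(3, 0.6), dg))$n, 3)
  expect_error(r2_trend(list(mk(2, 0.1), mk(2, 0.2), mk(2, 0.3))), "distinct k")
  expect_error(r2_trend(list(mk(1, 0.1), dg)), "at least 3")
})

test_that("flight-height accuracy comparison picks ANOVA or rank-sum correctly", {
  # well-separated near-normal groups sized like the validation design
  set.seed(55)
  acc2 <- pmin(1, 0.995 + rnorm(9, 0, 0.004))
  acc20 <- 0.93 + rnorm(30, 0, 0.02)
  res <- compare_accuracy(acc2, acc20)
  expect_lt(res$p_value, 0.001)
  expect_true(res$test %in% c("anova", "wilcoxon"))
  # ANOVA on clean normal groups matches the hand F computation
  a <- c(0.91, 0.93, 0.92, 0.94, 0.90, 0.95, 0.929, 0.941, 0.912)
  b <- a + 0.05
  res2 <- compare_accuracy(a, b)
  expect_equal(res2$test, "anova")
  grand <- mean(c(a, b))
  ss_b <- length(a) * (mean(a) - grand)^2 + length(b) * (mean(b) - grand)^2
  ss_w <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  f_hand <- (ss_b / 1) / (ss_w / (length(a) + length(b) - 2))
  expect_equal(res2$statistic, f_hand, tolerance = 1e-9)
  expect_equal(res2$p_value,
               pf(f_hand, 1, length(a) + length(b) - 2, lower.tail = FALSE),
               tolerance = 1e-9)
  # identical groups: no significance
  set.seed(56)
  g <- rnorm(10, 0.9, 0.01)
  same <- compare_accuracy(g, g)
  expect_gt(same$p_value, 0.95)
  # all-equal degenerate groups fall back to the flagged rank-sum path
  dg <- compare_accuracy(rep(0.9, 5), rep(0.9, 6))
  expect_equal(dg$test, "wilcoxon")
  expect_true(dg$degenerate)
  expect_error(compare_accuracy(c(0.9, 0.91), acc20), "at least 3")
})

test_that("inverse prediction recovers intensity and respects physical bounds", {
  x <- seq(0.2, 3, length.out = 20)
  set.seed(66)
  y <- 0.1 + 0.8 * x + rnorm(20, 0, 0.02)
  cal <- fit_relationship(y, x)
  # density equal to the intercept estimates zero intensity
  at0 <- predict_intensity(cal, cal$intercept)
  expect_equal(at0$intensity, 0, tolerance = 1e-9)
  # round trip through the fitted line
  pred <- predict_intensity(cal, cal$intercept + cal$slope * 1.7)
  expect_equal(pred$intensity, 1.7, tolerance = 1e-9)
  expect_lt(pred$lower, 1.7); expect_gt(pred$upper, 1.7)
  # negative estimates are clamped and flagged
  neg <- predict_intensity(cal, cal$intercept - 1)
  expect_equal(neg$intensity, 0)
  expect_true(neg$clamped)
  # a non-positive slope violates the proxy premise
  bad <- fit_relationship(rev(y), x)
  expect_error(predict_intensity(bad, 0.5), "slope")
})
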