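# Calibration stage: dung densities, accumulation-window pairing, OLS
# density-intensity relationships with R^2 / p, the R^2-vs-duration trend,
# the flight-height accuracy comparison, and inverse prediction.

#' Dung density from a count and an area
#'
#' @param count non-negative pat count(s).
#' @param area_m2 surveyed area (m^2), `> 0`.
#' @return Density in pats per square metre.
#' @examples
#' dung_density(18, 6)  # 3 pats / m^2
#' @export
dung_density <- function(count, area_m2) {
  if (any(area_m2 <= 0)) stop("area_m2 must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count / area_m2
}

#' Enumerate accumulation-window pairings
#'
#' For accumulation length `k`, every window of `k` consecutive months
#' ending at a feasible dung month is paired with that month's dung density:
#' e.g. over May-October, `k = 2` yields June with May-June grazing through
#' October with September-October grazing, and `k = 6` yields the single
#' pairing of October with the full season. All feasible windows are
#' enumerated; study-specific exclusions are passed via `exclude`.
#'
#' @param k accumulation length in months, `1 <= k <= length(months)`.
#' @param months integer vector of consecutive available months (default
#'   May-October).
#' @param exclude optional integer vector of dung months to drop from the
#'   enumeration.
#' @return An object of class `pairing_scheme`: list with `k` and `pairs`,
#'   a data frame of `dung_month`, `window_start`, `window_end`.
#' @examples
#' enumerate_pairs(6)$pairs            # October & May-October only
#' nrow(enumerate_pairs(2)$pairs)      # 5
#' @export
enumerate_pairs <- function(k, months = 5:10, exclude = NULL) {
  months <- sort(as.integer(months))
  if (length(months) > 1 && any(diff(months) != 1L)) {
    stop("months must be consecutive")
  }
  if (k < 1 || k > length(months)) {
    stop("k must lie between 1 and the number of available months")
  }
  ends <- months[months >= months[1] + k - 1L]
  if (!is.null(exclude)) ends <- setdiff(ends, as.integer(exclude))
  pairs <- data.frame(dung_month = ends, window_start = ends - k + 1L,
                      window_end = ends)
  structure(list(k = as.integer(k), pairs = pairs), class = "pairing_scheme")
}

#' Fit the dung density vs grazing intensity relationship
#'
#' Ordinary least squares of dung density on cumulative grazing intensity;
#' the p-value is the slope F-test. A density vector with zero variance
#' (e.g. all-zero counts at sites where pats vanished) produces a flagged
#' degenerate result rather than a fit.
#'
#' @param densities dung densities (pats per m^2).
#' @param intensities cumulative grazing intensities (yak-hours per m^2).
#' @param k,dung_month optional labels stored in the result.
#' @return An object of class `calibration_result`: `k`, `dung_month`, `n`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `resid_sd`, `degenerate`.
#' @export
fit_relationship <- function(densities, intensities, k = NA_integer_,
                             dung_month = NA_integer_) {
  if (length(densities) != length(intensities)) {
    stop("densities and intensities must have equal length")
  }
  keep <- is.finite(densities) & is.finite(intensities)
  densities <- densities[keep]; intensities <- intensities[keep]
  n <- length(densities)
  if (n < 3) stop("at least 3 points are required for a fit")
  if (stats::var(intensities) == 0) {
    stop("zero variance in intensity: relationship is not identifiable")
  }
  if (stats::var(densities) == 0) {
    return(structure(
      list(k = k, dung_month = dung_month, n = n, slope = 0,
           intercept = densities[1], r_squared = 0, p_value = NA_real_,
           resid_sd = 0, degenerate = TRUE),
      class = "calibration_result"))
  }
  fit <- stats::lm(densities ~ intensities)
  # exactly collinear inputs are legitimate here; summary.lm warns on them
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(
    list(k = k, dung_month = dung_month, n = n,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared, p_value = unname(p),
         resid_sd = sm$sigma, degenerate = FALSE),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> k=%s month=%s n=%d slope=%.4g intercept=%.4g R2=%.3f p=%.3g%s\n",
    x$k, if (is.na(x$dung_month)) "NA" else month_label(x$dung_month), x$n,
    x$slope, x$intercept, x$r_squared, x$p_value,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Trend of R-squared with accumulation duration
#'
#' OLS of the per-pair coefficients of determination on the accumulation
#' length k (replicated points per k allowed). Degenerate fits are excluded:
#' only genuine fitted relationships enter the trend.
#'
#' @param results list of [fit_relationship()] results with `k` labels.
#' @return List with `slope`, `r_squared`, `p_value`, `n` and the data used.
#' @export
r2_trend <- function(results) {
  ok <- vapply(results, function(r) !isTRUE(r$degenerate), logical(1))
  results <- results[ok]
  if (length(results) < 3) stop("at least 3 non-degenerate results required")
  k <- vapply(results, function(r) as.numeric(r$k), numeric(1))
  r2 <- vapply(results, function(r) r$r_squared, numeric(1))
  if (length(unique(k)) < 2) stop("results must span at least 2 distinct k")
  fit <- stats::lm(r2 ~ k)
  sm <- suppressWarnings(summary(fit))
  p <- if (stats::var(r2) == 0) NA_real_ else {
    fstat <- sm$fstatistic
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, n = length(k),
       data = data.frame(k = k, r_squared = r2))
}

#' Compare identification accuracy between flight heights
#'
#' Shapiro-Wilk normality per group and Levene homogeneity of variances at
#' alpha = 0.05; when both hold, a one-way ANOVA tests the flight-height
#' effect, otherwise a Wilcoxon rank-sum fallback is used (and logged in
#' the returned `path`). Accuracy fractions are analysed untransformed by
#' default; `transform = "arcsine"` applies the arcsine-square-root.
#'
#' @param acc_a,acc_b numeric vectors of per-sample accuracy fractions for
#'   the two heights (each `n >= 3`).
#' @param alpha assumption-test level (default 0.05).
#' @param transform `"none"` (default) or `"arcsine"`.
#' @return List: `test` ("anova" or "wilcoxon"), `statistic`, `p_value`,
#'   `path` (character log of the assumption checks), `group_means`.
#' @export
compare_accuracy <- function(acc_a, acc_b, alpha = 0.05,
                             transform = c("none", "arcsine")) {
  transform <- match.arg(transform)
  if (length(acc_a) < 3 || length(acc_b) < 3) {
    stop("at least 3 records per group are required")
  }
  if (transform == "arcsine") {
    acc_a <- asin(sqrt(pmin(pmax(acc_a, 0), 1)))
    acc_b <- asin(sqrt(pmin(pmax(acc_b, 0), 1)))
  }
  vals <- c(acc_a, acc_b)
  grp <- factor(rep(c("a", "b"), c(length(acc_a), length(acc_b))))
  path <- character(0)
  degenerate <- stats::var(acc_a) == 0 || stats::var(acc_b) == 0
  normal <- FALSE; homogeneous <- FALSE
  if (degenerate) {
    path <- c(path, "degenerate group with zero variance: rank-sum fallback")
  } else {
    sw_a <- stats::shapiro.test(acc_a)$p.value
    sw_b <- stats::shapiro.test(acc_b)$p.value
    normal <- sw_a > alpha && sw_b > alpha
    path <- c(path, sprintf("shapiro-wilk p = %.3g / %.3g -> %s", sw_a, sw_b,
                            if (normal) "normal" else "non-normal"))
    lev <- car::leveneTest(vals ~ grp)
    lev_p <- lev[["Pr(>F)"]][1]
    homogeneous <- lev_p > alpha
    path <- c(path, sprintf("levene p = %.3g -> %s", lev_p,
                            if (homogeneous) "homogeneous" else "heteroscedastic"))
  }
  if (!degenerate && normal && homogeneous) {
    fit <- stats::aov(vals ~ grp)
    sm <- summary(fit)[[1]]
    res <- list(test = "anova", statistic = sm[["F value"]][1],
                p_value = sm[["Pr(>F)"]][1])
    path <- c(path, "assumptions met: one-way ANOVA")
  } else if (stats::var(vals) == 0) {
    # every observation tied across both groups: no evidence of a difference
    res <- list(test = "wilcoxon", statistic = NA_real_, p_value = 1)
    path <- c(path, "all observations tied: p fixed at 1")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(acc_a, acc_b, exact = FALSE))
    res <- list(test = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value)
    path <- c(path, "rank-sum fallback used")
  }
  c(res, list(path = path,
              group_means = c(a = mean(acc_a), b = mean(acc_b)),
              degenerate = degenerate))
}

#' Invert a calibration to estimate grazing intensity from dung density
#'
#' First-order inverse regression: the point estimate is
#' `(density - intercept) / slope`, with an interval of plus/minus
#' `z * resid_sd / slope`. Estimates below zero are clamped to zero and
#' flagged. A non-positive slope contradicts the proxy premise (more grazing
#' leaves more dung) and is refused.
#'
#' @param calibration a non-degenerate [fit_relationship()] result.
#' @param density observed dung density (pats per m^2); vectorised.
#' @param level interval coverage (default 0.95).
#' @return Data frame: `density`, `intensity`, `lower`, `upper`, `clamped`.
#' @export
predict_intensity <- function(calibration, density, level = 0.95) {
  stopifnot(inherits(calibration, "calibration_result"))
  if (isTRUE(calibration$degenerate)) stop("calibration is degenerate")
  if (calibration$slope <= 0) {
    stop("non-positive slope: dung density does not track grazing intensity")
  }
  est <- (density - calibration$intercept) / calibration$slope
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * calibration$resid_sd / calibration$slope
  clamped <- est < 0
  lower <- pmax(est - half, 0)
  upper <- pmax(est + half, 0)
  est <- pmax(est, 0)
  data.frame(density = density, intensity = est, lower = lower,
             upper = upper, clamped = clamped)
}

#' Calibrate a virtual study
#'
#' Runs the full calibration stage on a [run_virtual_study()] result: dung
#' densities per waypoint and month, cumulative grazing-intensity extraction
#' at every waypoint footprint for every accumulation window, an OLS fit per
#' (dung month, window) pair for k = 1..K, and the R^2-vs-k trend.
#'
#' @param study a `virtual_study`.
#' @param k_range accumulation lengths to fit (default 1 to the number of
#'   months).
#' @param mode intensity extraction mode, see [sample_intensity_at()].
#' @param use_truth pair densities with the true cumulative occupancy
#'   surface instead of the KDE estimate (parameter-recovery analyses).
#' @param exclude optional dung months to exclude per k (named list, names =
#'   k; or a vector applied to all k).
#' @return List: `results` (list of `calibration_result`), `table` (data
#'   frame summary), `trend` (from [r2_trend()], or NULL when too few
#'   non-degenerate fits).
#' @export
calibrate_study <- function(study, k_range = NULL,
                            mode = c("footprint_mean", "center"),
                            use_truth = FALSE, exclude = NULL) {
  stopifnot(inherits(study, "virtual_study"))
  mode <- match.arg(mode)
  months <- study$config$months
  if (is.null(k_range)) k_range <- seq_along(months)
  dims <- study$footprint_dims
  wps <- study$waypoints
  fps <- lapply(seq_len(nrow(wps)), function(i) {
    footprint(c(wps$x_m[i], wps$y_m[i]), dims[["width_m"]], dims[["length_m"]])
  })
  # per-month densities keyed by waypoint order
  dens_by_month <- lapply(months, function(m) {
    cm <- study$counts[study$counts$month == m, ]
    cm <- cm[match(wps$waypoint_id, cm$waypoint_id), ]
    dung_density(cm$observed_count, cm$footprint_area_m2)
  })
  names(dens_by_month) <- month_label(months)
  results <- list()
  for (k in k_range) {
    excl_k <- if (is.list(exclude)) exclude[[as.character(k)]] else exclude
    scheme <- enumerate_pairs(k, months, exclude = excl_k)
    for (i in seq_len(nrow(scheme$pairs))) {
      pr <- scheme$pairs[i, ]
      window <- pr$window_start:pr$window_end
      cum <- if (use_truth) {
        # truth is the full-season occupancy: only the full window matches
        study$truth_raster
      } else {
        cumulative_intensity(study$monthly_rasters[month_label(window)])
      }
      if (use_truth && !identical(sort(window), sort(months))) next
      intens <- vapply(fps, function(fp) sample_intensity_at(cum, fp, mode),
                       numeric(1))
      dens <- dens_by_month[[month_label(pr$dung_month)]]
      res <- fit_relationship(dens, intens, k = k, dung_month = pr$dung_month)
      results[[sprintf("k%d_%s", k, month_label(pr$dung_month))]] <- res
    }
  }
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(k = r$k, dung_month = month_label(r$dung_month), n = r$n,
               slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, p_value = r$p_value,
               degenerate = r$degenerate)
  }))
  rownames(tab) <- NULL
  ok <- vapply(results, function(r) !r$degenerate, logical(1))
  kk <- vapply(results[ok], function(r) r$k, numeric(1))
  trend <- if (sum(ok) >= 3 && length(unique(kk)) >= 2) r2_trend(results) else NULL
  list(results = results, table = tab, trend = trend)
}
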