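## Circular (time-of-day) kernel density estimation and the coefficient of
## activity overlap between two groups, with a nonparametric bootstrap CI.

#' Convert clock times to angles
#'
#' Maps the clock time of each timestamp to an angle on `[0, 2pi)`
#' (midnight = 0, noon = pi).
#'
#' @param timestamps POSIXct vector.
#' @return numeric vector of radians.
#' @export
timesToRadians <- function(timestamps) {
  secs <- as.numeric(timestamps) -
    as.numeric(as.POSIXct(format(timestamps, "%Y-%m-%d"), tz = "UTC"))
  (secs / 86400 * 2 * pi) %% (2 * pi)
}

#' Collapse same-hour clusters to their median event
#'
#' Within each (station, calendar date, clock hour) group containing more
#' than one event, a single event at the median timestamp replaces the
#' group (for an even count, the midpoint of the two central times).
#'
#' @param events validated event data frame.
#' @return the collapsed event data frame, time-ordered.
#' @export
medianCollapse <- function(events) {
  if (!nrow(events)) return(events)
  events <- events[order(events$timestamp), , drop = FALSE]
  key <- paste(events$station_id, events$date,
               format(events$timestamp, "%H"))
  groups <- split(seq_len(nrow(events)), key)
  keep <- lapply(groups, function(idx) {
    if (length(idx) == 1) return(events[idx, , drop = FALSE])
    row <- events[idx[1], , drop = FALSE]
    med <- median(as.numeric(events$timestamp[idx]))
    row$timestamp <- as.POSIXct(med, tz = "UTC",
                                origin = "1970-01-01")
    if (!is.null(row$datetime))
      row$datetime <- format(row$timestamp, "%Y-%m-%d %H:%M:%S")
    row
  })
  out <- do.call(rbind, keep)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## von Mises concentration MLE via the standard A1-inverse approximations
.vmKappaMLE <- function(theta) {
  R <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
  else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
  else 1 / (R^3 - 4 * R^2 + 3 * R)
}

## plug-in smoothing concentration for the von Mises kernel
.ruleKappa <- function(theta) {
  kap <- .vmKappaMLE(theta)
  n <- length(theta)
  ((3 * n * kap^2 * besselI(2 * kap, 2)) /
      (4 * sqrt(pi) * besselI(kap, 0)^2))^(2 / 5)
}

## kernel density at grid points; numerically stable for large kappa
.vmKdeAt <- function(grid, sample, kappa) {
  denom <- 2 * pi * besselI(kappa, 0, expon.scaled = TRUE)
  rowMeans(exp(kappa * (cos(outer(grid, sample, "-")) - 1))) / denom
}

#' Circular kernel density estimate of activity times
#'
#' Von Mises kernel density on `[0, 2pi)`; the kernel concentration comes
#' from the circular plug-in bandwidth rule fitted to the sample, divided by
#' `adjust` (larger `adjust` smooths more). The density integrates to 1 over
#' the circle.
#'
#' @param sample numeric vector of angles in radians (at least 2).
#' @param gridN number of evaluation points (default 512).
#' @param adjust bandwidth adjustment (default 1).
#' @param kappa optional kernel concentration overriding the rule.
#' @return list of class `circularDensity` with `x` (grid), `y` (density),
#'   `kappa` and `n`.
#' @export
circularKde <- function(sample, gridN = 512, adjust = 1, kappa = NULL) {
  if (length(sample) < 2)
    stop("need at least 2 observations", call. = FALSE)
  if (any(sample < 0 | sample >= 2 * pi))
    sample <- sample %% (2 * pi)
  if (is.null(kappa)) kappa <- .ruleKappa(sample) / adjust
  grid <- seq(0, 2 * pi, length.out = gridN + 1)[seq_len(gridN)]
  out <- list(x = grid, y = .vmKdeAt(grid, sample, kappa),
              kappa = kappa, n = length(sample))
  class(out) <- "circularDensity"
  out
}

#' @export
print.circularDensity <- function(x, ...) {
  cat(sprintf("circular KDE: n = %d, kernel kappa = %.3f, grid %d\n",
              x$n, x$kappa, length(x$x)))
  invisible(x)
}

#' Coefficient of activity overlap
#'
#' The overlap coefficient is the area under the minimum of the two
#' estimated circular densities: 0 means disjoint activity, 1 identical
#' patterns. The default `"grid"` variant integrates `min(f1, f2)` by the
#' trapezoid rule on a common grid; the `"points"` variant averages the
#' truncated density ratios evaluated at the observed times.
#'
#' @param sample1,sample2 numeric vectors of angles in radians (each at
#'   least 2 observations).
#' @param gridN grid size for the `"grid"` variant.
#' @param adjust bandwidth adjustment passed to [circularKde()].
#' @param variant `"grid"` (default) or `"points"`.
#' @return the overlap coefficient in `[0, 1]`.
#' @export
overlapDelta <- function(sample1, sample2, gridN = 512, adjust = 1,
                         variant = c("grid", "points")) {
  variant <- match.arg(variant)
  if (length(sample1) < 2 || length(sample2) < 2)
    stop("need at least 2 observations per group", call. = FALSE)
  s1 <- sample1 %% (2 * pi); s2 <- sample2 %% (2 * pi)
  k1 <- .ruleKappa(s1) / adjust
  k2 <- .ruleKappa(s2) / adjust
  if (variant == "grid") {
    grid <- seq(0, 2 * pi, length.out = gridN + 1)[seq_len(gridN)]
    f1 <- .vmKdeAt(grid, s1, k1)
    f2 <- .vmKdeAt(grid, s2, k2)
    ## equally spaced circular grid: the trapezoid rule reduces to the mean
    d <- mean(pmin(f1, f2)) * 2 * pi
  } else {
    r1 <- pmin(1, .vmKdeAt(s1, s2, k2) / .vmKdeAt(s1, s1, k1))
    r2 <- pmin(1, .vmKdeAt(s2, s1, k1) / .vmKdeAt(s2, s2, k2))
    d <- (mean(r1) + mean(r2)) / 2
  }
  min(max(d, 0), 1)
}

#' Bootstrap confidence interval for the overlap coefficient
#'
#' Nonparametric bootstrap: each group is resampled with replacement
#' `nBoot` times and the overlap recomputed; the interval is the 2.5 and
#' 97.5 percentile of the bootstrap distribution (`type = "percentile"`,
#' default) or the basic bootstrap interval clamped to `[0, 1]`.
#'
#' @inheritParams overlapDelta
#' @param nBoot number of bootstrap resamples (default 999).
#' @param seed integer seed.
#' @param type `"percentile"` or `"basic"`.
#' @return list of class `overlapResult`: `delta_hat`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`, `variant`, `type` and the bootstrap draws `boot`.
#' @export
overlapCI <- function(sample1, sample2, nBoot = 999, seed = 1,
                      gridN = 512, adjust = 1,
                      variant = c("grid", "points"),
                      type = c("percentile", "basic")) {
  variant <- match.arg(variant)
  type <- match.arg(type)
  if (nBoot < 1) stop("nBoot must be at least 1", call. = FALSE)
  est <- overlapDelta(sample1, sample2, gridN, adjust, variant)
  set.seed(seed)
  boot <- vapply(seq_len(nBoot), function(b) {
    r1 <- sample(sample1, length(sample1), replace = TRUE)
    r2 <- sample(sample2, length(sample2), replace = TRUE)
    tryCatch(overlapDelta(r1, r2, gridN, adjust, variant),
             error = function(e) NA_real_)
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  q <- quantile(boot, c(0.025, 0.975), names = FALSE)
  if (type == "basic") {
    ci <- c(2 * est - q[2], 2 * est - q[1])
    ci <- pmin(pmax(ci, 0), 1)
  } else ci <- q
  out <- list(delta_hat = est, ci_low = ci[1], ci_high = ci[2],
              n_boot = nBoot, seed = seed, variant = variant, type = type,
              boot = boot)
  class(out) <- "overlapResult"
  out
}

#' @export
print.overlapResult <- function(x, ...) {
  cat(sprintf("activity overlap: %.3f (95%% CI %.3f-%.3f, %d bootstraps)\n",
              x$delta_hat, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}
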