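## Effort-detection analyses, movement and range proxies, dyad interaction
## and tenure / minimum-age estimation.

#' Regression through the origin
#'
#' Least-squares fit of `y = slope * x` with the closed form
#' `slope = sum(xy) / sum(x^2)`, reported with the uncentered R-squared
#' `1 - RSS / sum(y^2)` conventional for no-intercept fits.
#'
#' @param x,y equal-length numeric vectors; some `x` must be non-zero.
#' @return list of class `originFit`: `slope`, `se`, `p_value`,
#'   `r_squared` (uncentered), `n`.
#' @export
regressOrigin <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (all(x == 0)) stop("all x are zero", call. = FALSE)
  fit <- lm(y ~ 0 + x)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  out <- list(slope = unname(coef(fit)[1]),
              se = unname(sm$coefficients[1, 2]),
              p_value = if (length(x) > 1) unname(sm$coefficients[1, 4])
                        else NA_real_,
              r_squared = sm$r.squared,
              n = length(x))
  class(out) <- "originFit"
  out
}

#' @export
print.originFit <- function(x, ...) {
  cat(sprintf("through-origin fit: slope = %.4g (SE %.3g), R2 = %.2f, n = %d\n",
              x$slope, x$se, x$r_squared, x$n))
  invisible(x)
}

#' Detection against an effort threshold
#'
#' Cross-tabulates stations (or location-years) by effort at or above versus
#' below a threshold and by whether the species was detected, with the
#' Pearson chi-square test (no continuity correction, df = 1).
#'
#' @param effort numeric vector of functional trap-nights, one per unit.
#' @param detected logical vector, same length.
#' @param threshold trap-night threshold (default 100).
#' @return list with the 2 x 2 `counts` table (rows: effort >= / <
#'   threshold; columns: detected / not), `chi2`, `df`, `p_value`.
#' @export
effortThresholdTest <- function(effort, detected, threshold = 100) {
  stopifnot(length(effort) == length(detected))
  high <- factor(effort >= threshold, levels = c(TRUE, FALSE),
                 labels = c(">=threshold", "<threshold"))
  det <- factor(detected, levels = c(TRUE, FALSE),
                labels = c("detected", "not detected"))
  counts <- table(high, det)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("empty margin in the 2 x 2 table", call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(counts = counts, chi2 = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value)
}

#' Welch t-test on log-transformed values
#'
#' @param a,b positive numeric vectors with at least 2 values each.
#' @return list with `t`, `df` (Satterthwaite), `p_value` and the group
#'   log-scale means.
#' @export
welchLogT <- function(a, b) {
  if (any(c(a, b) <= 0)) stop("values must be positive", call. = FALSE)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per group", call. = FALSE)
  tt <- t.test(log(a), log(b), var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_log_a = mean(log(a)), mean_log_b = mean(log(b)))
}

.stationDist <- function(stations) {
  d <- as.matrix(dist(stations[, c("x_km", "y_km")]))
  dimnames(d) <- list(stations$station_id, stations$station_id)
  d
}

#' Maximum distance moved by an individual
#'
#' The largest pairwise Euclidean distance among the distinct stations at
#' which the individual was detected. With `scope = "within-year"` only
#' stations visited in the same calendar year are paired (the reported value
#' is the largest within-year MDM over the individual's years); `"pooled"`
#' pairs stations across all years.
#'
#' @param events events of one individual (validated data frame).
#' @param stations station registry.
#' @param scope `"pooled"` (default) or `"within-year"`.
#' @return distance in km (0 if detected at a single station or fewer).
#' @export
maxDistMoved <- function(events, stations, scope = c("pooled", "within-year")) {
  scope <- match.arg(scope)
  if (!nrow(events)) return(0)
  d <- .stationDist(stations)
  mdmOf <- function(st) {
    st <- unique(st)
    if (length(st) < 2) return(0)
    max(d[st, st])
  }
  if (scope == "pooled") return(mdmOf(events$station_id))
  yr <- format(events$date, "%Y")
  max(vapply(split(events$station_id, yr), mdmOf, numeric(1)))
}

#' Circular range area from a diameter proxy
#'
#' Treats the maximum distance moved as the diameter of a circular range:
#' `pi * (mdm / 2)^2`, reported to 1 decimal.
#'
#' @param mdm_km non-negative diameter proxy in km.
#' @return area in square km, rounded to 1 decimal.
#' @export
circleArea <- function(mdm_km) {
  if (any(mdm_km < 0)) stop("mdm must be non-negative", call. = FALSE)
  round(pi * (mdm_km / 2)^2, 1)
}

#' Per-individual summary table
#'
#' One row per identified individual: sex (the non-U code recorded, `U` if
#' never sexed), number of independent captures, number of distinct
#' stations, maximum distance moved, first and last detection year, tenure
#' (last - first) and minimum age (tenure + 1, assuming at least one year
#' old at first detection).
#'
#' @param events validated event data frame (identified events only are
#'   used).
#' @param stations station registry.
#' @param scope MDM scope passed to [maxDistMoved()].
#' @return data frame, one row per individual.
#' @export
individualSummary <- function(events, stations,
                              scope = c("pooled", "within-year")) {
  scope <- match.arg(scope)
  events <- events[!is.na(events$individual_id), , drop = FALSE]
  ids <- sort(unique(events$individual_id))
  rows <- lapply(ids, function(id) {
    ev <- events[events$individual_id == id, , drop = FALSE]
    yrs <- as.integer(format(ev$date, "%Y"))
    sx <- setdiff(unique(ev$sex), "U")
    ten <- max(yrs) - min(yrs)
    data.frame(individual_id = id,
               sex = if (length(sx)) sx[1] else "U",
               n_captures = nrow(ev),
               n_stations = length(unique(ev$station_id)),
               mdm_km = maxDistMoved(ev, stations, scope),
               first_year = min(yrs), last_year = max(yrs),
               tenure_years = ten, min_age_years = ten + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(individual_id = character(), sex = character(),
                      n_captures = integer(), n_stations = integer(),
                      mdm_km = numeric(), first_year = integer(),
                      last_year = integer(), tenure_years = integer(),
                      min_age_years = integer())
  rownames(out) <- NULL
  out
}

#' Tenure and minimum age of one individual
#'
#' @param events events of one individual (at least 1).
#' @return list with `tenure_years` (last minus first detection year) and
#'   `min_age_years` (tenure + 1).
#' @export
tenureYears <- function(events) {
  stopifnot(nrow(events) >= 1)
  yrs <- as.integer(format(events$date, "%Y"))
  ten <- max(yrs) - min(yrs)
  list(tenure_years = ten, min_age_years = ten + 1L)
}

#' Capture and spatial-recapture profiles
#'
#' Proportions of individuals with 1, 2, ..., k captures and with
#' detections at 1, 2, ..., k distinct stations.
#'
#' @param events validated event data frame (identified events only are
#'   used).
#' @return list with data frames `captures` (`k`, `prop`) and `stations`
#'   (`k`, `prop`); each `prop` column sums to 1 (empty input gives empty
#'   tables).
#' @export
recaptureProfile <- function(events) {
  events <- events[!is.na(events$individual_id), , drop = FALSE]
  prof <- function(counts) {
    if (!length(counts))
      return(data.frame(k = integer(), prop = numeric()))
    tab <- table(factor(counts, levels = seq_len(max(counts))))
    data.frame(k = as.integer(names(tab)),
               prop = as.numeric(tab) / length(counts))
  }
  caps <- table(events$individual_id)
  stns <- vapply(split(events$station_id, events$individual_id),
                 function(s) length(unique(s)), integer(1))
  list(captures = prof(as.integer(caps)), stations = prof(unname(stns)))
}

.sexClass <- function(s1, s2) {
  if (s1 == "U" || s2 == "U") return("unknown")
  paste(sort(c(s1, s2)), collapse = "")  # FF, FM, MM
}

.individualSex <- function(events) {
  vapply(split(events$sex, events$individual_id),
         function(s) { sx <- setdiff(unique(s), "U")
                       if (length(sx)) sx[1] else "U" }, character(1))
}

#' Static interaction within location-years
#'
#' For each location-year, the number of distinct identified individuals
#' and the sexed dyad composition: all unordered pairs among its
#' individuals, classified FF, MM, FM, or unknown when either member is
#' unsexed.
#'
#' @param locationYears output of [buildLocationYears()].
#' @return data frame with one row per location-year: `station_id`, `year`,
#'   `n_individuals`, `n_dyads`, `FF`, `MM`, `FM`, `unknown`.
#' @export
staticDyads <- function(locationYears) {
  rows <- lapply(seq_len(nrow(locationYears)), function(i) {
    ev <- locationYears$events[[i]]
    ev <- ev[!is.na(ev$individual_id), , drop = FALSE]
    ids <- unique(ev$individual_id)
    n <- length(ids)
    cls <- c(FF = 0L, MM = 0L, FM = 0L, unknown = 0L)
    if (n >= 2) {
      sex <- .individualSex(ev)
      pairs <- utils::combn(ids, 2)
      for (k in seq_len(ncol(pairs))) {
        cl <- .sexClass(sex[[pairs[1, k]]], sex[[pairs[2, k]]])
        cls[cl] <- cls[cl] + 1L
      }
    }
    data.frame(station_id = locationYears$station_id[i],
               year = locationYears$year[i],
               n_individuals = n, n_dyads = sum(cls),
               FF = cls[["FF"]], MM = cls[["MM"]], FM = cls[["FM"]],
               unknown = cls[["unknown"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.intervalBin <- function(days) {
  cut(days, breaks = c(-Inf, 0, 7, 14, 28, Inf),
      labels = c("same day", "<=7 d", "8-14 d", "15-28 d", ">28 d"))
}

#' Dynamic interaction: dyad detection intervals
#'
#' For every unordered pair of identified individuals detected in the same
#' location-year, the interval is the minimum absolute time difference
#' between a detection of one member and a detection of the other:
#' `interval_days` in whole calendar days (0 = same day), and
#' `interval_exact_days` as the fractional timestamp difference. Pairs
#' further apart than `independenceDays` (on `interval_days`, strict) are
#' flagged independent (no interaction); intervals are binned into the
#' classes same day, within 7 days, 8-14, 15-28 and over 28 days.
#'
#' @param locationYears output of [buildLocationYears()].
#' @param independenceDays strict independence threshold in days
#'   (default 28).
#' @return data frame with one row per dyad: `station_id`, `year`, `id1`,
#'   `id2`, `sex_class`, `interval_days`, `independent`, `bin`.
#' @export
dynamicIntervals <- function(locationYears, independenceDays = 28) {
  rows <- list()
  for (i in seq_len(nrow(locationYears))) {
    ev <- locationYears$events[[i]]
    ev <- ev[!is.na(ev$individual_id), , drop = FALSE]
    ids <- sort(unique(ev$individual_id))
    if (length(ids) < 2) next
    sex <- .individualSex(ev)
    times <- split(as.numeric(ev$timestamp) / 86400, ev$individual_id)
    dates <- split(as.numeric(ev$date), ev$individual_id)
    pairs <- utils::combn(ids, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      gap <- min(abs(outer(dates[[a]], dates[[b]], "-")))
      exact <- min(abs(outer(times[[a]], times[[b]], "-")))
      rows[[length(rows) + 1L]] <- data.frame(
        station_id = locationYears$station_id[i],
        year = locationYears$year[i],
        id1 = a, id2 = b,
        sex_class = .sexClass(sex[[a]], sex[[b]]),
        interval_days = gap,
        interval_exact_days = exact,
        independent = gap > independenceDays,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(station_id = character(), year = integer(),
               id1 = character(), id2 = character(),
               sex_class = character(), interval_days = numeric(),
               interval_exact_days = numeric(), independent = logical())
  out$bin <- .intervalBin(out$interval_days)
  rownames(out) <- NULL
  out
}
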