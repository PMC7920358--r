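## Individual-based camera-trap survey simulator.
##
## Detection model: an individual occupies a fixed circular range (diameter
## drawn from a sex-specific log-normal); on every functional station-night
## at a station lying within its range it is photographed with a sex-specific
## nightly encounter probability, at most once per individual-station-night.
## Clock times come from a sex-specific two-component von Mises mixture.
## Lifespans are geometric (stationary population under uniform entry).

#' Simulator configuration
#'
#' Builds and validates a configuration for the individual-based survey
#' simulator. All probabilities must lie in `[0, 1]`; mixture weights must
#' sum to 1; range diameters are parameterised on the log scale.
#'
#' `n_alive` is the target number of concurrently alive individuals on the
#' extent in any one year; the generator converts it into a cohort size using
#' the mean geometric lifespan `1 / (1 - annual_survival)` and the length of
#' the entry window.
#'
#' `nightly_encounter_prob` is the per-night probability that an individual
#' whose range covers a functional station is photographed there; it may be
#' a single number or a named pair `c(M = , F = )`.
#'
#' @param extent_km numeric length 2, rectangle width and height in km.
#' @param n_alive target number of concurrently alive individuals.
#' @param p_male probability a simulated individual is male.
#' @param range_diameter_km list with elements `M` and `F`, each
#'   `c(meanlog, sdlog)` of the log-normal range-diameter distribution (km).
#' @param nightly_encounter_prob scalar or named pair, see Details.
#' @param activity_mix list with elements `M` and `F`, each a list with
#'   `mu` (component means, radians), `kappa` (concentrations) and `w`
#'   (weights summing to 1).
#' @param annual_survival annual survival probability; lifespans are
#'   `1 + Geometric(1 - annual_survival)` years.
#' @param flank_probs named probabilities `c(L = , R = , B = )` for the flank
#'   recorded on an event; must sum to 1.
#' @param p_unidentified probability an event cannot be attributed to an
#'   individual (id blank, sex and flank recorded as `U`).
#' @param years calendar years with a survey season.
#' @param season_start_month,season_start_day season start within each year.
#' @param season_days season length in days (functional every night).
#' @param entry_lead_years how many years before the first season
#'   individuals may enter the population.
#' @param stations optional station registry data frame (`station_id`,
#'   `x_km`, `y_km`); defaults to a regular 4 x 5 grid at 2 km spacing.
#' @return validated list of class `simConfig`.
#' @export
simConfig <- function(extent_km = c(10, 10),
                      n_alive = 150,
                      p_male = 2 / 3,
                      range_diameter_km = list(
                        M = c(meanlog = 0.35125, sdlog = 0.68781),
                        F = c(meanlog = -0.84689, sdlog = 0.55451)),
                      nightly_encounter_prob = c(M = 0.0017, F = 0.021),
                      activity_mix = list(
                        M = list(mu = c(2, 20) * pi / 12,
                                 kappa = c(2, 1.5), w = c(0.6, 0.4)),
                        F = list(mu = c(3, 23) * pi / 12,
                                 kappa = c(2, 2), w = c(0.7, 0.3))),
                      annual_survival = 0.8,
                      flank_probs = c(L = 0.42, R = 0.42, B = 0.16),
                      p_unidentified = 0.07,
                      years = 2003:2014,
                      season_start_month = 2, season_start_day = 1,
                      season_days = 90,
                      entry_lead_years = 10,
                      stations = NULL) {
  lam <- nightly_encounter_prob
  if (length(lam) == 1) lam <- c(M = unname(lam), F = unname(lam))
  if (!all(c("M", "F") %in% names(lam)))
    stop("nightly_encounter_prob must be scalar or named c(M=, F=)",
         call. = FALSE)
  probs <- c(p_male, lam, annual_survival, flank_probs, p_unidentified)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(flank_probs) - 1) > 1e-8)
    stop("flank_probs must sum to 1", call. = FALSE)
  for (s in c("M", "F")) {
    mix <- activity_mix[[s]]
    if (abs(sum(mix$w) - 1) > 1e-8)
      stop("activity mixture weights must sum to 1", call. = FALSE)
    if (any(mix$kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
    if (exp(range_diameter_km[[s]]["meanlog"]) <= 0)
      stop("range diameters must be positive", call. = FALSE)
  }
  if (n_alive < 0 || any(extent_km <= 0) || season_days < 1)
    stop("invalid extent, n_alive or season_days", call. = FALSE)
  if (is.null(stations)) {
    xy <- expand.grid(x_km = seq(2, 8, by = 2), y_km = seq(1, 9, by = 2))
    stations <- data.frame(
      station_id = sprintf("S%02d", seq_len(nrow(xy))),
      x_km = xy$x_km, y_km = xy$y_km,
      site_class = "trail", stringsAsFactors = FALSE)
  }
  cfg <- list(extent_km = extent_km, n_alive = n_alive, p_male = p_male,
              range_diameter_km = range_diameter_km,
              nightly_encounter_prob = lam,
              activity_mix = activity_mix,
              annual_survival = annual_survival,
              flank_probs = flank_probs,
              p_unidentified = p_unidentified,
              years = sort(years),
              season_start_month = season_start_month,
              season_start_day = season_start_day,
              season_days = season_days,
              entry_lead_years = entry_lead_years,
              stations = stations)
  class(cfg) <- "simConfig"
  cfg
}

#' Default survey-like configuration
#'
#' The default configuration emulates a long-term felid monitoring grid:
#' 20 stations about 2 km apart surveyed in 12 annual 90-day seasons, a
#' sparse pooled detection rate (about 0.4--1.2 events per 100 trap-nights),
#' a roughly 2:1 male:female detection and individual ratio, nocturnal
#' bimodal activity, small circular ranges (male mean diameter 1.8 km, SD
#' 1.4; female 0.5 km, SD 0.3) and multi-year tenures.
#'
#' @param ... overrides passed on to [simConfig()].
#' @return a `simConfig` object.
#' @export
defaultSimConfig <- function(...) simConfig(...)

#' Seasonal effort schedule for a configuration
#'
#' One interval per station and survey year, starting at the configured
#' season start and running `season_days` nights.
#'
#' @param config a `simConfig`.
#' @return effort data frame (`station_id`, `start_date`, `end_date`).
#' @export
simulateEffort <- function(config) {
  starts <- as.Date(sprintf("%d-%02d-%02d", config$years,
                            config$season_start_month,
                            config$season_start_day))
  out <- expand.grid(station_id = config$stations$station_id,
                     start_date = starts, stringsAsFactors = FALSE)
  out$end_date <- out$start_date + config$season_days
  out[order(out$station_id, out$start_date), , drop = FALSE]
}

#' Simulate a true population
#'
#' Range centres are uniform on the extent; sex is Bernoulli(`p_male`);
#' range diameters are log-normal by sex; individuals enter in a year drawn
#' uniformly from the entry window (`entry_lead_years` before the first
#' season through the last season year) and live `1 + Geometric(1 -
#' annual_survival)` years. The cohort size is chosen so that the expected
#' number alive in a survey year is `n_alive`.
#'
#' @param config a `simConfig`.
#' @param seed integer seed; the result is fully reproducible from it.
#' @return data frame of class `truePopulation` with columns `id`, `sex`,
#'   `x_km`, `y_km`, `diameter_km`, `first_year`, `last_year`.
#' @export
simulatePopulation <- function(config, seed = 1) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(seed)
  y0 <- min(config$years) - config$entry_lead_years
  y1 <- max(config$years)
  window <- y1 - y0 + 1
  meanLife <- 1 / (1 - config$annual_survival)
  n <- round(config$n_alive * window / meanLife)
  if (n == 0)
    return(structure(data.frame(id = character(), sex = character(),
                                x_km = numeric(), y_km = numeric(),
                                diameter_km = numeric(),
                                first_year = integer(), last_year = integer()),
                     class = c("truePopulation", "data.frame")))
  sex <- ifelse(runif(n) < config$p_male, "M", "F")
  d <- numeric(n)
  for (s in c("M", "F")) {
    i <- sex == s
    pars <- config$range_diameter_km[[s]]
    d[i] <- rlnorm(sum(i), pars[["meanlog"]], pars[["sdlog"]])
  }
  entry <- sample(y0:y1, n, replace = TRUE)
  life <- 1L + rgeom(n, 1 - config$annual_survival)
  pop <- data.frame(id = sprintf("IND%04d", seq_len(n)), sex = sex,
                    x_km = runif(n, 0, config$extent_km[1]),
                    y_km = runif(n, 0, config$extent_km[2]),
                    diameter_km = d,
                    first_year = entry, last_year = entry + life - 1L,
                    stringsAsFactors = FALSE)
  class(pop) <- c("truePopulation", "data.frame")
  pop
}

## Best-Fisher rejection sampler for the von Mises distribution
.rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric())
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

## draw clock angles from a sex's activity mixture
.rActivity <- function(n, mix) {
  if (n == 0) return(numeric())
  comp <- sample.int(length(mix$w), n, replace = TRUE, prob = mix$w)
  out <- numeric(n)
  for (k in seq_along(mix$w)) {
    i <- comp == k
    out[i] <- .rvonmises(sum(i), mix$mu[k], mix$kappa[k])
  }
  out
}

#' Simulate detection events
#'
#' For every functional station-night and every alive individual whose range
#' centre lies within half its diameter of the station, an event occurs with
#' the sex's nightly encounter probability (at most one event per
#' individual-station-night). Event clock times are drawn from the sex's
#' activity mixture; flank from `flank_probs`; with probability
#' `p_unidentified` the record loses its id and its sex/flank become `U`.
#'
#' @param population a `truePopulation`.
#' @param stations station registry data frame.
#' @param effort effort table.
#' @param config the `simConfig` used.
#' @param seed integer seed.
#' @return validated event data frame (see [validateEvents()]) with an extra
#'   `true_id` column carrying the simulated individual for every event,
#'   including unidentified ones.
#' @export
simulateDetections <- function(population, stations, effort, config, seed = 1) {
  set.seed(seed)
  nights <- .effortNights(effort)
  nights <- nights[order(nights$station_id, nights$night), , drop = FALSE]
  nights$year <- as.integer(format(nights$night, "%Y"))
  rows <- list()
  for (si in seq_len(nrow(stations))) {
    st <- stations[si, ]
    sn <- nights[nights$station_id == st$station_id, , drop = FALSE]
    if (!nrow(sn)) next
    dx <- population$x_km - st$x_km
    dy <- population$y_km - st$y_km
    cover <- which(sqrt(dx^2 + dy^2) <= population$diameter_km / 2)
    for (ii in cover) {
      ind <- population[ii, ]
      alive <- sn$year >= ind$first_year & sn$year <= ind$last_year
      nd <- sn$night[alive]
      if (!length(nd)) next
      lam <- config$nightly_encounter_prob[[ind$sex]]
      hit <- runif(length(nd)) < lam
      nd <- nd[hit]
      if (!length(nd)) next
      theta <- .rActivity(length(nd), config$activity_mix[[ind$sex]])
      secs <- round(theta / (2 * pi) * 86400)
      flank <- sample(names(config$flank_probs), length(nd), replace = TRUE,
                      prob = config$flank_probs)
      rows[[length(rows) + 1L]] <- data.frame(
        station_id = st$station_id,
        timestamp = as.POSIXct(nd, tz = "UTC") + secs,
        individual_id = ind$id, sex = ind$sex, flank = flank,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    ev <- data.frame(station_id = character(), datetime = character(),
                     individual_id = character(), sex = character(),
                     flank = character(), stringsAsFactors = FALSE)
    ev <- validateEvents(ev)
    ev$true_id <- character()
    return(ev)
  }
  ev <- do.call(rbind, rows)
  ev$true_id <- ev$individual_id
  unid <- runif(nrow(ev)) < config$p_unidentified
  ev$individual_id[unid] <- NA_character_
  ev$sex[unid] <- "U"
  ev$flank[unid] <- "U"
  ev$datetime <- format(ev$timestamp, "%Y-%m-%d %H:%M:%S")
  ev$date <- as.Date(ev$timestamp, tz = "UTC")
  ev <- ev[order(ev$timestamp, ev$station_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev[, c("station_id", "datetime", "individual_id", "sex", "flank",
         "timestamp", "date", "true_id")]
}

#' Run a full simulated survey
#'
#' Draws a population, builds the seasonal effort schedule and simulates
#' detections; optionally writes the three input CSVs plus the population
#' truth table and a YAML echo of the configuration (with the seed) to a
#' directory.
#'
#' @param config a `simConfig`.
#' @param seed integer root seed (population and detections use derived
#'   substream seeds).
#' @param dir optional output directory; created if needed.
#' @return list of class `camtrapData` (elements `events`, `stations`,
#'   `effort`) with extra elements `truth` (the population) and `seed`.
#' @export
simulateSurvey <- function(config, seed = 1, dir = NULL) {
  stopifnot(inherits(config, "simConfig"))
  pop <- simulatePopulation(config, seed = seed)
  effort <- simulateEffort(config)
  events <- simulateDetections(pop, config$stations, effort, config,
                               seed = seed + 1L)
  out <- structure(list(events = events, stations = config$stations,
                        effort = effort, truth = pop, seed = seed),
                   class = "camtrapData")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ev <- events[, c("station_id", "datetime", "individual_id", "sex", "flank")]
    ev$individual_id[is.na(ev$individual_id)] <- ""
    write.csv(ev, file.path(dir, "detections.csv"), row.names = FALSE)
    write.csv(config$stations, file.path(dir, "stations.csv"), row.names = FALSE)
    write.csv(effort, file.path(dir, "effort.csv"), row.names = FALSE)
    write.csv(as.data.frame(pop), file.path(dir, "truth.csv"), row.names = FALSE)
    echo <- config
    echo$stations <- NULL
    echo$seed <- seed
    yaml::write_yaml(lapply(echo, function(x)
      if (is.numeric(x) || is.list(x)) x else as.character(x)),
      file.path(dir, "config.yaml"))
  }
  out
}

#' @export
print.camtrapData <- function(x, ...) {
  cat(sprintf("camtrapData: %d events, %d stations, %d effort intervals\n",
              nrow(x$events), nrow(x$stations), nrow(x$effort)))
  if (!is.null(x$truth))
    cat(sprintf("  simulated (seed %s): %d true individuals\n",
                format(x$seed), nrow(x$truth)))
  invisible(x)
}
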