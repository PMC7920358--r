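# Fixture builders and independent oracles used across the suite.

# build a validated event table from parallel vectors
makeEvents <- function(station, datetime, id = NA, sex = "U", flank = "B") {
  n <- length(datetime)
  df <- data.frame(station_id = rep_len(station, n),
                   datetime = datetime,
                   individual_id = rep_len(id, n),
                   sex = rep_len(sex, n),
                   flank = rep_len(flank, n),
                   stringsAsFactors = FALSE)
  validateEvents(df)
}

makeStations <- function(ids, x, y) {
  data.frame(station_id = ids, x_km = x, y_km = y,
             site_class = NA_character_, stringsAsFactors = FALSE)
}

makeEffort <- function(station, start, end) {
  data.frame(station_id = station, start_date = as.Date(start),
             end_date = as.Date(end), stringsAsFactors = FALSE)
}

# brute-force independence filter: keep an event unless an earlier event of
# the same (individual, station, date) exists; unidentified events compare
# at (station, date) level
bruteDedup <- function(events) {
  events <- events[order(events$timestamp), , drop = FALSE]
  keep <- rep(TRUE, nrow(events))
  for (i in seq_len(nrow(events))) {
    for (j in seq_len(i - 1)) {
      same_station <- events$station_id[i] == events$station_id[j]
      same_date <- events$date[i] == events$date[j]
      both_unid <- is.na(events$individual_id[i]) &&
        is.na(events$individual_id[j])
      same_id <- !is.na(events$individual_id[i]) &&
        !is.na(events$individual_id[j]) &&
        events$individual_id[i] == events$individual_id[j]
      if (same_station && same_date && (both_unid || same_id))
        keep[i] <- FALSE
    }
  }
  events[keep, , drop = FALSE]
}

# night-by-night enumeration of functional trap-nights
bruteTrapNights <- function(effort) {
  keys <- character()
  for (i in seq_len(nrow(effort))) {
    s <- effort$start_date[i]; e <- effort$end_date[i]
    if (e > s) {
      nights <- seq(s, e - 1, by = "day")
      keys <- c(keys, paste(effort$station_id[i], nights))
    }
  }
  length(unique(keys))
}

# exhaustive dynamic-occupancy likelihood: sum over all latent occupancy
# sequences z in {0,1}^T per site
bruteLoglik <- function(params, y) {
  M <- dim(y)[1]; T <- dim(y)[2]; J <- dim(y)[3]
  p <- if (is.matrix(params$p)) params$p else matrix(params$p, T, J)
  gam <- rep(params$gamma, length.out = max(T - 1, 1))
  eps <- rep(params$epsilon, length.out = max(T - 1, 1))
  zseq <- as.matrix(expand.grid(rep(list(0:1), T)))
  total <- 0
  for (m in seq_len(M)) {
    lik <- 0
    for (r in seq_len(nrow(zseq))) {
      z <- zseq[r, ]
      pr <- if (z[1] == 1) params$psi1 else 1 - params$psi1
      for (t in seq_len(T - 1)) {
        pr <- pr * if (z[t] == 1) {
          if (z[t + 1] == 1) 1 - eps[t] else eps[t]
        } else {
          if (z[t + 1] == 1) gam[t] else 1 - gam[t]
        }
      }
      for (t in seq_len(T)) {
        for (j in seq_len(J)) {
          yv <- y[m, t, j]
          if (is.na(yv)) next
          pr <- pr * if (z[t] == 1) p[t, j]^yv * (1 - p[t, j])^(1 - yv)
                     else as.numeric(yv == 0)
        }
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

vmDensity <- function(theta, mu, kappa) {
  exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0))
}

# quadrature of min(f, g) for two known von Mises laws
trueOverlap <- function(mu1, k1, mu2, k2, n = 1e5) {
  g <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  mean(pmin(vmDensity(g, mu1, k1), vmDensity(g, mu2, k2))) * 2 * pi
}

rvm <- function(n, mu, kappa) margaytrap:::.rvonmises(n, mu, kappa)

extfile <- function(name) system.file("extdata", name, package = "margaytrap")
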