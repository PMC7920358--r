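#' @import methods
#' @importFrom stats median optim quantile rbinom rgeom rlnorm runif sd
#'   chisq.test t.test lm coef pchisq aggregate setNames optimHess dist
#' @importFrom utils read.csv write.csv
NULL

SEX_CODES   <- c("M", "F", "U")
FLANK_CODES <- c("L", "R", "B", "U")

## ---- parsing and validation -------------------------------------------------

.parseTimestamp <- function(x) {
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

.checkColumns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read and validate camera-trap detection, station and effort tables
#'
#' Reads the three CSV tables that describe a camera-trap survey and returns
#' a validated `camtrapData` object. The expected schemas are:
#' `detections.csv` (`station_id`, `datetime`, `individual_id` possibly blank,
#' `sex` in M/F/U, `flank` in L/R/B/U), `stations.csv` (`station_id`, `x_km`,
#' `y_km`, optional `site_class`) and `effort.csv` (`station_id`,
#' `start_date`, `end_date`).
#'
#' Station coordinates are planar kilometres in any projected system;
#' distances downstream are Euclidean. Timestamps are local clock time,
#' stored without timezone conversion. Events whose timestamp falls outside
#' every functional effort interval of their station raise a warning, not an
#' error.
#'
#' @param detections_path,stations_path,effort_path paths to the three CSVs.
#' @return A list of class `camtrapData` with elements `events`, `stations`
#'   and `effort` (validated data frames; `events$timestamp` is POSIXct,
#'   `events$date` the calendar date, blank individual ids become `NA`).
#' @export
readCamtrapData <- function(detections_path, stations_path, effort_path) {
  for (p in c(detections_path, stations_path, effort_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  stations <- read.csv(stations_path, stringsAsFactors = FALSE)
  .checkColumns(stations, c("station_id", "x_km", "y_km"), "stations")
  stations$station_id <- as.character(stations$station_id)
  if (anyDuplicated(stations$station_id))
    stop("stations: duplicated station_id", call. = FALSE)
  if (!all(is.finite(stations$x_km)) || !all(is.finite(stations$y_km)))
    stop("stations: non-finite coordinates", call. = FALSE)
  if (is.null(stations$site_class)) stations$site_class <- NA_character_

  effort <- read.csv(effort_path, stringsAsFactors = FALSE)
  .checkColumns(effort, c("station_id", "start_date", "end_date"), "effort")
  effort$station_id <- as.character(effort$station_id)
  effort$start_date <- as.Date(effort$start_date)
  effort$end_date   <- as.Date(effort$end_date)
  if (anyNA(effort$start_date) || anyNA(effort$end_date))
    stop("effort: unparseable date", call. = FALSE)
  if (any(effort$end_date < effort$start_date))
    stop("effort: end_date before start_date", call. = FALSE)
  bad <- setdiff(effort$station_id, stations$station_id)
  if (length(bad))
    stop("effort: unknown station_id: ", paste(bad, collapse = ", "),
         call. = FALSE)

  events <- read.csv(detections_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  .checkColumns(events, c("station_id", "datetime", "individual_id",
                          "sex", "flank"), "detections")
  events <- validateEvents(events, stations, effort)
  structure(list(events = events, stations = stations, effort = effort),
            class = "camtrapData")
}

#' Validate a raw detection-event table
#'
#' Parses timestamps, normalises blank individual ids to `NA`, enforces the
#' sex and flank enumerations, checks station references and warns about
#' events outside all functional effort intervals of their station.
#'
#' @param events data frame with columns `station_id`, `datetime`,
#'   `individual_id`, `sex`, `flank`.
#' @param stations station registry (for reference checks), or `NULL`.
#' @param effort effort table (for the outside-effort warning), or `NULL`.
#' @return the validated events data frame, with `timestamp` (POSIXct) and
#'   `date` (Date) columns added and rows ordered by time.
#' @export
validateEvents <- function(events, stations = NULL, effort = NULL) {
  events$station_id <- as.character(events$station_id)
  if (nrow(events)) {
    ts <- .parseTimestamp(events$datetime)
    if (anyNA(ts))
      stop("detections: unparseable datetime in row(s) ",
           paste(which(is.na(ts)), collapse = ", "), call. = FALSE)
    events$timestamp <- ts
  } else {
    events$timestamp <- as.POSIXct(character(), tz = "UTC")
  }
  events$date <- as.Date(events$timestamp, tz = "UTC")
  id <- as.character(events$individual_id)
  id[!is.na(id) & !nzchar(trimws(id))] <- NA_character_
  events$individual_id <- id
  badsex <- which(!(events$sex %in% SEX_CODES))
  if (length(badsex))
    stop("detections: sex outside {M,F,U} in row(s) ",
         paste(badsex, collapse = ", "), call. = FALSE)
  badfl <- which(!(events$flank %in% FLANK_CODES))
  if (length(badfl))
    stop("detections: flank outside {L,R,B,U} in row(s) ",
         paste(badfl, collapse = ", "), call. = FALSE)
  if (!is.null(stations)) {
    bad <- setdiff(events$station_id, stations$station_id)
    if (length(bad))
      stop("detections: unknown station_id: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(effort) && nrow(events)) {
    nights <- .effortNights(effort)
    key <- paste(events$station_id, events$date)
    ok <- key %in% paste(nights$station_id, nights$night)
    if (any(!ok))
      warning(sum(!ok), " event(s) fall outside all functional effort ",
              "intervals of their station", call. = FALSE)
  }
  events[order(events$timestamp), , drop = FALSE]
}

## ---- independence filter ----------------------------------------------------

#' Retain temporally independent detection events
#'
#' Repeat detections of the same individual at the same station on the same
#' calendar day are collapsed to the earliest event. Events without an
#' individual id cannot be attributed, so they are deduplicated at the
#' station x calendar-date level by default (the strictest reading), or per
#' station x date x clock-hour with `unidentifiedBy = "hour"`.
#'
#' The filter is idempotent.
#'
#' @param events validated event data frame (see [validateEvents()]).
#' @param unidentifiedBy grouping for events lacking an individual id:
#'   `"date"` (default) or `"hour"`.
#' @return the filtered event data frame, time-ordered.
#' @export
filterIndependent <- function(events, unidentifiedBy = c("date", "hour")) {
  unidentifiedBy <- match.arg(unidentifiedBy)
  if (!nrow(events)) return(events)
  events <- events[order(events$timestamp), , drop = FALSE]
  unid <- is.na(events$individual_id)
  key <- character(nrow(events))
  key[!unid] <- paste("id", events$individual_id[!unid],
                      events$station_id[!unid], events$date[!unid])
  ukey <- paste("u", events$station_id[unid], events$date[unid])
  if (unidentifiedBy == "hour")
    ukey <- paste(ukey, format(events$timestamp[unid], "%H"))
  key[unid] <- ukey
  events[!duplicated(key), , drop = FALSE]
}

## ---- trap-night accounting --------------------------------------------------

## distinct (station, night) pairs covered by the effort intervals;
## an interval [s, e] covers nights s, ..., e - 1 (night labelled by its
## starting date, midnight local time as the boundary)
.effortNights <- function(effort) {
  if (!nrow(effort))
    return(data.frame(station_id = character(), night = as.Date(character())))
  n <- as.integer(effort$end_date - effort$start_date)
  idx <- rep.int(seq_len(nrow(effort)), n)
  nights <- effort$start_date[idx] + sequence(n) - 1L
  out <- unique(data.frame(station_id = effort$station_id[idx],
                           night = nights, stringsAsFactors = FALSE))
  out
}

#' Count functional trap-nights
#'
#' A station-night counts once if at least one camera at the station
#' functioned that night, i.e. overlapping intervals and twin cameras are
#' unioned. An interval from `start_date` to `end_date` contributes
#' `end_date - start_date` nights (the night is labelled by the date on which
#' it starts).
#'
#' @param effort effort table (`station_id`, `start_date`, `end_date`).
#' @param stations optional character vector of station ids to restrict to.
#' @param from,to optional date window (inclusive, on night labels).
#' @return integer number of distinct functional station-nights.
#' @export
trapNights <- function(effort, stations = NULL, from = NULL, to = NULL) {
  if (!is.null(from) && !is.null(to) && as.Date(to) < as.Date(from))
    stop("date window ends before it starts", call. = FALSE)
  nights <- .effortNights(effort)
  if (!is.null(stations))
    nights <- nights[nights$station_id %in% stations, , drop = FALSE]
  if (!is.null(from)) nights <- nights[nights$night >= as.Date(from), , drop = FALSE]
  if (!is.null(to))   nights <- nights[nights$night <= as.Date(to), , drop = FALSE]
  nrow(nights)
}

## ---- individual accounting --------------------------------------------------

#' Minimum and maximum number of distinct individuals from flank records
#'
#' Individuals photographed on both flanks (any both-flank event, or separate
#' left- and right-flank events linked to the same id) are known exactly.
#' Individuals known from a single flank only cannot be matched across
#' flanks, so the flank side with the most single-flank individuals gives the
#' conservative minimum and the sum of both sides the maximum:
#' `n_min = B + max(L, R)`, `n_max = B + L + R`.
#'
#' Events with flank code `U` are excluded from the count with a warning;
#' events without an individual id never contribute.
#'
#' @param events validated event data frame.
#' @return list of class `individualCount` with `n_min`, `n_max`, and the
#'   component tallies `n_both`, `n_left_only`, `n_right_only`.
#' @export
countIndividuals <- function(events) {
  if (nrow(events)) {
    u <- events$flank == "U" & !is.na(events$individual_id)
    if (any(u))
      warning(sum(u), " identified event(s) with unknown flank excluded ",
              "from individual counting", call. = FALSE)
    events <- events[events$flank != "U", , drop = FALSE]
  }
  events <- events[!is.na(events$individual_id), , drop = FALSE]
  if (!nrow(events)) {
    out <- list(n_min = 0L, n_max = 0L, n_both = 0L,
                n_left_only = 0L, n_right_only = 0L)
    class(out) <- "individualCount"
    return(out)
  }
  fl <- split(events$flank, events$individual_id)
  cls <- vapply(fl, function(f) {
    if ("B" %in% f || all(c("L", "R") %in% f)) "B"
    else if ("L" %in% f) "L" else "R"
  }, character(1))
  B <- sum(cls == "B"); L <- sum(cls == "L"); R <- sum(cls == "R")
  out <- list(n_min = B + max(L, R), n_max = B + L + R,
              n_both = B, n_left_only = L, n_right_only = R)
  class(out) <- "individualCount"
  out
}

#' @export
print.individualCount <- function(x, ...) {
  cat(sprintf(
    "individual count: %d-%d (both-flank %d, left-only %d, right-only %d)\n",
    x$n_min, x$n_max, x$n_both, x$n_left_only, x$n_right_only))
  invisible(x)
}

#' Detection rate per 100 trap-nights
#'
#' @param nEvents number of (independent) detection events.
#' @param trapNights functional trap-nights over the same scope; must be
#'   positive.
#' @return `100 * nEvents / trapNights`, rounded to 2 decimals.
#' @export
detectionRate <- function(nEvents, trapNights) {
  if (any(trapNights <= 0)) stop("trapNights must be positive", call. = FALSE)
  round(100 * nEvents / trapNights, 2)
}

## ---- location-years ---------------------------------------------------------

#' Pool camera-trap data into location-years
#'
#' A location-year is all data from one camera station within one calendar
#' year; it is the unit of the interaction and effort analyses. One record is
#' produced for every (station, calendar year) with any functional effort;
#' events are assigned by station and event year.
#'
#' @param events validated event data frame.
#' @param effort effort table.
#' @return data frame with `station_id`, `year`, `trap_nights`, `n_events`
#'   and a list-column `events` holding each cell's event rows.
#' @export
buildLocationYears <- function(events, effort) {
  nights <- .effortNights(effort)
  if (!nrow(nights))
    return(data.frame(station_id = character(), year = integer(),
                      trap_nights = integer(), n_events = integer()))
  nights$year <- as.integer(format(nights$night, "%Y"))
  tn <- aggregate(list(trap_nights = nights$night),
                  by = list(station_id = nights$station_id, year = nights$year),
                  FUN = length)
  tn <- tn[order(tn$station_id, tn$year), , drop = FALSE]
  evyear <- as.integer(format(events$date, "%Y"))
  evkey <- paste(events$station_id, evyear)
  lykey <- paste(tn$station_id, tn$year)
  evlist <- lapply(lykey, function(k) events[evkey == k, , drop = FALSE])
  tn$n_events <- vapply(evlist, nrow, integer(1))
  tn$events <- evlist
  rownames(tn) <- NULL
  tn
}
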