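test_that("reading tables validates schemas, parses timestamps and rejects bad codes", {
  dir <- withr::local_tempdir()
  stations <- "station_id,x_km,y_km,site_class\nA,0,0,trail\nB,3,4,road\n"
  effort <- "station_id,start_date,end_date\nA,2020-01-01,2020-03-01\nB,2020-01-01,2020-03-01\n"
  writeLines(stations, file.path(dir, "stations.csv"))
  writeLines(effort, file.path(dir, "effort.csv"))

  # header-only detections -> empty event list
  writeLines("station_id,datetime,individual_id,sex,flank",
             file.path(dir, "det.csv"))
  dat <- readCamtrapData(file.path(dir, "det.csv"),
                         file.path(dir, "stations.csv"),
                         file.path(dir, "effort.csv"))
  expect_s3_class(dat, "camtrapData")
  expect_equal(nrow(dat$events), 0)

  # well-formed rows parse
  writeLines(paste0("station_id,datetime,individual_id,sex,flank\n",
                    "A,2020-01-05 21:30:00,ind1,M,L\n",
                    "A,2020-01-06T02:00:00,ind2,F,B\n",
                    "B,2020-02-01 04:15:00,,U,U\n"),
             file.path(dir, "det.csv"))
  dat <- readCamtrapData(file.path(dir, "det.csv"),
                         file.path(dir, "stations.csv"),
                         file.path(dir, "effort.csv"))
  expect_equal(nrow(dat$events), 3)
  expect_s3_class(dat$events$timestamp, "POSIXct")
  expect_equal(format(dat$events$timestamp[2], "%H:%M"), "02:00")
  expect_true(is.na(dat$events$individual_id[3]))

  # enumeration violations name the offending row
  writeLines(paste0("station_id,datetime,individual_id,sex,flank\n",
                    "A,2020-01-05 21:30:00,ind1,X,L\n"),
             file.path(dir, "det.csv"))
  expect_error(readCamtrapData(file.path(dir, "det.csv"),
                               file.path(dir, "stations.csv"),
                               file.path(dir, "effort.csv")),
               "sex.*row.*1")

  # unknown station reference rejected
  writeLines(paste0("station_id,datetime,individual_id,sex,flank\n",
                    "Z,2020-01-05 21:30:00,ind1,M,L\n"),
             file.path(dir, "det.csv"))
  expect_error(readCamtrapData(file.path(dir, "det.csv"),
                               file.path(dir, "stations.csv"),
                               file.path(dir, "effort.csv")),
               "unknown station")

  # events outside all effort intervals warn but load
  writeLines(paste0("station_id,datetime,individual_id,sex,flank\n",
                    "A,2021-06-05 21:30:00,ind1,M,L\n"),
             file.path(dir, "det.csv"))
  expect_warning(readCamtrapData(file.path(dir, "det.csv"),
                                 file.path(dir, "stations.csv"),
                                 file.path(dir, "effort.csv")),
                 "outside")
})

test_that("daily independence filter keeps the earliest event per rule and is idempotent", {
  ev <- makeEvents("A",
                   c("2020-01-01 02:00:00", "2020-01-01 23:00:00"),
                   id = "ind1")
  expect_equal(nrow(filterIndependent(ev)), 1)
  expect_equal(format(filterIndependent(ev)$timestamp, "%H"), "02")

  # same individual at two stations on one date: both kept
  ev2 <- makeEvents(c("A", "B"),
                    c("2020-01-01 02:00:00", "2020-01-01 23:00:00"),
                    id = "ind1")
  expect_equal(nrow(filterIndependent(ev2)), 2)

  # 5 events with 2 duplicate pairs -> 3 retained, against the brute oracle
  ev3 <- makeEvents(c("A", "A", "A", "B", "B"),
                    c("2020-01-01 02:00:00", "2020-01-01 12:00:00",
                      "2020-01-02 03:00:00", "2020-01-02 04:00:00",
                      "2020-01-02 20:00:00"),
                    id = c("i1", "i1", "i2", "i3", "i3"))
  got <- filterIndependent(ev3)
  expect_equal(nrow(got), 3)
  expect_equal(got$timestamp, bruteDedup(ev3)$timestamp)

  # randomized property: matches brute force and is idempotent
  set.seed(7)
  for (rep in 1:10) {
    n <- 30
    ev <- makeEvents(sample(c("A", "B", "C"), n, replace = TRUE),
                     format(as.POSIXct("2020-01-01", tz = "UTC") +
                              runif(n, 0, 5 * 86400), "%Y-%m-%d %H:%M:%S"),
                     id = sample(c("i1", "i2", NA), n, replace = TRUE))
    got <- filterIndependent(ev)
    expect_equal(got$timestamp, bruteDedup(ev)$timestamp)
    expect_equal(filterIndependent(got), got)
  }
})

test_that("trap-night counting follows the nights = end - start union convention", {
  eff <- makeEffort("A", "2020-01-01", "2020-01-11")
  expect_equal(trapNights(eff), 10)

  # overlapping intervals at one station count each night once
  eff2 <- makeEffort(c("A", "A"), c("2020-01-01", "2020-01-05"),
                     c("2020-01-11", "2020-01-15"))
  expect_equal(trapNights(eff2), 14)

  # 12-station fixture against night-by-night enumeration
  set.seed(11)
  st <- sprintf("S%02d", 1:12)
  eff3 <- do.call(rbind, lapply(st, function(s) {
    k <- sample(1:3, 1)
    starts <- as.Date("2020-01-01") + sample(0:60, k)
    makeEffort(s, format(starts), format(starts + sample(5:20, k, TRUE)))
  }))
  expect_equal(trapNights(eff3), bruteTrapNights(eff3))

  # window clipping and bad windows
  expect_equal(trapNights(eff, from = "2020-01-05", to = "2020-01-07"), 3)
  expect_error(trapNights(eff, from = "2020-02-01", to = "2020-01-01"),
               "window")
})

test_that("flank rule gives conservative and maximal individual counts", {
  # B = 1, L-only = 2, R-only = 1 -> (3, 4)
  ev <- makeEvents("A",
                   sprintf("2020-01-%02d 02:00:00", 1:5),
                   id = c("b1", "l1", "l2", "r1", "b1"),
                   flank = c("B", "L", "L", "R", "L"))
  cnt <- countIndividuals(ev)
  expect_equal(cnt$n_min, 3)
  expect_equal(cnt$n_max, 4)

  # all both-flanked -> exact count
  ev2 <- makeEvents("A", sprintf("2020-01-%02d 02:00:00", 1:5),
                    id = paste0("i", 1:5), flank = "B")
  expect_equal(countIndividuals(ev2)$n_min, 5)
  expect_equal(countIndividuals(ev2)$n_max, 5)

  # an individual seen L in one event and R in another is both-flank known
  ev3 <- makeEvents("A", sprintf("2020-01-%02d 02:00:00", 1:2),
                    id = "i1", flank = c("L", "R"))
  expect_equal(countIndividuals(ev3)$n_both, 1)

  # empty input
  empty <- makeEvents(character(), character())
  expect_equal(countIndividuals(empty)$n_min, 0)
  expect_equal(countIndividuals(empty)$n_max, 0)

  # U-flank identified events excluded with a warning
  ev4 <- makeEvents("A", sprintf("2020-01-%02d 02:00:00", 1:2),
                    id = c("i1", "i2"), flank = c("B", "U"))
  expect_warning(cnt4 <- countIndividuals(ev4), "unknown flank")
  expect_equal(cnt4$n_max, 1)

  # property: n_max - n_min = min(L, R)
  set.seed(3)
  for (rep in 1:10) {
    n <- 20
    ev <- makeEvents("A",
                     format(as.POSIXct("2020-01-01", tz = "UTC") +
                              seq_len(n) * 86400, "%Y-%m-%d %H:%M:%S"),
                     id = sample(paste0("i", 1:8), n, replace = TRUE),
                     flank = sample(c("L", "R", "B"), n, replace = TRUE))
    cnt <- countIndividuals(ev)
    expect_equal(cnt$n_max - cnt$n_min,
                 min(cnt$n_left_only, cnt$n_right_only))
  }
})

test_that("detection rate matches the published per-100-trap-night convention", {
  expect_equal(detectionRate(21, 1425), 1.47)
  expect_equal(detectionRate(3, 2122), 0.14)
  expect_equal(detectionRate(0, 500), 0)
  expect_error(detectionRate(3, 0), "positive")
  # homogeneity: doubling events and effort leaves the rate unchanged
  expect_equal(detectionRate(42, 2850), detectionRate(21, 1425))
})

test_that("location-years split by calendar year and match a group-by oracle", {
  # one station active across a year boundary -> 2 location-years
  eff <- makeEffort("A", "2012-12-01", "2013-02-15")
  ev <- makeEvents("A", c("2012-12-15 02:00:00", "2013-01-10 03:00:00"),
                   id = "i1")
  ly <- buildLocationYears(ev, eff)
  expect_equal(nrow(ly), 2)
  expect_equal(ly$year, c(2012, 2013))
  expect_equal(ly$n_events, c(1, 1))
  expect_equal(sum(ly$trap_nights), trapNights(eff))

  # effort with no events still yields a location-year
  eff2 <- rbind(eff, makeEffort("B", "2013-01-01", "2013-01-20"))
  ly2 <- buildLocationYears(ev, eff2)
  expect_equal(ly2$n_events[ly2$station_id == "B"], 0)

  # 4 stations x 3 years against a brute group-by
  set.seed(5)
  st <- c("A", "B", "C", "D")
  eff3 <- do.call(rbind, lapply(st, function(s)
    makeEffort(s, paste0(2010:2012, "-02-01"), paste0(2010:2012, "-05-01"))))
  n <- 60
  ev3 <- makeEvents(sample(st, n, TRUE),
                    format(as.POSIXct("2010-02-01", tz = "UTC") +
                             sample(0:80, n, TRUE) * 86400 +
                             rep(c(0, 366, 731), 20)[sample(1:60)] * 86400,
                           "%Y-%m-%d %H:%M:%S"),
                    id = "i1")
  ev3 <- ev3[format(ev3$date, "%m") %in% c("02", "03", "04"), ]
  ly3 <- buildLocationYears(ev3, eff3)
  expect_equal(nrow(ly3), 12)
  manual <- table(ev3$station_id, format(ev3$date, "%Y"))
  for (i in seq_len(nrow(ly3)))
    expect_equal(ly3$n_events[i],
                 unname(manual[ly3$station_id[i], as.character(ly3$year[i])]))

  # per-station location-year trap-nights sum to the station total
  for (s in st)
    expect_equal(sum(ly3$trap_nights[ly3$station_id == s]),
                 trapNights(eff3, stations = s))
})
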