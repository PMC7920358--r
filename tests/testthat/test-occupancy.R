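test_that("detection histories encode detection, absence and missing effort", {
  st <- makeStations(c("A", "B"), c(0, 2), c(0, 0))
  # A surveyed both seasons; B only in season 1
  eff <- rbind(makeEffort("A", c("2010-02-01", "2011-02-01"),
                          c("2010-05-02", "2011-05-02")),
               makeEffort("B", "2010-02-01", "2010-05-02"))
  # event on day 45 of season 1 -> occasion 2
  ev <- makeEvents("A", c("2010-03-17 02:00:00", "2011-02-05 03:00:00"),
                   id = "i1")
  h <- buildHistory(ev, eff, st, c("2010-02-01", "2011-02-01"))
  expect_s4_class(h, "DetectionHistory")
  expect_equal(dim(historyArray(h)), c(2, 2, 3))
  expect_equal(historyArray(h)["A", 1, ], c(0, 1, 0))
  expect_equal(historyArray(h)["A", 2, ], c(1, 0, 0))
  expect_true(all(is.na(historyArray(h)["B", 2, ])))
  expect_equal(historyArray(h)["B", 1, ], c(0, 0, 0))
  expect_equal(nSites(h), 2)
  expect_equal(nSeasons(h), 2)
  expect_equal(nOccasions(h), 3)
})

test_that("the forward-recursion likelihood matches closed cases and brute-force enumeration", {
  mkHist <- function(y) new("DetectionHistory", y = y,
                            seasonStarts = as.Date(character()),
                            occasionDays = 30,
                            stationIds = as.character(seq_len(dim(y)[1])))
  # certain detection at an occupied site has probability 1
  y <- array(1L, dim = c(1, 1, 3))
  h <- mkHist(y)
  expect_equal(occuLoglik(list(psi1 = 1, gamma = 0, epsilon = 0, p = 1), h), 0)

  # an all-missing history is uninformative
  y <- array(NA_integer_, dim = c(2, 3, 2))
  expect_equal(occuLoglik(list(psi1 = 0.4, gamma = 0.2, epsilon = 0.3,
                               p = 0.5), mkHist(y)), 0)

  # brute-force latent-state enumeration, random params and histories
  set.seed(21)
  for (rep in 1:20) {
    T <- sample(2:4, 1); J <- sample(1:3, 1); M <- sample(1:4, 1)
    y <- array(sample(c(0L, 1L, NA), M * T * J, TRUE), dim = c(M, T, J))
    pars <- list(psi1 = runif(1), gamma = runif(T - 1),
                 epsilon = runif(T - 1),
                 p = matrix(runif(T * J), T, J))
    h <- mkHist(y)
    expect_equal(occuLoglik(pars, h), bruteLoglik(pars, y),
                 tolerance = 1e-10)
  }

  # invariance to permuting sites
  y <- array(sample(c(0L, 1L, NA), 24, TRUE), dim = c(4, 3, 2))
  pars <- list(psi1 = 0.5, gamma = c(0.2, 0.3), epsilon = c(0.1, 0.4),
               p = 0.6)
  expect_equal(occuLoglik(pars, mkHist(y)),
               occuLoglik(pars, mkHist(y[c(3, 1, 4, 2), , , drop = FALSE])))

  expect_error(occuLoglik(list(psi1 = 1.2, gamma = 0, epsilon = 0, p = 1),
                          mkHist(array(0L, c(1, 1, 1)))), "\\[0, 1\\]")
})

test_that("seasonal occupancy derives by the colonization-extinction recursion", {
  # published worked examples, to the printed precision
  expect_equal(round(derivedPsi(0.52, 0.80, 0.78)[2], 2), 0.50)
  expect_equal(round(derivedPsi(0.50, 0.00, 0.67)[2], 2), 0.16)

  # absorbing dynamics keep occupancy constant
  expect_equal(derivedPsi(0.37, rep(0, 5), rep(0, 5)), rep(0.37, 6))

  # stays in [0,1]; converges to gamma/(gamma+eps) when rates are constant
  set.seed(2)
  for (rep in 1:10) {
    g <- runif(1); e <- runif(1)
    psi <- derivedPsi(runif(1), rep(g, 199), rep(e, 199))
    expect_true(all(psi >= 0 & psi <= 1))
    expect_equal(psi[200], g / (g + e), tolerance = 1e-6)
  }
})

test_that("the candidate model set reproduces the published parameter accounting", {
  ms <- modelSet()
  expect_length(ms, 7)
  labels <- vapply(ms, function(s) s$label, character(1))
  expect_true("psi(.)gam(t)eps(t)p(.)" %in% labels)
  # ranking-table K (model params + 1 for c-hat) for 12 seasons x 3 occasions
  K <- vapply(ms, nParams, integer(1), T = 12, J = 3) + 1L
  expect_equal(K, c(25L, 60L, 40L, 36L, 5L, 7L, 16L))
  expect_equal(nParams(occuModelSpec(".", ".", "."), 12, 3), 4L)
})

test_that("model fitting is deterministic, recovers truth and flags boundaries", {
  set.seed(77)
  truth <- list(psi1 = 0.6, gamma = 0.3, epsilon = 0.2, p = 0.5)
  y <- array(NA_integer_, dim = c(150, 4, 3))
  z <- rbinom(150, 1, truth$psi1)
  for (t in 1:4) {
    for (j in 1:3) y[, t, j] <- rbinom(150, 1, z * truth$p)
    if (t < 4) z <- rbinom(150, 1, ifelse(z == 1, 1 - truth$epsilon,
                                          truth$gamma))
  }
  h <- new("DetectionHistory", y = y, seasonStarts = as.Date(character()),
           occasionDays = 30, stationIds = as.character(1:150))
  f1 <- fitOccupancy(h, occuModelSpec(), nStarts = 5, seed = 4)
  f2 <- fitOccupancy(h, occuModelSpec(), nStarts = 5, seed = 4)
  expect_identical(f1@theta, f2@theta)
  expect_true(f1@converged)
  est <- occuEstimates(f1)
  expect_equal(est$estimate[est$parameter == "psi1"], 0.6, tolerance = 0.35)
  expect_equal(est$estimate[est$parameter == "p"], 0.5, tolerance = 0.2)
  expect_true(all(est$se >= 0, na.rm = TRUE))

  # all-zero history drives detection (or occupancy) to the boundary
  y0 <- array(0L, dim = c(30, 3, 3))
  h0 <- new("DetectionHistory", y = y0, seasonStarts = as.Date(character()),
            occasionDays = 30, stationIds = as.character(1:30))
  f0 <- fitOccupancy(h0, occuModelSpec(), nStarts = 8, seed = 2)
  expect_true(any(occuEstimates(f0)$boundary))
  expect_true(all(occuEstimates(f0)$se[occuEstimates(f0)$boundary] == 0))

  expect_error(fitOccupancy(
    new("DetectionHistory", y = array(0L, c(2, 1, 3)),
        seasonStarts = as.Date(character()), occasionDays = 30,
        stationIds = c("a", "b")), occuModelSpec()), "2 seasons")
})

test_that("QAICc ranking follows the quasi-likelihood small-sample formula", {
  mkFit <- function(ll, K, label) {
    y <- array(0L, c(20, 12, 3))
    h <- new("DetectionHistory", y = y, seasonStarts = as.Date(character()),
             occasionDays = 30, stationIds = as.character(1:20))
    new("OccupancyFit", spec = list(label = label), estimates = data.frame(),
        theta = numeric(K), logLik = ll, nPar = as.integer(K),
        converged = TRUE, seed = 1L, history = h)
  }
  # c-hat = 1, one model: QAICc equals AICc with K = nPar + 1
  t1 <- qaiccTable(list(mkFit(-100, 4, "m1")), cHat = 1, effectiveN = 50)
  K <- 5
  expect_equal(t1$QAICc, 200 + 2 * K + 2 * K * (K + 1) / (50 - K - 1))

  # two hand-made (ll, K) pairs against a hand calculation
  tt <- qaiccTable(list(mkFit(-100, 4, "m1"), mkFit(-97, 9, "m2")),
                   cHat = 1.5, effectiveN = 50)
  q1 <- 200 / 1.5 + 10 + 60 / 44
  q2 <- 194 / 1.5 + 20 + 220 / 39
  expect_equal(sort(tt$QAICc), sort(c(q1, q2)))
  expect_equal(tt$delta, sort(c(q1, q2)) - min(q1, q2))
  w <- exp(-(c(q1, q2) - min(q1, q2)) / 2)
  expect_equal(sort(tt$weight), sort(w / sum(w)))
  expect_equal(sum(tt$weight), 1, tolerance = 1e-12)

  # c-hat below 1 is used as 1
  expect_equal(qaiccTable(list(mkFit(-100, 4, "m1")), cHat = 0.6,
                          effectiveN = 50)$QAICc, t1$QAICc)

  # permuting model order changes no QAICc value
  tp <- qaiccTable(list(mkFit(-97, 9, "m2"), mkFit(-100, 4, "m1")),
                   cHat = 1.5, effectiveN = 50)
  expect_equal(tp$QAICc, tt$QAICc)

  # degenerate small-sample correction is flagged, not hidden
  td <- qaiccTable(list(mkFit(-100, 24, "big")), cHat = 1, effectiveN = 20)
  expect_true(td$smallSampleDegenerate)
})

test_that("the parametric-bootstrap GOF is reproducible and validates its inputs", {
  set.seed(5)
  y <- array(rbinom(40 * 3 * 3, 1, 0.3), dim = c(40, 3, 3))
  h <- new("DetectionHistory", y = y, seasonStarts = as.Date(character()),
           occasionDays = 30, stationIds = as.character(1:40))
  f <- fitOccupancy(h, occuModelSpec(), nStarts = 4, seed = 3)
  expect_error(gofBootstrap(f, nSims = 0), "at least 1")
  g1 <- gofBootstrap(f, nSims = 8, seed = 11)
  g2 <- gofBootstrap(f, nSims = 8, seed = 11)
  expect_identical(g1$sim_chi2, g2$sim_chi2)
  expect_gt(g1$c_hat, 0)
  expect_true(g1$p_value >= 0 && g1$p_value <= 1)
})

test_that("turnover labels use the strict 0.1 threshold", {
  expect_equal(placementSuitability(0.05, 0.05), "consistent")
  expect_equal(placementSuitability(0.80, 0.78), "high-turnover")
  expect_equal(placementSuitability(0.1, 0.1), "consistent")
  expect_equal(placementSuitability(c(0.8, 0.0), c(0.78, 0.67)),
               c("high-turnover", "high-turnover"))
})
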