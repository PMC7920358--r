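## Dynamic (multi-season) site-occupancy model: initial occupancy psi1,
## per-transition colonization gamma_t and extinction epsilon_t, and
## detection probability p. The site likelihood is a forward recursion over
## the two latent states; fitting is by quasi-Newton maximisation on the
## logit scale with random multi-starts.

setOldClass("Date")

#' Detection history container
#'
#' Sites x seasons x occasions array of detection (1), non-detection under
#' effort (0) and missing (`NA`, no functional effort in the occasion).
#'
#' @slot y integer array, sites x seasons x occasions.
#' @slot seasonStarts season start dates.
#' @slot occasionDays occasion length in days.
#' @slot stationIds site labels (first array dimension).
#' @export
setClass("DetectionHistory",
         representation(y = "array", seasonStarts = "Date",
                        occasionDays = "numeric", stationIds = "character"),
         validity = function(object) {
           y <- object@y
           if (length(dim(y)) != 3)
             return("y must be a 3-d array (sites x seasons x occasions)")
           v <- y[!is.na(y)]
           if (length(v) && !all(v %in% c(0, 1)))
             return("history values must be 0, 1 or NA")
           if (length(object@seasonStarts) &&
               length(object@seasonStarts) != dim(y)[2])
             return("seasonStarts length must match the season dimension")
           TRUE
         })

#' @describeIn DetectionHistory number of sites
#' @param x,object a `DetectionHistory`.
#' @export
nSites <- function(x) dim(x@y)[1]

#' @describeIn DetectionHistory number of primary seasons
#' @export
nSeasons <- function(x) dim(x@y)[2]

#' @describeIn DetectionHistory number of secondary occasions per season
#' @export
nOccasions <- function(x) dim(x@y)[3]

#' @describeIn DetectionHistory the underlying array
#' @export
historyArray <- function(x) x@y

setMethod("show", "DetectionHistory", function(object) {
  d <- dim(object@y)
  cat(sprintf("DetectionHistory: %d sites x %d seasons x %d occasions\n",
              d[1], d[2], d[3]))
  cat(sprintf("  detections %d, zeros %d, missing %d\n",
              sum(object@y == 1, na.rm = TRUE),
              sum(object@y == 0, na.rm = TRUE), sum(is.na(object@y))))
})

#' Build a seasonal detection history
#'
#' Each season window is divided into `nOccasions` consecutive occasions of
#' `occasionDays` days. A cell is 1 if any event (of any individual) occurred
#' at the site in the occasion, 0 if the site had functional effort but no
#' event, and missing if it had no functional night in the occasion.
#'
#' @param events validated event data frame.
#' @param effort effort table.
#' @param stations station registry data frame (defines the site order).
#' @param seasonStarts Date vector of season start dates (non-overlapping).
#' @param occasionDays occasion length in days (default 30).
#' @param nOccasions occasions per season (default 3).
#' @return a [DetectionHistory-class] object.
#' @export
buildHistory <- function(events, effort, stations, seasonStarts,
                         occasionDays = 30, nOccasions = 3) {
  seasonStarts <- sort(as.Date(seasonStarts))
  if (length(seasonStarts) > 1 &&
      any(diff(seasonStarts) < occasionDays * nOccasions))
    stop("season windows overlap the occasion grid", call. = FALSE)
  sites <- stations$station_id
  M <- length(sites); T <- length(seasonStarts); J <- nOccasions
  y <- array(NA_integer_, dim = c(M, T, J),
             dimnames = list(sites, format(seasonStarts, "%Y"), NULL))
  nights <- .effortNights(effort)
  for (t in seq_len(T)) {
    for (j in seq_len(J)) {
      w0 <- seasonStarts[t] + (j - 1) * occasionDays
      w1 <- w0 + occasionDays - 1          # nights w0 .. w1 inclusive
      nt <- nights[nights$night >= w0 & nights$night <= w1, , drop = FALSE]
      surveyed <- sites %in% nt$station_id
      ev <- events[events$date >= w0 & events$date <= w1, , drop = FALSE]
      det <- sites %in% ev$station_id
      y[surveyed, t, j] <- 0L
      y[det & surveyed, t, j] <- 1L
    }
  }
  new("DetectionHistory", y = y, seasonStarts = seasonStarts,
      occasionDays = occasionDays, stationIds = as.character(sites))
}

## normalise p to a T x J matrix
.pMatrix <- function(p, T, J) {
  if (is.matrix(p)) {
    stopifnot(nrow(p) == T, ncol(p) == J)
    return(p)
  }
  if (length(p) == 1) return(matrix(p, T, J))
  stop("p must be a scalar or a T x J matrix", call. = FALSE)
}

#' Dynamic-occupancy log-likelihood
#'
#' Forward recursion over the two latent states per site: initial law
#' `(psi1, 1 - psi1)`, between-season transition matrix
#' `[[1 - eps_t, eps_t], [gamma_t, 1 - gamma_t]]` (rows: occupied,
#' unoccupied), and within-season emission `prod_j p^y (1-p)^(1-y)` when
#' occupied or the indicator of an all-zero observed season when unoccupied.
#' Missing occasions contribute a factor of 1. Site log-probabilities are
#' summed.
#'
#' @param params list with `psi1` (scalar), `gamma` and `epsilon` (length
#'   `T - 1`, or scalars recycled), and `p` (scalar or `T x J` matrix).
#' @param history a [DetectionHistory-class].
#' @return the log-likelihood.
#' @export
occuLoglik <- function(params, history) {
  y <- history@y
  M <- dim(y)[1]; T <- dim(y)[2]; J <- dim(y)[3]
  psi <- params$psi1
  gam <- rep(params$gamma, length.out = max(T - 1, 0))
  eps <- rep(params$epsilon, length.out = max(T - 1, 0))
  p <- .pMatrix(params$p, T, J)
  if (any(c(psi, gam, eps, p) < 0) || any(c(psi, gam, eps, p) > 1))
    stop("parameters must lie in [0, 1]", call. = FALSE)
  aOcc <- rep(psi, M); aUn <- rep(1 - psi, M)
  for (t in seq_len(T)) {
    yt <- matrix(y[, t, ], nrow = M)
    eOcc <- rep(1, M)
    anyDet <- rep(FALSE, M)
    for (j in seq_len(J)) {
      yj <- yt[, j]
      obs <- !is.na(yj)
      eOcc[obs] <- eOcc[obs] *
        ifelse(yj[obs] == 1, p[t, j], 1 - p[t, j])
      anyDet <- anyDet | (obs & !is.na(yj) & yj == 1)
    }
    aOcc <- aOcc * eOcc; aUn <- aUn * as.numeric(!anyDet)
    if (t < T) {
      newOcc <- aOcc * (1 - eps[t]) + aUn * gam[t]
      newUn <- aOcc * eps[t] + aUn * (1 - gam[t])
      aOcc <- newOcc; aUn <- newUn
    }
  }
  sum(log(pmax(aOcc + aUn, 1e-300)))
}

#' Occupancy model structure
#'
#' Defines which parameters vary: colonization and extinction constant
#' (`"."`) or by transition (`"t"`); detection constant (`"."`), by occasion
#' (`"s"`), by season (`"t"`) or by season and occasion (`"t*s"`).
#'
#' @param gamma,epsilon `"."` or `"t"`.
#' @param p one of `"."`, `"s"`, `"t"`, `"t*s"`.
#' @return list of class `occuModelSpec` with a `label` field.
#' @export
occuModelSpec <- function(gamma = ".", epsilon = ".", p = ".") {
  gamma <- match.arg(gamma, c(".", "t"))
  epsilon <- match.arg(epsilon, c(".", "t"))
  p <- match.arg(p, c(".", "s", "t", "t*s"))
  out <- list(gamma = gamma, epsilon = epsilon, p = p,
              label = sprintf("psi(.)gam(%s)eps(%s)p(%s)", gamma, epsilon, p))
  class(out) <- "occuModelSpec"
  out
}

#' Number of free parameters of a model structure
#'
#' Excludes the overdispersion parameter c-hat; the ranking table adds 1
#' for it.
#'
#' @param spec an `occuModelSpec`.
#' @param T number of seasons.
#' @param J number of occasions per season.
#' @return integer parameter count.
#' @export
nParams <- function(spec, T, J) {
  ng <- if (spec$gamma == "t") T - 1 else 1
  ne <- if (spec$epsilon == "t") T - 1 else 1
  np <- switch(spec$p, "." = 1, "s" = J, "t" = T, "t*s" = T * J)
  as.integer(1 + ng + ne + np)
}

#' The standard seven-model candidate set
#'
#' All combinations in which colonization and extinction are jointly
#' constant or time-varying, crossed with detection constant, by occasion,
#' by season, or by season x occasion -- excluding time-varying dynamics
#' with occasion-only detection, giving seven models.
#'
#' @return list of `occuModelSpec` objects.
#' @export
modelSet <- function() {
  list(occuModelSpec("t", "t", "."),
       occuModelSpec("t", "t", "t*s"),
       occuModelSpec(".", ".", "t*s"),
       occuModelSpec("t", "t", "t"),
       occuModelSpec(".", ".", "."),
       occuModelSpec(".", ".", "s"),
       occuModelSpec(".", ".", "t"))
}

## ---- parameter packing ------------------------------------------------------

.plogis <- function(x) 1 / (1 + exp(-x))
.qlogis <- function(p) log(p / (1 - p))

.thetaTemplate <- function(spec, T, J) {
  ng <- if (spec$gamma == "t") T - 1 else 1
  ne <- if (spec$epsilon == "t") T - 1 else 1
  np <- switch(spec$p, "." = 1, "s" = J, "t" = T, "t*s" = T * J)
  list(ng = ng, ne = ne, np = np, total = 1 + ng + ne + np)
}

.unpackTheta <- function(theta, spec, T, J) {
  tpl <- .thetaTemplate(spec, T, J)
  pr <- .plogis(theta)
  i <- 1
  psi <- pr[i]; i <- i + 1
  gam <- pr[i:(i + tpl$ng - 1)]; i <- i + tpl$ng
  eps <- pr[i:(i + tpl$ne - 1)]; i <- i + tpl$ne
  praw <- pr[i:(i + tpl$np - 1)]
  p <- switch(spec$p,
              "." = matrix(praw, T, J),
              "s" = matrix(praw, T, J, byrow = TRUE),
              "t" = matrix(praw, T, J),
              "t*s" = matrix(praw, T, J, byrow = TRUE))
  list(psi1 = psi,
       gamma = rep(gam, length.out = max(T - 1, 1)),
       epsilon = rep(eps, length.out = max(T - 1, 1)),
       p = p)
}

.thetaNames <- function(spec, T, J) {
  tpl <- .thetaTemplate(spec, T, J)
  gn <- if (tpl$ng == 1) "gamma" else sprintf("gamma[%d]", seq_len(tpl$ng))
  en <- if (tpl$ne == 1) "epsilon" else sprintf("epsilon[%d]", seq_len(tpl$ne))
  pn <- switch(spec$p,
               "." = "p",
               "s" = sprintf("p[occ %d]", seq_len(J)),
               "t" = sprintf("p[season %d]", seq_len(T)),
               "t*s" = sprintf("p[%s]", outer(seq_len(J), seq_len(T),
                               function(j, t) sprintf("season %d, occ %d", t, j))))
  c("psi1", gn, en, pn)
}

#' Fitted dynamic-occupancy model
#'
#' @slot spec the `occuModelSpec` fitted.
#' @slot estimates data frame of estimates and delta-method standard errors
#'   on the probability scale, with boundary flags.
#' @slot theta maximising parameter vector on the logit scale.
#' @slot logLik maximised log-likelihood.
#' @slot nPar number of free model parameters (c-hat excluded).
#' @slot converged optimiser convergence flag.
#' @slot seed seed used for the random starts.
#' @slot history the fitted `DetectionHistory`.
#' @export
setClass("OccupancyFit",
         representation(spec = "list", estimates = "data.frame",
                        theta = "numeric", logLik = "numeric",
                        nPar = "integer", converged = "logical",
                        seed = "integer", history = "DetectionHistory"),
         validity = function(object) {
           if (object@nPar != length(object@theta))
             return("nPar must match the parameter vector length")
           if (any(object@estimates$se < 0, na.rm = TRUE))
             return("standard errors must be non-negative")
           TRUE
         })

setMethod("show", "OccupancyFit", function(object) {
  cat(sprintf("OccupancyFit %s: logLik %.3f, K = %d, converged = %s\n",
              object@spec$label, object@logLik, object@nPar,
              object@converged))
  print(object@estimates, digits = 3)
})

#' @describeIn OccupancyFit estimates table (probability scale)
#' @param fit an `OccupancyFit`.
#' @export
occuEstimates <- function(fit) fit@estimates

#' @describeIn OccupancyFit fitted parameters as an [occuLoglik()] params list
#' @export
occuParams <- function(fit) {
  h <- fit@history
  .unpackTheta(fit@theta, fit@spec, nSeasons(h), nOccasions(h))
}

#' @describeIn OccupancyFit maximised log-likelihood
#' @export
occuLogLik <- function(fit) fit@logLik

#' Fit a dynamic-occupancy model
#'
#' Maximum likelihood on the logit scale by BFGS with `nStarts` random
#' initialisations drawn uniformly on (-2, 2); the best optimum is kept.
#' Standard errors come from the numeric curvature at the optimum by the
#' delta method; estimates with `|logit| > 10` are flagged as boundary and
#' reported with SE 0.
#'
#' @param history a [DetectionHistory-class] with at least 2 seasons.
#' @param spec an [occuModelSpec()].
#' @param nStarts number of random starts (default 25).
#' @param seed integer seed for the starts.
#' @return an [OccupancyFit-class].
#' @export
fitOccupancy <- function(history, spec = occuModelSpec(), nStarts = 25,
                         seed = 1) {
  T <- nSeasons(history); J <- nOccasions(history)
  if (T < 2) stop("history must span at least 2 seasons", call. = FALSE)
  tpl <- .thetaTemplate(spec, T, J)
  negll <- function(theta) {
    pr <- .unpackTheta(theta, spec, T, J)
    -occuLoglik(pr, history)
  }
  set.seed(seed)
  best <- NULL
  for (k in seq_len(nStarts)) {
    th0 <- runif(tpl$total, -2, 2)
    opt <- tryCatch(
      optim(th0, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("no start converged", call. = FALSE)
  theta <- best$par
  boundary <- abs(theta) > 10
  se <- rep(NA_real_, length(theta))
  hin <- which(!boundary)
  if (length(hin)) {
    hess <- tryCatch(optimHess(theta, negll), error = function(e) NULL)
    if (!is.null(hess)) {
      vc <- tryCatch(solve(hess[hin, hin, drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(vc)) {
        d <- diag(vc)
        d[d < 0] <- NA_real_
        se[hin] <- sqrt(d)
      }
    }
  }
  prob <- .plogis(theta)
  seProb <- se * prob * (1 - prob)
  seProb[boundary] <- 0
  est <- data.frame(parameter = .thetaNames(spec, T, J),
                    estimate = prob, se = seProb, boundary = boundary,
                    stringsAsFactors = FALSE)
  new("OccupancyFit", spec = unclass(spec), estimates = est, theta = theta,
      logLik = -best$value, nPar = as.integer(tpl$total),
      converged = best$convergence == 0, seed = as.integer(seed),
      history = history)
}

#' Derived seasonal occupancy
#'
#' Occupancy is a free parameter in the first season only; afterwards it
#' follows the recursion `psi[t+1] = psi[t] (1 - epsilon[t]) +
#' (1 - psi[t]) gamma[t]`.
#'
#' @param psi1 initial occupancy.
#' @param gamma,epsilon per-transition colonization and extinction
#'   probabilities (equal length `T - 1`).
#' @return numeric vector `psi[1..T]`.
#' @export
derivedPsi <- function(psi1, gamma, epsilon) {
  stopifnot(length(gamma) == length(epsilon),
            all(c(psi1, gamma, epsilon) >= 0),
            all(c(psi1, gamma, epsilon) <= 1))
  psi <- numeric(length(gamma) + 1)
  psi[1] <- psi1
  for (t in seq_along(gamma))
    psi[t + 1] <- psi[t] * (1 - epsilon[t]) + (1 - psi[t]) * gamma[t]
  psi
}

## ---- model selection --------------------------------------------------------

#' QAICc model-ranking table
#'
#' `QAICc = -2 logLik / c-hat + 2K + 2K(K+1)/(n - K - 1)` with
#' `K = nPar + 1` (the overdispersion parameter counts as estimated).
#' A supplied `cHat < 1` is treated as 1. Rows are sorted ascending by
#' QAICc; Akaike weights are normalised over the set. When
#' `effectiveN <= K + 1` the small-sample term is degenerate; the value is
#' still computed as specified and the row is flagged.
#'
#' @param fits list of [OccupancyFit-class] objects on the same history.
#' @param cHat overdispersion inflation factor applied to the whole table
#'   (conventionally taken from the most parameterised model).
#' @param effectiveN effective sample size for the small-sample correction
#'   (conventionally the number of sites).
#' @param gof optional list of [gofBootstrap()] results parallel to `fits`,
#'   whose chi-square, p and per-model c-hat are appended.
#' @return data frame of class `modelTable`, sorted by QAICc.
#' @export
qaiccTable <- function(fits, cHat = 1, effectiveN, gof = NULL) {
  cHat <- max(cHat, 1)
  K <- vapply(fits, function(f) f@nPar + 1L, integer(1))
  ll <- vapply(fits, function(f) f@logLik, numeric(1))
  corr <- 2 * K * (K + 1) / (effectiveN - K - 1)
  qaicc <- -2 * ll / cHat + 2 * K + corr
  out <- data.frame(
    model = vapply(fits, function(f) f@spec$label, character(1)),
    nPars = K, QAICc = qaicc, stringsAsFactors = FALSE)
  out$smallSampleDegenerate <- effectiveN <= K + 1
  if (!is.null(gof)) {
    out$gof_chi2 <- vapply(gof, function(g) g$chi2_observed, numeric(1))
    out$gof_p <- vapply(gof, function(g) g$p_value, numeric(1))
    out$c_hat <- vapply(gof, function(g) g$c_hat, numeric(1))
  }
  out <- out[order(out$QAICc), , drop = FALSE]
  out$delta <- out$QAICc - out$QAICc[1]
  w <- exp(-out$delta / 2)
  out$weight <- w / sum(w)
  out$cumWeight <- cumsum(out$weight)
  rownames(out) <- NULL
  class(out) <- c("modelTable", "data.frame")
  out
}

#' Camera-placement suitability from turnover rates
#'
#' A transition is labelled `high-turnover` when colonization or extinction
#' strictly exceeds the threshold (default 0.1, i.e. a change at two
#' stations of a fully occupied or fully empty 20-station grid), and
#' `consistent` otherwise.
#'
#' @param gamma,epsilon per-transition probabilities.
#' @param threshold strict threshold (default 0.1).
#' @return character vector of labels, one per transition.
#' @export
placementSuitability <- function(gamma, epsilon, threshold = 0.1) {
  stopifnot(length(gamma) == length(epsilon))
  ifelse(gamma > threshold | epsilon > threshold,
         "high-turnover", "consistent")
}

## ---- goodness of fit --------------------------------------------------------

## Pearson chi-square of observed vs expected within-season detection
## history frequencies. Cohorts are formed per season from sites with no
## missing occasion in that season; expected cell counts below `pool` are
## merged into one pooled cell per season.
.historyChi2 <- function(params, history, pool = 2) {
  y <- history@y
  M <- dim(y)[1]; T <- dim(y)[2]; J <- dim(y)[3]
  p <- .pMatrix(params$p, T, J)
  psiT <- derivedPsi(params$psi1,
                     rep(params$gamma, length.out = T - 1),
                     rep(params$epsilon, length.out = T - 1))
  codes <- as.matrix(expand.grid(rep(list(0:1), J)))[, J:1, drop = FALSE]
  chi2 <- 0
  for (t in seq_len(T)) {
    yt <- matrix(y[, t, ], nrow = M)
    ok <- rowSums(is.na(yt)) == 0
    n <- sum(ok)
    if (!n) next
    hstr <- apply(yt[ok, , drop = FALSE], 1, paste, collapse = "")
    cstr <- apply(codes, 1, paste, collapse = "")
    obs <- as.numeric(table(factor(hstr, levels = cstr)))
    pr <- apply(codes, 1, function(h) {
      det <- prod(p[t, ]^h * (1 - p[t, ])^(1 - h))
      psiT[t] * det + (1 - psiT[t]) * as.numeric(all(h == 0))
    })
    expd <- n * pr
    small <- expd < pool
    if (any(small) && sum(!small)) {
      obs <- c(obs[!small], sum(obs[small]))
      expd <- c(expd[!small], sum(expd[small]))
    }
    keep <- expd > 0
    chi2 <- chi2 + sum((obs[keep] - expd[keep])^2 / expd[keep])
  }
  chi2
}

## simulate a history from parameter values, preserving the missingness
## pattern of `history`
.simulateHistory <- function(params, history) {
  y <- history@y
  M <- dim(y)[1]; T <- dim(y)[2]; J <- dim(y)[3]
  p <- .pMatrix(params$p, T, J)
  gam <- rep(params$gamma, length.out = max(T - 1, 1))
  eps <- rep(params$epsilon, length.out = max(T - 1, 1))
  z <- matrix(0L, M, T)
  z[, 1] <- rbinom(M, 1, params$psi1)
  for (t in seq_len(T - 1))
    z[, t + 1] <- rbinom(M, 1, ifelse(z[, t] == 1, 1 - eps[t], gam[t]))
  ysim <- y
  for (t in seq_len(T)) {
    for (j in seq_len(J)) {
      obs <- !is.na(y[, t, j])
      ysim[obs, t, j] <- rbinom(sum(obs), 1, z[obs, t] * p[t, j])
    }
  }
  new("DetectionHistory", y = ysim, seasonStarts = history@seasonStarts,
      occasionDays = history@occasionDays, stationIds = history@stationIds)
}

#' Parametric-bootstrap goodness of fit and overdispersion
#'
#' Computes the Pearson chi-square of observed against expected
#' detection-history frequencies (cohorts by season, expected counts below 2
#' pooled), simulates `nSims` datasets from the fitted parameters, refits
#' the same model structure to each and recomputes the statistic. The
#' bootstrap p-value is the proportion of simulated statistics at least as
#' large as the observed one, and `c_hat` is the observed statistic over the
#' simulated mean.
#'
#' @param fit a converged [OccupancyFit-class].
#' @param history the fitted history (defaults to the one in `fit`).
#' @param nSims number of parametric-bootstrap simulations (default 1000).
#' @param seed integer seed.
#' @param refitStarts random starts per refit, in addition to a start at the
#'   original optimum (default 2).
#' @return list of class `gofResult`: `chi2_observed`, `p_value`, `c_hat`,
#'   `n_sims`, `seed`, and the simulated statistics `sim_chi2`.
#' @export
gofBootstrap <- function(fit, history = fit@history, nSims = 1000, seed = 1,
                         refitStarts = 2) {
  if (nSims < 1) stop("nSims must be at least 1", call. = FALSE)
  T <- nSeasons(history); J <- nOccasions(history)
  spec <- structure(fit@spec, class = "occuModelSpec")
  obs <- .historyChi2(occuParams(fit), history)
  set.seed(seed)
  sim <- numeric(nSims)
  for (b in seq_len(nSims)) {
    hb <- .simulateHistory(occuParams(fit), history)
    negll <- function(theta) -occuLoglik(.unpackTheta(theta, spec, T, J), hb)
    best <- tryCatch(
      optim(fit@theta, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    for (k in seq_len(refitStarts)) {
      th0 <- runif(length(fit@theta), -2, 2)
      opt <- tryCatch(
        optim(th0, negll, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    pb <- .unpackTheta(best$par, spec, T, J)
    sim[b] <- .historyChi2(pb, hb)
  }
  ## a saturated model can fit every cohort exactly; 0/0 means no evidence
  ## of overdispersion, so c-hat defaults to 1 there
  chat <- if (mean(sim) > 0) obs / mean(sim) else if (obs == 0) 1 else Inf
  out <- list(chi2_observed = obs,
              p_value = mean(sim >= obs),
              c_hat = chat,
              n_sims = nSims, seed = seed, sim_chi2 = sim)
  class(out) <- "gofResult"
  out
}

#' @export
print.gofResult <- function(x, ...) {
  cat(sprintf(
    "GOF bootstrap: chi2 = %.2f, p = %.3f, c-hat = %.2f (%d sims, seed %d)\n",
    x$chi2_observed, x$p_value, x$c_hat, x$n_sims, x$seed))
  invisible(x)
}
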