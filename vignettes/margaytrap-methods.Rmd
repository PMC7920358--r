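---
title: "Methods: long-term camera-trap by-catch analysis"
author: "margaytrap"
output: rmarkdown::html_document
---

# Scope

`margaytrap` analyses long-term camera-trap records of a cryptic,
individually identifiable felid photographed as by-catch on a grid designed
for a larger species. The central question such data can address is whether
a low detection rate reflects true rarity or a sampling design mismatched
to the animal's ranging behaviour. The package covers five analysis layers —
detection accounting, dynamic occupancy, activity overlap, effort–detection
relationships, and movement/interaction/tenure summaries — plus an
individual-based simulator that generates data with the statistical
structure the analyses assume, so the whole pipeline is testable without
field data.

# Detection accounting

**Independence.** Repeat photographs of one individual at one station on
one calendar day are collapsed to the earliest event. Events that cannot be
attributed to an individual are deduplicated per station and calendar date,
the strictest defensible reading; a per-hour alternative is available
(`filterIndependent(unidentifiedBy = "hour")`). The filter is idempotent,
and the suite verifies it against an exhaustive pairwise oracle.

**Trap-nights.** A station-night counts once if any camera at the station
functioned that night; an interval from `s` to `e` contributes `e - s`
nights, with midnight local time as the (undefined in most field
protocols, so documented here) night boundary. Twin cameras and
overlapping intervals are unioned.

**Flank counting.** When cameras are set for a larger species, single-flank
photographs are common and left-only/right-only individuals cannot be
matched. With `B` both-flank individuals and `L`/`R` single-flank ones, the
count is bounded by `n_min = B + max(L, R)` and `n_max = B + L + R`.

**Location-years.** All records of one station in one calendar year; the
unit for interaction and effort analyses.

# Dynamic occupancy

The detection history is sites x seasons x occasions with values 1
(detected), 0 (surveyed, undetected) and missing (no functional effort in
the occasion); the default occasion grid is three 30-day occasions over the
first 90 days of each annual season. The model is the standard two-state
dynamic occupancy model: initial occupancy $\psi_1$, per-transition
colonization $\gamma_t$ and extinction $\epsilon_t$, detection $p$. The
site likelihood is computed by a forward recursion over the latent
occupied/unoccupied states with transition matrix
$[[1-\epsilon_t, \epsilon_t], [\gamma_t, 1-\gamma_t]]$; missing occasions
contribute a factor of one. The recursion is verified against brute-force
enumeration of all latent sequences for up to four seasons at $10^{-10}$.

One $(\gamma_t, \epsilon_t)$ pair is attached to each inter-survey gap
regardless of the gap's calendar length; with irregular multi-year gaps the
pair simply absorbs the whole transition, which is what the usual
`T - 1`-transition parameter count implies.

**Fitting.** Maximum likelihood on the logit scale via BFGS with 25 random
starts drawn uniformly on (-2, 2) by default; convergence uses a relative
tolerance of $10^{-10}$. Standard errors are delta-method transforms of the
inverse numeric Hessian; estimates with |logit| > 10 are reported as
boundary estimates with SE 0. Parameter recovery is exercised at 500 sites
and 6 seasons over 50 replicates (a size chosen to make the 2-SE coverage
check sharp while staying desk-scale): every parameter is inside two
standard errors of truth in at least 90% of replicates.

**Model set and ranking.** Seven candidate structures: dynamics jointly
constant or time-varying, crossed with detection constant, per occasion,
per season, or per season x occasion (the time-varying-dynamics /
occasion-only-detection cell is not in the conventional set). Ranking uses
$\mathrm{QAICc} = -2\ell/\hat c + 2K + 2K(K+1)/(n_{\mathrm{eff}} - K - 1)$
with $K$ equal to the model parameter count plus one because $\hat c$
counts as estimated. The effective sample size is the number of sites by
default and configurable: it has no universally agreed definition, and with
20 sites and a 25-parameter model the small-sample term is degenerate — the
implementation computes the term exactly as written and flags
$n_{\mathrm{eff}} \le K + 1$ rows rather than silently altering the
formula. Because of that freedom, absolute QAICc values are not comparable
across choices of $n_{\mathrm{eff}}$; the parameter-count bookkeeping and
the within-table ranking are.

**Overdispersion.** $\hat c$ comes from a parametric bootstrap: the Pearson
chi-square of observed versus expected within-season detection-history
frequencies (cohorts by season; sites with partial missingness in a season
are dropped from that season's cohort; expected cells below 2 are pooled
into one cell — the pooling rule is a documented choice, as published
analyses rarely state theirs) is compared with its distribution over
datasets simulated from the fitted model and refitted. $\hat c$ is the
observed statistic over the simulated mean; a saturated model that fits
exactly gives 0/0, which is reported as 1 (no evidence of overdispersion).
The whole ranking table is inflated by the $\hat c$ of the most
parameterised model, and $\hat c < 1$ is used as 1. Calibration is checked
by simulating from the true model: the bootstrap's mean $\hat c$ stays
within [0.8, 1.2] and its p-values are consistent with uniformity.

**Placement suitability.** Transitions with $\gamma_t > 0.1$ or
$\epsilon_t > 0.1$ (strict) are labelled high-turnover: on a 20-station
grid, 0.1 corresponds to a change at two stations, and persistent
high turnover indicates stations that margay-like species occupy
inconsistently, i.e. sub-optimal placement rather than population change.

# Activity overlap

Clock times map to angles on $[0, 2\pi)$; no sun-anchoring is applied, raw
local clock time is used. Same-station same-hour clusters are first
collapsed to their median event (midpoint for even counts). Densities are
von Mises kernel estimates whose concentration comes from the standard
circular plug-in rule, divided by the `adjust` argument so larger values
smooth more. The overlap coefficient is the area under the minimum of the
two densities. The default estimator integrates on a common grid (512
points; the trapezoid rule on an equally spaced circular grid reduces to
the mean); a point-evaluation variant that averages truncated density
ratios at the observed times is selectable, since field studies rarely
state which published variant they used — results are labelled with the
variant. The estimator is checked against quadrature of the true minimum
for known mixtures (within 0.03 at n = 3000) and at its extremes
(identical samples give 1, tight antipodal clusters give < 0.05).

Confidence intervals are nonparametric bootstrap percentiles (999
resamples of each group by default); a basic-bootstrap option is available,
clamped to [0, 1]. Percentile intervals on a known two-law configuration at
n = 100 per group cover the quadrature truth in at least 85% of replicates.
For two samples drawn from the *same* law the true coefficient is 1, a
boundary the kernel estimator approaches only as n grows; no bootstrap
interval can cover it at moderate n, so interval calibration is assessed
against an interior truth instead.

# Effort, movement, interaction, tenure

* Through-origin regression (`y = bx`) uses the closed form
  `b = sum(xy)/sum(x^2)` via `lm(y ~ 0 + x)`; the reported R-squared is the
  uncentered form conventional for no-intercept fits, and that basis is
  recorded in report metadata.
* The effort-threshold test is the Pearson chi-square on the 2 x 2 table of
  (effort at or above / below the threshold) x (detected / not), without
  continuity correction. Group comparisons use Welch's t on natural-log
  transformed values.
* The maximum distance moved (MDM) is the largest pairwise Euclidean
  distance among the stations where an individual was detected, computed
  either within calendar years or pooled across them — the two scopes
  mirror survey designs with different temporal reach, and pooled MDM is
  never smaller. Treating MDM as a home-range diameter gives the circular
  proxy area $\pi(\mathrm{MDM}/2)^2$. Coordinates are planar kilometres;
  at study extents of tens of kilometres, projecting before ingest and
  using Euclidean distances is accurate to well under the station spacing.
* Dyads are unordered pairs of individuals in one location-year. The
  interval between a dyad's members is the minimum absolute difference
  between their detections — the conservative, interaction-prone choice,
  measured in whole calendar days for binning (same day; 1-7; 8-14; 15-28;
  over 28) with the exact fractional gap also reported. Pairs more than 28
  days apart (strict) are treated as independent, a threshold taken from
  decay rates of field sign in comparable forest.
* Tenure is last minus first detection year; minimum age adds one year on
  the assumption that first-detected animals are at least one year old.
* p-values are reported without multiple-testing correction, matching
  standard practice for these descriptive survey analyses; reports that
  run many tests should interpret single marginal results cautiously.

# The simulator

`simConfig()` defines an individual-based generator: range centres uniform
on a rectangular extent, sex Bernoulli, log-normal range diameters by sex,
geometric lifespans anchored at a uniform entry year (a stationary
population, matching the stable-environment assumption of long-term
protected-area monitoring), detection as a per-night Bernoulli trial for
every functional station-night whose station lies within half the
individual's range diameter, at most one event per individual-station-night
(matching the downstream independence filter), clock times from a per-sex
two-component von Mises mixture, flanks multinomial, and a small fraction
of events left unidentified.

The defaults emulate a long-term felid by-catch survey: a 20-station 4 x 5
grid at 2 km spacing inside a 10 x 10 km extent, 12 annual 90-day seasons,
male mean range diameter 1.8 km (SD 1.4) and female 0.5 km (SD 0.3) on the
log-normal scale, annual survival 0.8 (mean lifespan 5 years, tenures up to
about a decade), flank probabilities (0.42, 0.42, 0.16) and 7% unidentified
events. Detection within range is uniform (no distance decay) — the
simplest model consistent with treating MDM as a range diameter.

Two calibration choices deserve note. First, the nightly encounter
probability is per-sex (M 0.0017, F 0.021): a constant rate cannot
reproduce a 2:1 male:female detection ratio when male ranges cover about
fifteen times the area of female ranges, and a higher within-range
encounter rate for small intensively used ranges is the natural mechanism.
With two-thirds of individuals male, both detections and detected
individuals then stand near 2:1. Second, density is 1.5 concurrently alive
individuals per square km (within published estimates for small
neotropical felids), set together with the encounter rates so that the
pooled detection rate falls in the sparse 0.4–1.2 events per 100
trap-nights band in over 90% of seeds; the analytic product
(rate = density x encounter x mean range area) overpredicts because range
discs truncate at the extent boundary, so the final values were set against
simulation.

What the simulator does **not** emulate: movement within ranges (detection
is spatially uniform, so spacing-versus-range-size biases in spatial
recaptures are reproduced only coarsely), territoriality or interactions
between individuals, detector failure mid-season (effort is exactly the
schedule), seasonal or between-year variation in behaviour, and
misidentification. Passing tests therefore demonstrate the statistical
machinery under the stated assumptions, not robustness to these field
realities.

# Numerical and degenerate-input conventions

* Likelihood evaluations clamp site probabilities at $10^{-300}$ before
  logging; all-missing histories contribute zero log-likelihood.
* Fit determinism: every stochastic routine takes an explicit seed, and
  the pipeline derives fixed per-stage substreams from one root seed, so a
  configuration reproduces byte-identical reports.
* `detectionRate` requires positive effort; zero-effort cells are reported
  missing rather than zero. Rates print to 2 decimals, areas to 1, as in
  the field's summary tables.
* Von Mises sampling uses the Best–Fisher rejection method; concentration
  estimation uses the standard A1-inverse approximations. Kernel densities
  are computed with exponent-scaled Bessel functions, stable for tight
  clusters.
* Ties in the median-collapse rule resolve to the midpoint of the two
  central times; the collapsed event inherits the remaining fields of the
  group's first event.

# Problem sizes in the test suite

The suite runs the likelihood oracle at up to 4 seasons and 4 sites
(exhaustive enumeration), parameter recovery at 500 sites x 6 seasons x 50
replicates, bootstrap calibration at 80 sites with 30 simulations x 20
replicates, overlap oracles at n = 3000, and pipeline smoke tests on a
4-year simulated survey. These sizes were chosen as the smallest at which
the corresponding statistical property is sharp enough to be a real check.

# Known limitations

* Detection histories pool all individuals; the occupancy layer is
  single-species, single-state, with no covariates or spatial correlation.
* The GOF cohort construction drops sites with partial missingness within
  a season, which loses information when effort gaps are frequent.
* MDM under-estimates range span when stations are sparse relative to
  ranges — which is precisely the effect the effort analyses are designed
  to expose, but it means simulator truth comparisons should use dense
  virtual grids.
* The flank-count bounds assume single-flank identities are never linkable
  across sides; if supplementary evidence links them, counts should be
  corrected upstream.
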