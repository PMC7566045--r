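---
title: "Methods: demographic estimation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic estimation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`demrecon` re-creates, at a size a single machine can test exhaustively,
the estimation chain that modern global demographic accounting uses:
noisy, incomplete, mutually inconsistent observations (vital registration,
censuses, birth and sibling histories) are corrected for their known
biases, synthesised into smooth age-time surfaces with uncertainty, and
reconciled into a single internally consistent population history. This
vignette records the models, their assumptions, the tunable parameters,
and the places where the design was genuinely open and a choice had to be
made.

## Life tables

A `life_table` carries the standard columns on an `age_grid` whose last
interval is open. Two mx-to-qx rules are offered.

* **`constant_hazard`** treats mx as a flat hazard within the interval:
  `qx = 1 − exp(−n·mx)` with the exact exponential ax. This rule has three
  properties the test-suite leans on: a flat hazard µ gives `e0 = 1/µ`
  exactly; `dx/Lx` returns mx to machine precision (idempotence); and the
  open interval closes with `Lx = lx/mx`.
* **`midpoint+infant`** is the classical abridged construction
  `qx = n·mx/(1 + (n − ax)·mx)` with `ax = n/2` from age 5 and
  Coale–Demeny-style linear functions of the infant death rate for the
  infant and 1–4 intervals. The coefficient table
  (`ax_coefficients()`) is configuration, not an assertion: published
  conventions differ at the margins, and on the 23-group grid the
  neonatal splits keep midpoint ax while the post-neonatal interval
  absorbs the infant mean age at death shifted to its own origin.

**Single-year expansion.** Survivorship is interpolated at integer ages by
a monotone piecewise-cubic (Fritsch–Carlson) of log *lx*, which preserves
boundary values and cannot create negative hazards; above the last closed
age the terminal hazard continues as a constant. Because the interpolant
fixes boundary survivorship but not the within-group area, single-year
`Lx` are then rescaled group-by-group to conserve the abridged table's
person-years, so the expansion reproduces the abridged expectancies
(to ~1e-9) rather than merely approximating them. For a constant-hazard
input the rescaling factor is 1 and the single-year rates equal the input
rate.

**Under-5 detail.** The constraint that detailed early-age probabilities
reproduce an externally estimated 5q0 is a single scalar k on the four
hazards `−log(1−q)`. Because the hazards scale jointly the solution is
closed-form, `k = log(1−target)/Σ log(1−q)` — exact rather than iterative,
and order-preserving by construction.

## Fertility

Schedules are the nine 5-year maternal groups 10–54. The terminal groups
are filled as fixed ratios of their neighbours (defaults r10 = 0.03,
r50 = 0.02; the published extrapolation model is not reproducible at this
scale, so the ratios are plain configuration). Net reproduction uses
female life-table person-years, `NRR = (1/(1+SRB))·Σ ASFRₐ·(ₙLₐ/l₀)`, and
replacement TFR is `TFR/NRR`: rescaling a schedule rescales NRR
proportionally, so the ratio is the exact root of NRR = 1 for the given
age shape. Sources reporting only total births enter a second estimation
round as pseudo-rates: the total is split proportionally to first-round
expected births and carries a 4× inflated variance (configurable), so such
sources inform the level but not the age pattern.

## Registration completeness

**GGB** regresses, over a trimmed age range, the entry rate minus the
growth rate of the open-ended population above each age on the registered
death rate above that age. Orthogonal (total-least-squares) regression is
used since both axes carry error. The slope estimates 1/c; the intercept
estimates the census-2:census-1 relative coverage via
`k = exp(−intercept·Δt)` (sign fixed by simulation: inflating census 2 by
10% must return k ≈ 1.1). **SEG** rebuilds the exact-age population from
deaths above each age grown at age-specific intercensal growth rates, with
the open interval seeded by `D(open)·(exp(r·e) − (r·e)²/6)`; the default
`e(open)` is the stationary approximation `N(open)/D(open)`, replaceable
by a reference life-table value. **GGB-SEG** applies the GGB coverage
ratio before SEG. Completeness is the *median* of the age-specific ratios
(robust to single-age distortions). Age trims are selected by minimising
the method's own fit diagnostic — regression residual RMSE for GGB,
dispersion of the age ratios for SEG — with ties (to within 1e-9) going to
the widest trim. Time-series synthesis happens in a scaled-logit space
(completeness capped at 1.5) through the ST-GPR engine, with child
registration completeness available as a covariate; the series used for
death adjustment is capped at 1 while the raw series is retained for
diagnostics.

**Summary birth histories** use the classic Trussell ("West") multipliers
and time-location coefficients; the table is swappable configuration. The
index-age probabilities q(2), q(3), q(5) are mapped to q(5) through a
one-parameter logit level shift of a standard child mortality schedule
(mid-level member of the synthetic standard library by default). The
record format carries a `women` column: mean parities, which the method
needs for its parity ratios, are not recoverable from totals of children
alone. **Sibling histories** weight each sibship by
(sibship size)/(surviving potential respondents) — the Gakidou–King-style
correction for the fact that sibships are observed with probability
proportional to their surviving adult members — and convert weighted
5-year-band rates to 45q15 under piecewise-constant hazards. The estimator
is documented as conditional on at least one survivor: all-dead sibships
are structurally unobservable.

## The ST-GPR engine

All stages run in transform space: logit for probabilities and
completeness, log for rates.

1. **Stage 1** is a precision-weighted linear model of the transformed
   observations on covariates, fit only on *standard locations* so covariate
   effects come from well-measured places, plus nested shrunken location
   intercepts (`n/(n+1)` of the mean residual); a location with no data
   inherits its parent's intercept.
2. **Source bias**: per-source mean residuals against the prior; every
   non-reference source is shifted by (reference RE − its RE), variances
   untouched.
3. **Stage 2** averages residuals into each cell with multiplicative
   weights — time `1 − (|Δt|/(1+Δt_max))^λ`, age `exp(−ω·|Δa|)`, space 1 /
   ζ / ζ² for same location / sibling / other — normalised to sum to one.
   Defaults λ = 0.7, ζ = 0.9, ω = 1.0 are engine configuration, not
   asserted production values.
4. **Stage 3** is a GP per location over time: mean = stage-2 surface,
   squared-exponential kernel (amplitude 0.3 transform units, length scale
   12 years by default), heteroskedastic noise equal to each point's data
   variance. Draws (default 1000) come from the posterior via an
   eigendecomposition square root with one deterministic stream per
   location; the 95% interval is the 25th/975th order statistics at 1000
   draws and nearest-rank quantiles otherwise. Rank-matched draws
   propagate downstream so pipeline uncertainty stays coherent.

The posterior interpolates a datum as its variance → 0, reverts to the
stage-2 mean as variance → ∞, and back-transforming logit-space draws
keeps everything in (0,1) — all asserted in the suite, along with interval
calibration on worlds drawn from the prior itself.

## Model life tables

The standard library is synthetic: 25 Siler-hazard schedules (declining
child component, constant background, senescent exponential) spanning
roughly 5q0 ∈ [0.004, 0.26] and 45q15 ∈ [0.06, 0.53], each passing shape
checks (monotone hazard above 30, strictly decreasing survivorship). It
stands in for an empirical life-table collection with the same interface:
selection takes the k nearest standards in (logit 5q0, logit 45q15) and
pools logit-survivorship with inverse-distance weights.

The relational model is Brass's: `Y(x) = logit(1 − lx/l0)`,
`Y = α + β·Y_std`. Given β, the 5q0 target fixes α in closed form, so the
fit reduces to one-dimensional root finding in β (bracket [0.3, 3],
expanded geometrically if needed; residual tolerance 1e-12), and both
targets are met to better than 1e-8. Old-age extension fits the Kannisto
logistic `µ = A e^{Bx}/(1 + A e^{Bx})` by linear regression of logit(mx)
on interval midpoints over ages 60–89 and evaluates it at 92.5 and 100 for
the 90–94 and 95+ groups — non-decreasing and bounded by 1, and below a
pure Gompertz extrapolation by construction. Shocks are disaggregated
proportionally to (pattern rate × population) and rescaled to conserve
the event total exactly; HIV enters as a plain rate addition with no
competing-risk correction (a documented simplification).

## Population reconstruction

`project_ccmpp()` is a female-dominant annual projection. Internally the
state lives on single-year ages (5-year groups are expanded uniformly,
the open group with a geometric tail), so cohorts advance exactly along
diagonals and a rate-free projection is a pure shift — the 1/5-per-year
fractional-advancement alternative mixes cohorts and cannot satisfy that
identity. Rates are applied uniformly within their 5-year group; half of
each year's net migrants move before exposure, half after. Person-years
are the exact constant-hazard exposure `(P − S)/m` (plus the birth
cohort's half-year exposure), so recorded deaths equal mx × person-years
identically and the ledger closes ΔP = B − D + M to machine precision.

The Bayesian reconstruction (`estimate_baseline_migration()`)
parameterises the baseline as per-age log perturbations of a prior mean
(shared across sexes) and migration as a yearly level path (knots every 5
years, random-walk smoothness penalty) applied to a fixed
Rogers–Castro-like age shape — a deliberately low-dimensional
parameterisation chosen for identifiability from a handful of censuses.
Censuses contribute independent normals on log counts (coverage SD 0.03
by default); registered deaths, when completeness is estimated, contribute
log-normals around c × projected deaths (overdispersion SD 0.1) with a
logit-normal prior on c. Two samplers: a Laplace approximation around the
posterior mode (BFGS on rescaled parameters, eigenvalue-floored Hessian) —
the default, used throughout the tests — and adaptive random-walk
Metropolis with multiple chains and a split-R̂ diagnostic that warns, never
silently passes. Wild proposals that clip projected counts to zero receive
a finite penalty so the samplers can retreat.

## HALE, SDI, expected outcomes

Sullivan HALE is the abridged form `Σ Lₐ(1 − YLDₐ)/lx` with no
within-interval interpolation of the disability weight. The SDI is the
geometric mean of min-max-scaled components — income on the log scale,
schooling linear, under-25 fertility inverted — with the bounds as
configuration chosen to span the synthetic worlds; the geometric mean
makes any component at its worst bound annihilate the index.

The expected-outcome model is an ensemble of 50 cubic splines of the
transformed outcome on SDI. Each member draws three interior knots
uniformly in [0.1, 0.8] under a minimum inter-knot distance of 0.1
(rejection sampling); with the boundary knots at 0 and 1 this gives five
knots whose outermost segments are enforced linear — implemented as a
natural cubic spline on the interior knots, so linearity and slope
matching at the outer interior knots hold by construction and
extrapolation beyond [0,1] is linear (flagged with a warning). Members are
plain least squares with an optional symmetric residual-trimming refit
(default 0% for determinism; 10% mimics trimmed meta-regression);
ensemble weights are uniform. Whether the published "five knots" includes
the boundary knots is ambiguous; this package reads it as 2 boundary + 3
interior. Fitted per age-sex group on log mortality, the ensembles yield
an expected mx schedule, expected e0, and the observed-minus-expected gap.
Expected fertility schedules are raked multiplicatively so their TFR
matches the expected TFR exactly.

## Transition taxonomy

"Sustained decline" is operationalised as the first year beginning ≥ 10
consecutive years each at least 5% (relative) below the running
pre-run maximum — both parameters configurable, since the source notion is
qualitative. The seven labels follow a deterministic cascade on the
history through the classified year: no sustained CDR decline → *before*;
NRI < 0 → *post* (split by the sign of a trailing 5-year mean net
migration rate, exact zero counting as immigration with a flag); both
rates in sustained decline with max-to-date NRI ≥ 3.0%/yr and NRI still at
≥ 80% of its historical peak → *mid*; NRI fallen below 80% of its peak →
*late* (split by migration sign); otherwise *early*. The published rules
leave one cell undefined — growth still rising at its peak while the CBR
has not yet entered sustained decline but the 3% threshold is already met;
mapping it to *early* (transition underway, growth not yet falling) keeps
stage order monotone on canonical trajectories. The 80%-of-peak boundary
between mid and late is a declared operationalisation of "the improvement
in crude death rate has slowed down", which has no quantitative source
definition.

## The synthetic world

`build_world()` scripts each location's history: logistic paths for TFR
(6.5 → 1.8, midpoint 1995), under-5 (0.25 → 0.02) and adult (0.45 → 0.08)
mortality with the mortality decline leading fertility by two decades —
values chosen as a textbook classical transition over 1950–2019 — plus a
±10% deterministic per-location jitter. Mortality paths are realised
through the same relational machinery the estimators use; population comes
from `project_ccmpp()` after a 60-year burn-in under the initial rates, so
worlds open on the stable age structure of their starting regime rather
than ringing with cohort waves from an arbitrary seed structure.
Ground-truth stage labels are the stage definitions applied to the
noise-free rate series; the classifier consistency test recomputes the
rates from pooled event tallies and must agree exactly.

Observation models: registered deaths are binomial thinnings with the
completeness path (exact pass-through when c = 1); censuses multiply truth
by log-normal coverage noise (exact when the SD is 0); surveys simulate
individual mothers (annual fertility Bernoulli draws, one under-5 fate per
child with the death age drawn from the life table's infant/child split)
and sibships (childhood survival, then annual adult hazards with an
optional shared log-normal frailty; respondents sampled with probability
proportional to surviving adult members, reproducing the selection bias
the weighted estimator corrects). Scenario presets perturb one dial each:
an HIV bump, a conflict shock, an incomplete-VR ramp (0.5 → 0.9), an
emigration wave.

What the generator does *not* emulate: age misreporting and heaping,
migration age-structure mismatch with the prior, recall error in survey
dates, correlated census coverage by age, and cause-of-death structure
beyond a single shock pattern. Passing tests therefore demonstrate
correctness of the estimators under their own assumptions plus the
declared noise models — not robustness to every distortion real data
carry.

## Numerical choices and problem sizes

Radix 100 000; day-width intervals use a 365-day year. Root finding
targets 1e-12 residuals; the GP adds 1e-9 jitter and floors eigenvalues at
zero before drawing. The suite's recovery studies use 13 age groups × 20
years with 3 censuses for the Bayesian reconstruction (50 replicates for
the calibration study; the acceptance script reports a 10-replicate
version), 200 replicates for GP calibration, 5 replicate surveys of 2000
mothers for the summary-birth-history check, and a 10-location × 70-year
zero-noise world with 100 draws for the end-to-end check — sizes at which
every study completes quickly on one core while the Monte-Carlo error
stays well inside the asserted tolerances.

## Known limitations

The HIV addition ignores competing risks; the BCCMP migration model fixes
the age shape; stage-1 random effects are moment shrinkage rather than
REML; the SBH conversion ships one multiplier family; the synthetic
standard library spans a 25-point grid, not thousands of empirical
schedules; and the single-year expansion conserves person-years per source
group, so within-group detail is only as good as monotone-cubic
interpolation of log-survivorship.
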