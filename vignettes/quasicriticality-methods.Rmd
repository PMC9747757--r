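---
title: "Quasicriticality methods: the cortical branching model, avalanche exponents, and the position-on-line biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasicriticality methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasicrit)
```

## The scientific problem

Neural population activity propagates in avalanches: bursts of discrete
events bounded by silent periods, characterized by a size $S$ (total
events) and a duration $T$ (time bins).  Near a critical point these obey
power laws, $P(S)\propto S^{-\tau_S}$, $P(T)\propto T^{-\tau_T}$, and
$\langle S\rangle(T)\propto T^{\gamma}$, tied together by the exact scaling
relation $\gamma=(\tau_T-1)/(\tau_S-1)$.  Living networks, however, are
driven by spontaneous activity ($p_s>0$), which concatenates avalanches and
pushes the *effective* exponents $(\tilde\tau_S,\tilde\tau_T)$ down the
**$\gamma$-scaling line** $\tilde\tau_T-1=\gamma(\tilde\tau_S-1)$ rather
than holding them at a fixed critical value.  The quasicriticality
hypothesis states that homeostasis tunes such networks to the *peak of
dynamical susceptibility* for their noise level — the Widom line — and
predicts that where a subject sits on the scaling line is a meaningful,
age-sensitive biomarker.

This package implements the full chain needed to study that prediction:

1. a **cortical branching model (CBM)** simulator that generates
   quasicritical dynamics with controllable structural bias,
2. **event extraction** from continuous multichannel recordings,
3. **avalanche statistics** and effective-exponent estimation,
4. the cohort-level **scaling line** and **position-on-line** biomarker,
5. **activity statistics** ($\chi$, LTF, var($S$), branching ratios), and
6. a **synthetic cohort generator** plus an end-to-end pipeline, so every
   claim is testable without access to human recordings.

## The cortical branching model

The CBM is a probabilistic cellular automaton on a random directed network
of $N$ nodes (default 256), each with exactly $k_{in}$ inbound connections
(default 5).  Inbound connections of node $j$ are ranked
$n_{ij}=1,\dots,k_{in}$ and carry transmission probabilities from the
exponential weighting function

$$p_n = \frac{e^{-Bn}}{\sum_{m=1}^{k_{in}} e^{-Bm}},$$

so each node's inbound probabilities sum to one.  The bias $B\ge 0$
controls skew: $B=0$ is homogeneous; large $B$ gives few strong and many
weak connections, the structural signature of aging connectivity (fiber
density studies show weight distributions steepening with age).  The
branching parameter $\kappa$ scales every probability,
$P_{ij}=\kappa\,p_{n_{ij}}$; with $p_s=0$ the critical point sits at
$\kappa=1$, where $\kappa$ equals the branching ratio $\sigma$.

Dynamics are synchronous.  A quiescent node activates at $t{+}1$ if an
active in-neighbour's edge transmits (uniform draw $\le P_{ij}$) or by
spontaneous activation (draw $\le p_s$, default $10^{-3}$); after firing
for one step a node is refractory for $\tau_r$ steps (default 1) during
which it cannot activate at all.  Two normalization readings are possible
for the weighting function (outbound sums versus inbound sums); the
package normalizes **inbound** weights to one, because the ranks
$n=1..k_{in}$ over which the weighting function is defined are inbound
ranks.  "Fully connected" is interpreted as connectivity of the underlying
undirected graph; wirings violating it are resampled (at most 1000
attempts — with the default geometry virtually the first draw succeeds).

Numerical choices: the automaton starts all-quiescent and discards a
burn-in of $10^3$ steps before recording; one seeded RNG drives wiring and
dynamics, with transmission draws consumed in ascending source-node order
and spontaneous draws in ascending node order, so a configuration plus seed
reproduces a run bit for bit.  Activity is summarized by the per-step
active count; the full binary raster is retained only on request, since all
downstream statistics (avalanches, $\chi$, branching ratios) are functions
of the count series.

In the noise-free subcritical regime the model must reduce to a
Galton–Watson branching process with mean offspring $\kappa$ and mean
avalanche size $1/(1-\kappa)$; `seeded_avalanches()` exposes exactly this
mode and the test suite holds the simulator to the closed form within 5%.

## Susceptibility and the quasicritical region

The activity density $\rho_1(t)$ (fraction of nodes active) yields the
dynamical susceptibility

$$\chi = N\left[\langle\rho_1^2\rangle_T-\langle\rho_1\rangle_T^2\right],$$

the node count times the *population* temporal variance (the angle-bracket
notation denotes plain time averages, so no $n-1$ correction is applied).
`kappa_sweep()` locates the susceptibility peak on a $\kappa$ grid; at
$p_s=10^{-3}$ the peak sits near $\kappa\approx1.07$ for $B=1.8$ and
$\kappa\approx1.12$ for $B=0.6$, with larger bias giving a higher peak —
steeper weight distributions make the network both more excitable and more
variable.  Susceptibility estimates converge per run on the order of
$10^6$ steps but retain substantial network-to-network spread (SD
$\approx0.15$ at the $B=1.8$ peak), so peak locations and table-level
values are always reported as means over independent runs.

The local time fluctuation
$\mathrm{LTF}=\sqrt{\chi/N}\,/\,\langle\rho_1\rangle_T$ is a coefficient of
variation of the firing-rate density: above 1 the activity is bursting,
below 1 regular.  By construction
$\mathrm{LTF}^2\langle\rho_1\rangle^2N=\chi$ exactly, an identity the test
suite checks to $10^{-10}$ on every analyzed subject.

## Event extraction from continuous recordings

Continuous channels are z-scored (constant channels are a hard error naming
the channel; non-finite samples are rejected at load), and events are
detected as threshold excursions: each maximal run of samples with
$|z|>\theta$ yields exactly **one** event at the sample of maximum absolute
amplitude, earliest sample on ties.  One event per excursion prevents a
sustained deflection from being counted as many events.  The default
$\theta=3$ SD is the conventional optimum for separating neural events from
sensor background; it is exposed as a parameter.  Both polarities are
treated symmetrically, so the event count is invariant under a global sign
flip.

Events are binned into a channels-by-bins raster.  The bin width is not a
physical constant of the method; the default is the rounded mean
inter-event interval of the pooled (all-channel) event train — the standard
choice that adapts the avalanche time scale to the array-wide event rate —
and the width used is recorded on the raster and in all derived metrics.

## Avalanche statistics and exponent estimation

An avalanche is a maximal run of consecutive non-empty bins; $S$ sums all
events in the run, $T$ counts its bins.  Runs touching either end of the
recording are discarded (their true extent is unknown), which keeps
durations unbiased at the cost of a few events.

Exponent estimation needs care because driven ($p_s>0$) systems are *not*
pure power laws: beyond the scale-invariant region the size and duration
distributions carry a bump of system-spanning events (this is why
avalanche-size variances reach $10^{8}$–$10^{9}$ at the susceptibility
peak).  Two estimators are provided:

* **Discrete maximum likelihood** with Kolmogorov–Smirnov selection of
  $x_{min}$ (Clauset-style), with the Hurwitz-zeta normalization evaluated
  by truncated sums plus an Euler–Maclaurin tail.  Standard errors come
  from a nonparametric bootstrap of the tail (200 resamples by default) or
  from observed Fisher information.  This is the estimator of choice for
  clean power-law tails, and the generator–estimator round trip in the test
  suite requires it to recover a known exponent of 1.6 within $\pm0.03$ at
  $n=10^5$.

* **Windowed log-binned least squares** (`method = "lsq"`), the default for
  avalanche catalogs (`fit_exponents()`): log density against log bin
  centre over logarithmically spaced bins, restricted to the
  scale-invariant window.  The window ends where the smoothed local
  log-log slope (3-bin regressions) flattens above $-0.6$ — the onset of
  the supercritical bump — with at least 8 populated bins always retained;
  a pure power law triggers no flattening and uses the whole range.  When
  no lower cutoff is fixed, a small set of cutoffs (1, 2, 3, 5) is scanned
  and the fit with the smallest residual SD wins — the least-squares
  analog of the KS-based $x_{min}$ selection, needed because duration
  distributions depart from the power law at their first values.  The
  cohort pipeline instead fixes the cutoff at 1 for every subject
  (`analysis_params(fit_xmin = 1)`): exponent *pairs* feeding the scaling
  line must be methodologically comparable across subjects, and a
  per-subject adaptive cutoff injects between-subject estimator variance
  that dilutes the position biomarker.  On
  quasicritical catalogs the KS criterion otherwise locks $x_{min}$ onto
  the bump (fitting the bump itself, with exponents near 4) and plain MLE
  from $x_{min}=1$ is dragged below the scaling-region slope by the bump
  mass; the windowed estimator reproduces the scaling-region exponents
  stably.  This choice of default for catalogs is the package's own
  judgement call; both estimators remain available everywhere.

$\gamma$ is fitted by ordinary least squares of
$\log_{10}\langle S\rangle(T)$ on $\log_{10}T$ over durations with at
least 10 avalanches (stabilizing the tail of the conditional mean), with at
least 5 qualifying durations required.  The scaling fraction
$(\tilde\tau_T-1)/(\tilde\tau_S-1)$ carries a first-order propagated
error, and the distance to criticality coefficient is
$DCC=|(\tilde\tau_T-1)/(\tilde\tau_S-1)-\gamma_{fit}|$.

## Branching-ratio estimators

The **naive** estimator is the classical one: the mean over avalanches of
the ratio of second-bin to first-bin event counts, with single-bin
avalanches contributing a ratio of zero.  Including the extinctions is what
keeps the estimator unbiased for a branching process with mean offspring
$\kappa$ — conditioning on survival would inflate it to
$E[X\,|\,X\ge1]>\kappa$ — and the test suite pins it to seeded subcritical
avalanches within 5%.  The naive ratio is known to be biased downward under
spatial subsampling (fewer observed channels than sources).

The **multistep-regression** estimator fits the lag structure instead: for
lags $k=1..k_{max}$ (default 40) the regression slope $r_k$ of $a(t{+}k)$
on $a(t)$ follows $r_k=A\,m^k$ for a stationary branching process with
drive, and subsampling is absorbed into the amplitude $A$ while $m$ stays
consistent.  The package fits $A, m$ by least squares in linear space,
initialized from a log-space fit (a pure log fit is biased low where $r_k$
is small and noisy).  The estimator is invariant under positive scaling of
the series, so per-bin counts and densities give the same $m$.  The
activity series fed to it is the per-bin total event count.

## The scaling line and the position biomarker

Cohort exponent pairs are fitted with ordinary least squares of
$\tilde\tau_T$ on $\tilde\tau_S$ (subjects whose fits failed are excluded
beforehand, with the reason logged).  The position biomarker then: (1)
shifts all points vertically by the line's intercept so the line passes
through the origin, (2) scalar-projects each shifted vector onto the unit
vector along the line, and (3) rescales by the cohort maximum, so positions
lie in $[0,1]$ with the maximum exactly 1.  Scalar projection and
orthogonal-foot distance give the same ordering, so only the former is
implemented.  Because step (3) is cohort-relative, **positions are
comparable only within a jointly normalized cohort** — this is documented
on the function and is the main caveat for using the biomarker across
studies.

## The synthetic cohort generator

The generator stands in for a human resting-state MEG cohort and encodes
the package's model of aging: a subject of age $a$ receives bias $B(a)$
linearly interpolated between 0.6 at the youngest age (18) and 1.8 at the
oldest (88) — the two biases whose simulations bracket the aging trend;
the aging-connectivity literature motivates monotonicity but no functional
form, so the linear map is the simplest defensible choice.  Each subject's
$\kappa$ is pinned to the susceptibility peak for their bias
(`kappa_for_bias()`, linear between the swept anchors $\kappa^*(0.6)=1.12$
and $\kappa^*(1.8)=1.07$), expressing quasicritical homeostasis; a fixed
global $\kappa$ can be requested instead.

The sensor model is minimal but its parameters are load-bearing, because a
naive observation chain *inverts* the trends it is supposed to carry.  Four
choices matter:

* **Model clock.** One CBM step lasts `samples_per_step` samples (default
  5, i.e. a 5 ms propagation tick at 1 kHz, the time scale of avalanche
  binning in sensor-array studies).  Mapping one step to one sample makes
  channel traces implausibly dense.
* **Fractional observability.** Each node event registers on a listening
  channel only with probability `p_observe` (default 0.2): sensor arrays
  observe a vanishing fraction of their source units, and this subsampling
  is what makes sensor-level event trains sparse even though the generative
  network at its susceptibility peak is dense.
* **Timing jitter.** A registered event lands uniformly within its step
  window, de-aliasing event times from the model clock; without it the
  pooled inter-event interval (and hence the automatic bin width) beats
  against the step length.
* **Noise-dominated variance.** Events have unit peak amplitude (convolved
  with the narrow kernel 0.15, 1, 0.15) and ride on Gaussian noise of SD
  `noise_sd` (default 0.15).  Because z-scoring normalizes by the *total*
  SD, the detection threshold must be set by the noise floor, not by the
  event rate: with noise-dominated variance the 3-SD threshold is the same
  for every subject and detection is unbiased across ages, while unit
  events still clear it comfortably.  With event-dominated variance
  (low noise, dense events), high-activity subjects get higher absolute
  thresholds, lose more events, and the measured age trends flip sign —
  the failure mode that fixed these defaults.

With identity mixing, full observation (`p_observe = 1`) and near-zero
noise, 3-SD thresholding recovers over 95% of ground-truth events, which
the test suite checks.  What the generator does **not** emulate: MEG
forward fields and sensor geometry, 1/f background spectra, physiological
artifacts, head movement — so passing cohort tests demonstrates that the
*pipeline* recovers the built-in structure, not that real MEG data will be
as clean.  Ages are drawn uniformly over the range; gender labels are
balanced and, by construction, carry no effect, so the gender contrast of
the pipeline acts as a negative control on synthetic cohorts.

## The end-to-end pipeline

`analyze_subject()` chains z-score, detection, binning, extraction, fits
and activity metrics, flagging subjects as excluded (with the reason) when
any fit fails.  `analyze_synthetic_cohort()` streams subjects one at a time
(a full 520 s, 102-channel cohort never needs to sit in memory), fits the
scaling line, computes positions, and produces the statistics table:
two-sided Pearson correlations for the variable pairs of interest (age
versus position, $\chi$, rate, LTF, $\log_{10}$var($S$), both branching
ratios; position versus $\chi$; $\chi$ versus $\log_{10}$var($S$)) and a
Welch two-tailed t-test of position by gender label.  Variance of avalanche
sizes enters correlations on the $\log_{10}$ scale.  No multiple-testing
correction is applied, matching the descriptive use of the table.

The expected signature of the aging model on a synthetic cohort is: age
(hence bias) up $\Rightarrow$ exponents down the line $\Rightarrow$
position down, susceptibility up — so $r(\text{age},\text{position})<0$,
$r(\text{age},\chi)>0$, $r(\text{position},\chi)<0$.

## Problem sizes and tolerances used in validation

The table-level reproduction runs 3-5 independent simulations of
$2\times10^6$ recorded steps per $(B,\kappa)$ cell (several thousand
avalanches per run, an order of magnitude above what the exponent fits need
to stabilize) and reports means; with these sizes the run-to-run SDs are
roughly 0.15 for $\chi$ at the $B=1.8$ peak, 0.01 for $\chi$ at the
$B=0.6$ peak, and about 0.04 for the exponents.  Cohort-level validation
uses 40 subjects at a reduced recording length of 60 s, which keeps a full
ten-cohort replication affordable while each subject still yields thousands
of avalanches.  Susceptibility-peak location uses grids of step 0.01 with
two to four repetitions per point (the high-bias peak is sharp, the
low-bias peak flatter and thus averaged harder).  The Galton-Watson
cross-check scales the network with the expected avalanche size
(up to 4096 nodes at \(\kappa=0.9\)), since the closed form assumes
refractory collisions are rare.  These sizes are the package's validation
choices and are all configurable.

## Known limitations

* Positions are cohort-relative; cross-cohort comparisons require joint
  normalization.
* The windowed least-squares estimator depends on a well-populated log-binned
  density; catalogs with under a few hundred avalanches fall back to noisy
  windows, and such subjects should be (and are) excluded by fit failure.
* The age-to-bias map and the sensor model are modeling choices, not fitted
  to data; only the *signs* of cohort-level trends, not their magnitudes,
  transfer to real recordings.
* The CBM is excitatory-only with fixed unit delays; inhibition, rich-club
  structure, and biophysical detail are out of scope.
* Increasing the spontaneous rate blunts the susceptibility peak sharply,
  but a systematic shift of the peak *location* toward lower branching
  parameters is not resolvable in this automaton at N = 256 — the peak
  flattens faster than it moves, so the package tests the blunting and
  makes no claim about the shift.
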