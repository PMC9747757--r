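# quasicrit

Neuronal avalanches, effective exponents and quasicriticality biomarkers
for multichannel neural recordings.

## What this package is for

Cortical networks produce avalanches of activity whose size and duration
distributions are approximately power laws, `P(S) ∝ S^(−τ̃_S)`,
`P(T) ∝ T^(−τ̃_T)`, with `⟨S⟩(T) ∝ T^γ`.  At a critical point the
exponents satisfy the exact scaling relation `γ = (τ_T − 1)/(τ_S − 1)`;
driven, noisy networks instead slide *along* the γ-scaling line
`τ̃_T − 1 = γ(τ̃_S − 1)` as spontaneous activity concatenates avalanches.
The quasicriticality hypothesis holds that living networks sit near the
peak of dynamical susceptibility `χ = N[⟨ρ₁²⟩ − ⟨ρ₁⟩²]` for their noise
level, and that a subject's normalized *position on the scaling line* is a
biomarker that tracks structural change — notably aging, modeled as an
increasingly skewed connection-weight distribution.

The package provides, as composable pieces:

- **`cbm_config()` / `simulate_cbm()` / `kappa_sweep()`** — a fast
  probabilistic cellular-automaton simulator of the cortical branching
  model: N nodes (default 256), k_in inbound edges each (default 5) with
  exponentially biased weights `p_n ∝ e^(−Bn)`, branching parameter κ,
  spontaneous activation p_s, refractory period τ_r.
- **`zscore_recording()` / `detect_events()` / `bin_events()`** —
  continuous multichannel signals to a binary event raster (3-SD excursion
  detection, one event per excursion at the absolute extremum).
- **`extract_avalanches()` / `fit_power_law()` / `fit_gamma()` /
  `fit_exponents()`** — avalanche catalogs and effective-exponent
  estimation (discrete MLE with KS cutoff selection, and a windowed
  log-binned least-squares estimator for driven-system catalogs), the
  scaling fraction and the distance-to-criticality coefficient.
- **`fit_scaling_line()` / `position_on_line()`** — the cohort γ-scaling
  line and the normalized position biomarker.
- **`susceptibility()` / `ltf()` / `avalanche_size_variance()` /
  `branching_naive()` / `branching_mr()`** — activity statistics and both
  branching-ratio estimators.
- **`cohort_config()` / `generate_cohort()` /
  `analyze_synthetic_cohort()`** — an age-labeled synthetic MEG-like
  cohort generator (age → weight bias → CBM → sensor mixing + noise) and
  the end-to-end pipeline with cohort statistics.

## Worked example

Simulate the branching model near its susceptibility peak, extract
avalanches, and fit the effective exponents:

```r
library(quasicrit)

cfg <- cbm_config(n_nodes = 256, k_in = 5, kappa = 1.07, p_s = 1e-3,
                  bias = 1.8, n_steps = 5e5, seed = 11)
sim <- simulate_cbm(cfg)
catalog <- extract_avalanches(sim)
pair <- fit_exponents(catalog)          # windowed least-squares estimator
pair
#> effective exponents: tau_S 1.509 +/- 0.030, tau_T 1.652 +/- 0.056
#>   fraction (tau_T-1)/(tau_S-1) = 1.281 +/- 0.135, gamma = 1.433, DCC = 0.152
susceptibility(activity_series(sim))
#> [1] 1.106961
```

τ̃_S ≈ 1.51 and τ̃_T ≈ 1.65 are the slopes of the avalanche size and
duration distributions over their scale-invariant window; the fraction
(τ̃_T−1)/(τ̃_S−1) ≈ 1.28 against the independently fitted γ ≈ 1.43 gives a
distance-to-criticality coefficient of 0.15 — close to, but not exactly
at, criticality, as expected for a driven network near its susceptibility
peak (χ ≈ 1.1 in this run; means over independent runs settle near the
reference value 0.9, with substantial network-to-network spread).

A small synthetic cohort end to end:

```r
cohort <- cohort_config(n_subjects = 12, duration_s = 60, seed = 42)
res <- analyze_synthetic_cohort(cohort, analysis_params(n_boot = 0))
res$line
#> gamma-scaling line: slope 1.318 +/- 0.781, intercept -0.337 (n = 12)
subset(res$statistics, var2 %in% c("position", "chi"))[1:3, ]
#>       test     var1     var2   estimate      p_value  n
#>  pearson_r      age position -0.6881052 1.337050e-02 12
#>  pearson_r      age      chi  0.9812051 1.789754e-08 12
#>  pearson_r position      chi -0.7668048 3.615402e-03 12
```

Older synthetic subjects (larger weight bias) have smaller exponents —
lower position on the line — and higher susceptibility, the signature the
biomarker is designed to detect.

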