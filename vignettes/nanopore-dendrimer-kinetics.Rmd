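---
title: "Models and methods: nanopore blockade kinetics, energetics and transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: nanopore blockade kinetics, energetics and transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porekin)
```

# The measurement being modelled

A single α-hemolysin (α-HL) pore in a lipid bilayer conducts ~100 pA at
+100 mV in 1 M KCl. When a polycationic analyte — here a generation-1
PAMAM dendrimer added on the *trans* side — is reversibly captured by the
pore, the current drops to a blocked level and recovers when the analyte
leaves. The recording is therefore a two-state telegraph signal hidden in
amplifier noise and shaped by the acquisition low-pass filter. Three
observables carry the physics: the inter-event time τ_on (capture), the
blockade duration τ_off (residence), and the blockade amplitude
ΔI_block = I_blocked − I_o.

`porekin` treats this system as a continuous-time two-state renewal
process: open lifetimes ~ Exp(rate_on), blocked lifetimes ~ Exp(rate_off).
All downstream estimators assume exactly this model, which is why the
synthetic generator — not a convenience fixture, but the package's
ground-truth instrument — simulates precisely it.

# The synthetic trace generator

`simulate_trace()` draws the alternating state sequence in continuous
time, samples it onto a uniform grid (default 80 kHz), adds i.i.d.
Gaussian noise per sample, and optionally applies the low-pass filter.
Ground-truth state intervals are stored on the trace.

Defaults and their rationale:

* **Open current**: linear conductance `I_o = G·ΔV` with G = 1 nS per
  mol/L KCl, so I_o ≈ 100 pA at +100 mV in 1 M KCl — the open-pore
  conductance of α-HL under these buffers. Blocked levels are set via the
  per-condition blockade fraction (0.39 at pH 3/1 M, 0.50 at pH 7/1 M,
  0.43 at pH 7/0.5 M; see `reference_conditions()`).
* **Noise**: 1.5 pA RMS before filtering. The source study does not report
  its noise amplitude; 1–2 pA RMS is typical of an Axopatch-class
  amplifier at 10 kHz bandwidth, and 1.5 pA was fixed once as the
  package-wide fixture value. It is a free parameter of `sim_params()`.
* **Sampling/filtering**: 80 kHz sampling, 10 kHz low-pass, matching the
  emulated acquisition chain.
* **Units** are fixed package-wide: pA, mV, s, K, mol/L; energies are
  reported in both k_B·T and kcal/mol.

What the generator deliberately does *not* emulate: multi-level
sub-states, 1/f and excess noise, baseline drift, and voltage-step
protocols. Passing parameter-recovery tests therefore demonstrates
estimator correctness under the renewal model, not robustness to every
pathology of real recordings; for real data the event tables and QC plots
(`all_points_histogram()`, `plot_dwell_histogram()`) are the place to
check the model's adequacy.

## The filter

The acquisition filter is implemented as a zero-phase Gaussian FIR
(`apply_lowpass()`), the standard software filter for single-channel
analysis: unit DC gain, no overshoot, 10–90% rise time T_r = 0.3396/f_c
(≈34 µs at 10 kHz). A 4-pole Bessel is the common hardware analogue; the
Gaussian was chosen because it is numerically exact to implement, has the
same "rise time × bandwidth" phenomenology, and makes the censoring
analysis below clean. Rise-time calibrations in the tests use the Gaussian
value. Kernel support is ±4σ with replicate-padded edges, so output length
equals input length and long plateaus are preserved to better than 1%.

# Event detection and censoring

`detect_levels()` takes the two most prominent, well-separated modes of
the all-points histogram and refines each as a count-weighted local mean —
a mode must hold at least a small fraction (default 2×10⁻⁵) of all
samples, low enough that a pore blocked only ~0.3% of the time still
yields its blocked level.

`detect_events()` uses hysteresis thresholding: an event opens when the
current crosses 75% of the open→blocked gap and closes when it recovers
past 75% of the blocked→open transition (i.e. the 25% residual-depth
line). Because both transitions trigger at the same fractional progress,
the entry and exit delays cancel and dwell durations of events longer than
the filter rise time are unbiased; the 25%/75% pair is far enough from
both levels to be robust at the noise levels considered (the detector
refuses level pairs closer than 4× the estimated noise SD).

Events shorter than `min_duration_s` — default 2·T_r ≈ 68 µs at 10 kHz —
are discarded and the cutoff is recorded as the **censoring floor**. Two
consequences propagate downstream:

1. Kept dwells are left-truncated at the floor. By memorylessness the MLE
   is the shifted estimator `rate_off = n / Σ(t_i − floor)`, exact under
   the model.
2. Missed events merge the two open gaps around them, so detected captures
   are a thinned renewal process. The capture rate is corrected by the
   detection probability `p = exp(−rate_off·floor)` estimated from the
   fitted escape rate. At the fastest study condition
   (rate_off ≈ 4.4×10³ s⁻¹) about a quarter of events fall below the
   floor, so this correction is essential for unbiased k_on; it is the
   package's analogue of the specialised short-event analyses used in the
   experimental literature, and can be disabled
   (`correct_missed = FALSE`) for diagnostics.

τ_on is defined as the gap preceding each event after the first (renewal
convention; the partial gap at the trace start is discarded). ΔI_block is
stored signed and reported as a magnitude; in-event means are trimmed by
one rise time per edge so filter transients do not dilute the amplitude.

# Rate estimation and bimolecular kinetics

`fit_exponential_rate()` offers two paths. The **MLE path** is the
estimator of record: rate = n/Σ(t−floor) with a gamma-based confidence
interval from the exact distribution of the duration sum. The
**histogram path** — exponential decay fitted to binned counts — mirrors
the display-style analysis traditionally applied to dwell histograms; it
is retained for QC and agrees with the MLE within ~10% on clean samples of
n ≥ 200, but the MLE is better behaved at small n and under censoring,
which is why it is the default. Binning (linear, count-weighted log-space
fit) is configurable since the traditional analyses rarely state theirs.

`fit_bimolecular()` converts a concentration series into constants via the
bimolecular model: k_on is the slope of a weighted least-squares line
**through the origin** (the model's proportionality rate_on = k_on·[C] —
a free-intercept variant exists behind a flag for diagnosing deviations),
and k_off is the weighted mean of the escape rates. Fits whose slope SE
exceeds 50% of the slope are flagged rather than refused.

# Capture energetics

Capture is barrier-limited: τ_on = a·exp(−ΔV/b), equivalently
rate_on = r₀·exp(z_eff·e·ΔV/k_B·T). `fit_kramers_rate()` fits the log-rate
by weighted linear regression — weights from the rates' relative standard
errors, matching the multiplicative error structure — and reports z_eff
(slope × thermal voltage; 25.4 mV at 295 K) and r₀ (exponentiated
intercept). The Kramers prefactor A and barrier height U\* enter only
through r₀ = A·exp(−U\*/k_B·T) and are **not separately identifiable**, so
the API never reports them alone; what is identifiable across conditions
sharing A (same analyte concentration and bulk diffusivity) is the barrier
difference ΔU\* = k_B·T·ln(r₀^A/r₀^B), reported in kcal/mol and k_B·T.

`fit_arrhenius_tau()` fits the time-form by nonlinear least squares seeded
from the log-linear fit; on noiseless data nls cannot iterate from an
exact start, and the log-linear estimates (identical in that case) are
returned with delta-method errors. Temperatures are explicit arguments
everywhere — 295 K where the energetics and selectivity are evaluated,
300 K as the default for the screening-length helpers — never constants
buried in formulas.

Because the per-voltage dwell values behind the study's voltage-series
figures are not tabulated anywhere, the energetics stage is validated by
parameter recovery: rates generated from the published (z_eff, r₀) pairs,
perturbed with the exact sampling distribution of an n-event exponential
estimate (`simulate_voltage_rates()`, rate·n/Γ(n,1)), must be recovered
within two standard errors.

# Transport: charge, screening and first passage

**Net charge.** The dendrimer's charge vs pH is a sum of
Henderson–Hasselbalch protonated fractions over its 8 primary and 6
tertiary amines. Published structural diagrams give the net charges
(+12 at pH 3, +8 at pH 7, ≈0 at pH 10.3) but not numeric pKa values, so
the default table (primary 9.0; outer tertiary 6.0; core tertiary 1.5) is
a **calibration to those printed charges**, squarely inside the generic
pKa ranges of PAMAM amines, and fully overridable via `charge_model()`.

**Screening.** `debye_length()` and `bjerrum_length()` implement the
standard electrolyte formulas (κ⁻¹ ≈ 0.30 nm at 1 M KCl, 0.43 nm at
0.5 M; l_B ≈ 0.71 nm at 300 K, ε_r = 78). Note the 0.5 M value: the
correct formula gives 4.3 Å, which one-digit literature quotes round to
"≈4 Å" — the package reports the formula value, not the rounding.

**First passage.** Residence times are modelled as the mean first-passage
time of a drift–diffusing particle on [0, L] with a *reflecting* entry and
*absorbing* exit:

τ(v, D, L) = L/v − (D/v²)(1 − e^(−vL/D)),

evaluated by a series below |vL/D| < 10⁻⁴ so the diffusive limit L²/2D is
reached stably. This boundary choice is a declared model variant (labelled
`"reflecting-absorbing"` on results): the original formalism for this
system lives in unavailable supplementary material, so the variant was
anchored instead to its limiting forms (L²/2D diffusive, L/v ballistic)
and cross-checked against an independent Euler–Maruyama Monte-Carlo
first-passage simulation (with the standard 0.5826·σ·√dt boundary-shift
continuity correction) to within 2%. An inverse-Gaussian two-absorbing
variant could be swapped in behind the same label.

The drift velocity combines the Einstein mobility response to the
electrophoretic force with an opposing electro-osmotic slip:
v = (D/k_B·T)·(z_eff·e·ΔV/l_p) − v_eo. Since no microscopic water-flux
model is provided by the source analysis, **v_eo is an explicit
per-condition scalar** (default 0), not a derived quantity.

`estimate_diffusion()` inverts τ(ΔV) for D. With v_eo = 0 the model is
τ = (L²/D)·g(z_eff·e·ΔV/k_B·T) with g independent of D, so the
least-squares solution is closed-form and the inversion is exact on
noiseless forward-generated data; otherwise each voltage is solved by
bisection and the fit refined numerically. The result is reported as a
*lower-limit* estimate — wall friction and position-dependent mobility are
not modelled — and the published diffusion coefficients
(3.04/1.78/1.12×10⁻⁸ cm²/s) are used strictly as fixture ground truth for
recovery tests, never re-derived from figure data. Pore geometry defaults
(`pore_model()`): length 10 nm (the full α-HL channel), β-barrel 2.0 nm,
constriction 1.5 nm, dendrimer 1.8 nm.

# Ion selectivity

`pitzer_activity()` implements the 1:1-electrolyte Pitzer model with the
standard KCl coefficients (β₀ = 0.04835, β₁ = 0.2122, C^φ = −0.00084,
A_φ = 0.392 at 25 °C, b = 1.2, α = 2.0), valid to 6 mol/kg. Molality and
molarity are treated interchangeably for KCl ≤ 3 M, a ~2% density-level
approximation that matches how these activities are conventionally fed
into the GHK analysis. A_φ is the 25 °C value and is not re-derived from
the temperature arguments elsewhere.

`reversal_potential()` finds the zero-current crossing of an I–V table by
bracketing interpolation (or a linear-fit root), with the sign convention
"applied *trans* potential, *cis* grounded". `ghk_permeability_ratio()`
evaluates the bi-ionic Goldman–Hodgkin–Katz expression exactly as
conventionally printed; outside the Nernst window it raises a domain
error, and the degenerate symmetric case (zero potential, equal activities
on both sides, a 0/0 of the formula) returns 1 by the non-selective
convention. Its inverse (`ghk_reversal_potential()`) root-finds within the
Nernst window; the pair is mutually inverse to 10⁻⁹ relative tolerance.
Because the measured reversal potentials behind the published selectivity
ratios (0.453 at pH 3, 0.703 at pH 7 under 0.1 M cis / 3 M trans) are not
printed, those anchors are validated by round trip, not from raw I–V data.

# Validation strategy and problem sizes

Every stage is tested against an independent oracle: closed forms against
brute-force or Monte-Carlo computations, estimators against numerical
likelihood maximization, and the full trace pipeline against the
generator's ground truth. The parameter-recovery checks simulate 60 s of
80 kHz trace per concentration over 4–6 concentrations and 10 seeds for
the bimolecular constants (tolerance 10% on the medians), 10 voltage-series
seeds for the energetics (2 SE), and ≥300-event traces for the blockade
fraction (±0.01). These sizes were chosen to put the Monte-Carlo error of
each check comfortably inside its tolerance while keeping a full test run
in minutes on one core; `scripts/acceptance.R` re-runs the same recoveries
from scratch under a user-supplied seed.

# Known limitations

* Single two-level channel only: no hidden-Markov idealization, no
  multi-level sub-states, no baseline-drift correction, no multi-channel
  records.
* The first-passage boundary conditions are a declared stand-in (see
  above); absolute barrier heights and voltage-dependent z_eff are out of
  scope by design.
* The excluded-volume blockade formula is an order-of-magnitude
  proportionality; for non-cylindrical pores the blockade depends on
  analyte position and charge.
* Selectivity is restricted to the K⁺/Cl⁻ pair; junction-potential
  corrections for salt bridges are not applied.
* Trace ingestion is CSV (`time_s`, `current_pA`); proprietary
  acquisition formats are not read.
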