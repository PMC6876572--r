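---
title: "Occupancy-gated pointed-end depolymerization: models, estimators, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy-gated pointed-end depolymerization: models, estimators, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdep)
```

## The model

`capdep` implements the kinetic analysis of a processive actin
depolymerase — hexameric cyclase-associated protein (CAP/Srv2) — acting at
the pointed ends of cofilin-decorated actin filaments. The core model is a
two-state Markov switch for the filament end:

* **unbound → bound** at rate $k_{on} c$ (pseudo-first-order binding at
  free hexamer concentration $c$, molar);
* **bound → unbound** at rate $k_{off}$ (per second);
* while bound *and productive* (probability $\phi$ per event), subunits
  leave the end at $v_\mathrm{bound}$ subunits/s; otherwise at
  $v_\mathrm{unbound}$.

All arguments are in molar and seconds internally; nanomolar appears only
in display and interface tables. The equilibrium occupancy is
$cK_A/(1+cK_A)$ with $K_A = k_{on}/k_{off}$, and the ergodic mean velocity
is the occupancy-weighted mixture implemented in
`predicted_mean_velocity()`. That closed form doubles as the oracle the
stochastic simulator is tested against.

Two independent routes to the same physics are deliberately carried side
by side and never reconciled numerically: the **single-molecule** route
($k_{on}$, $k_{off}$, occupancy) and the **bulk saturation** route ($K_M$,
$k_{cat}$). The model-implied half-saturation $k_{off}/k_{on} \approx 41$
nM differs somewhat from a typical fitted $K_M \approx 50$ nM; both are
legitimate measurements with their own uncertainties, so the package
reports each from its own data and compares them only in the
occupancy-versus-velocity table. Similarly, the headline fold-change of
synergistic over spontaneous depolymerization is always computed from
unrounded inputs and never asserted against a round number.

## Assumptions worth knowing

* Exponential dwell and gap durations (memoryless kinetics, one binding
  site per end).
* Subunit removal while bound is a Poisson process at rate
  $v_\mathrm{bound}$. The microscopic removal statistics (monomers versus
  short oligomers) are unresolved experimentally; a Poisson monomer stream
  is the simplest model consistent with ~100 subunits removed per
  multi-second binding event, and the simulator removes monomer
  equivalents only.
* Binding events are independently "productive" with probability $\phi$
  (default 1). The parameter exists because a fraction of observed binding
  events is not accompanied by rapid depolymerization; that fraction has
  not been quantified, so $\phi$ is exposed rather than fixed.
* No severing, annealing or re-polymerization; filaments only shrink.

## Tunable parameters

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `k_on` | 1.1e7 | /M/s | measured association rate constant |
| `k_off` | 0.45 | /s | 1 / (2.2 s mean dwell) |
| `v_bound` | 53 | subunits/s | saturating velocity ($k_{cat}$) |
| `v_unbound` | 0.43 | subunits/s | cofilin-alone pointed-end rate |
| `frame_interval` | 0.065 | s | high-speed camera frame time |
| `noise_sd` (length) | 10 | subunits | stands in for Brownian wobble + sparse (10%) actin labeling |
| `unit_intensity` | 200 | a.u./dye | arbitrary; SNR is what matters |
| `trace noise_sd` | 20 | a.u. | step SNR 10 on traces, SNR 5 staircases in the photobleach stage |
| `k_bleach` | 0.02 | /s | kept ≤ 0.05/s so dwell truncation bias < 10% of $1/k_{off}$ |
| `n_sites` | 6 | — | one labelable cysteine per monomer, six per hexamer |
| `p_site` / `f` | f = 0.779 | — | measured labeled-hexamer fraction |
| `subunit_nm` | 2.7 | nm | filament length per subunit |
| `pixel_nm` | 130 (143 mf-TIRF) | nm | camera pixel sizes |
| `min_frames` | 4 | frames | dwells must be *longer than* four frames |

The mf-TIRF kymograph frame interval varies by acquisition and has no
defensible default, so `kymograph_slope()` requires it explicitly.

## What the generators emulate — and what they do not

`simulate_end_dynamics()` is event-driven: exact exponential sampling of
the alternating bound/unbound schedule, then discretization onto the frame
grid (Poisson per-frame removal counts, which is an exact discretization
of the removal process — there is no fixed-timestep approximation in the
kinetics). `render_intensity_trace()` adds per-event Binomial(6, p) dye
counts, independent per-dye exponential bleaching while at the end, and
Gaussian camera noise. `simulate_photobleach_traces()` draws visible
molecules from the zero-truncated dye-count distribution and bleaches one
unit step at a time. `render_movie()` draws both channels with Gaussian
PSFs and Poisson shot noise.

Real data differ in ways the generators deliberately ignore: filament
severing and annealing, stage drift, tracking errors, dye blinking and
partial quenching, non-uniform cofilin decoration near the end, and any
correlation between dwell duration and productivity. Passing the recovery
tests therefore shows that the estimator chain is *internally* unbiased
under the stated noise model — not that it is robust to every artefact of
a real microscope. The spot-intensity distribution comparison
(`compare_intensity_distribution()`) is the tool provided for checking one
of those assumptions (single hexamers at the end) against data.

## Numerical and design choices

**Dwell threshold policy.** The thresholding rule in the original
analyses of this kind is rarely stated in full. The default here enters a
dwell at background + 3 robust SD, exits at background + 1.5 SD
(hysteresis), and is computed **per trace**, since illumination and
background vary between filaments; the policy object (`dwell_threshold()`)
keeps the parameters pluggable. The background level is the *lowest mode*
of the intensity density rather than a two-cluster split: the occupied
state is itself multimodal (1–6 dyes), so a bimodal model would place the
background wrong. A trace whose maximum stays within what extreme-value
statistics of pure background noise would produce is declared featureless
and yields zero dwells.

**Boundary refinement.** Savitzky–Golay smoothing (11 frames at 0.065
s/frame) spreads each step over the window, and an asymmetric pair of
enter/exit thresholds would dilate every dwell by several frames. After
hysteresis detection each boundary is therefore refined to the
half-amplitude crossing of that dwell's own level, which restores ±1-frame
accuracy on clean steps.

**The "> four frames" filter** is read strictly: a run of exactly four
frames is rejected, five are kept. The cutoff is an integer argument, not
a constant.

**Censoring.** Dwells touching either end of a trace are excluded from the
mean dwell; only gaps between two complete interior dwells enter the gap
statistics. This avoids length-biased censoring; up to two consecutive
missing frames inside a run are bridged before a run is split.

**Dwell-filter interaction with the labeling correction.** The classic
inter-event correction $m = f m' - (1-f)/k_{off}$ accounts for *invisible*
(unlabeled) events, each of which inserts a full mean dwell into the
observed gap. The dwell-length filter creates a second thinning channel —
*labeled but short* events — whose inserted dwells are much shorter than
$1/k_{off}$. `estimate_kon(min_dwell_s = ...)` implements the generalized
correction $m = q m' - (1-q)\delta$ with $q = f e^{-k_{off} t_{min}}$ and
$\delta$ the mean dwell of a skipped event; at `min_dwell_s = 0` it
reduces exactly to the classic formula, which remains the default because
it is the form the method is known by. The analogous memoryless
left-truncation correction ($k_{off} = 1/(\bar\tau - t_{min})$) is
available in `estimate_koff()`. The pipeline uses both corrections; at the
study's n (~100–300 events) the uncorrected estimators are still within
sampling error of truth, which is presumably why the classic analysis
could ignore the filter.

**Step counting.** Changepoint segmentation is an exact O(n²)
penalized-least-squares dynamic program with a BIC-like default penalty
($2\hat\sigma^2\log n$, $\hat\sigma$ from median absolute first
differences); segments closer than half a unit intensity are merged before
counting downward transitions, and traces that never return to background
are flagged censored and excluded from the labeling fit. On simulated
staircases at step SNR 5 the counter is ≥ 95% exact for 1–6 steps; the
residual errors are near-simultaneous double bleaches, which bias counts
slightly low.

**Labeling fit.** The per-site probability is fitted by zero-truncated
Binomial(6, p) maximum likelihood (`optimize`, tolerance 1e-10), with a
profile-likelihood CI mapped monotonically to $f$ and an
observed-information SE alongside. A printed "±" on a labeled fraction
can mean either; both are reported and labelled.

**MM fitting.** `minpack.lm::nlsLM` with analytic-free Levenberg–
Marquardt, initialized at $K_M$ = median concentration, $k_{cat}$ = max
velocity, positivity bounds, Wald t-intervals. Weighted (1/sd²) fitting is
available but off by default, because unweighted is the common practice
for this assay. Per-filament velocities are simulated as truncated normal
(negatives resampled) with CV 0.15 — a typical filament-to-filament spread
for this measurement.

**Velocity sign convention.** Velocities are signed internally (negative
slope = shrinkage) and reported as positive depolymerization rates at the
interface.

**Kymograph edges** are located per time-row by threshold crossing with
subpixel linear interpolation, using dim/bright quantiles (2%/98%) for the
background and signal levels so a filament that fills most of the field
does not corrupt the background estimate. The slope is OLS by default,
with `MASS::rlm` as the robust option against edge-detection outliers.

## Problem sizes used in the shipped checks

The package's own tests and the acceptance script run at deliberately
modest scale, chosen to keep each stochastic check's 3-SE band meaningful:
5,000–8,000 events for thinning-inversion properties, 300 photobleaching
staircases, 7 concentrations × 30 filaments for saturation fits, 50
trajectories × 40 frames for slope velocimetry, and a few hundred to a
thousand seconds of simulated single-molecule recording for the dwell/gap
chain. These sizes mirror (or exceed) the corresponding experimental
n's, and all recoveries are asserted within 3 standard errors, never
against rounded headline numbers.

## Known limitations

* The dwell detector assumes the end spends a detectable fraction of time
  unoccupied per trace; above ~80% visible occupancy the background mode
  becomes unreliable and threshold policies should be supplied explicitly.
* Closely spaced binding events (gaps shorter than the smoothing window,
  ~0.7 s) merge into single detected dwells; at 83 nM this inflates the
  apparent mean dwell. Gap statistics are less affected, and the
  dissociation rate is better measured at lower concentrations — which is
  exactly why sparse-event conditions exist in the study design.
* Bleaching truncates dwells; keep $k_\mathrm{bleach} \lesssim 0.05$/s
  relative to $k_{off} = 0.45$/s, or fit the dwell distribution with the
  bleach rate as a nuisance parameter (not implemented).
* `fit_labeling()` conditions on visibility; it cannot detect a population
  of permanently dark hexamers beyond the binomial zero class.
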