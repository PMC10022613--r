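---
title: "Runaway cavitation, optical embolism detection and dehydration thresholds: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runaway cavitation, optical embolism detection and dehydration thresholds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavistress)
```

This vignette documents the models, the estimators, the synthetic-data
generator and the numerical choices behind `cavistress`, in the spirit of
a methods section: what is assumed, what is tunable, and what passing the
package's tests does and does not demonstrate about real data.

## The hydraulic model

Leaf hydraulic conductance is modelled as a declining sigmoid of leaf
water potential $\Psi$ (MPa, negative):

$$K(\Psi) = \frac{K_{max}}{1 + e^{(P50 - \Psi)/\alpha}}, \qquad \alpha > 0,$$

with $K_{max}$ the well-hydrated maximum (mmol s$^{-1}$ m$^{-2}$
MPa$^{-1}$), $P50$ the potential at half loss, and $\alpha$ (MPa) the
slope. A note on the sign convention: the equivalent form with
$e^{(\Psi-P50)/\alpha}$ and a *negative* slope parameter describes the
same curve; `cavistress` fixes $\alpha > 0$ with the $(P50-\Psi)$
ordering because only then are the runaway formulas below algebraically
self-consistent with a conductance that *falls* as the leaf dries. The
constructor `vuln_curve()` enforces $\alpha > 0$, $K_{max} > 0$,
$P50 < 0$, and `conductance(curve, p50)` equals $K_{max}/2$ exactly.

After stomatal closure the only demand is cuticular transpiration
$E_c = g_{min}\,\mathrm{VPD}/P_{atm}$, with VPD from the Arden–Buck
saturation formula
$(1 - RH/100)\,0.61121\,e^{17.502T/(240.97+T)}$ (kPa, $T$ in °C).
Steady-state supply through the cavitating pathway at source potential
$\Psi_s$ is $S(\Psi_l) = K(\Psi_l)(\Psi_s - \Psi_l)$; it is unimodal in
$\Psi_l$. Setting $S'(\Psi_l) = 0$ and $S = E_c$ simultaneously gives the
fold point where the steady state vanishes:

$$\Psi_{run} = P50 - \alpha\,\ln\!\left(\frac{\alpha K_{max}}{E_c}\right),
\qquad PLC_{run} = 100\,\frac{x}{1+x},\quad x = \frac{\alpha K_{max}}{E_c}.$$

The derivation is exact, not asymptotic: at the critical source potential
the maximiser of $S$ satisfies $K/K_{max} = 1/(1+x)$, which is both
formulas at once. `runaway_point()` implements the closed form;
`runaway_point_numeric()` re-derives the same point with no shared
algebra, by scalar maximisation of $S$ and bisection on $\Psi_s$, and the
two agree to $10^{-6}$ MPa across a broad random parameter sweep in the
test suite. One caveat worth stating: a *single* parameter set cannot
reproduce both a runaway potential of $-3.82$ MPa and a runaway PLC of
$79\%$ under these formulas with the mean $K_{max}$, $P50$ and $E_c$ of
the emulated study; with the package's calibrated default slope
($\alpha = 0.09$ MPa, chosen so the closed form reproduces the $-3.82$
MPa mean) the implied PLC is $73\%$. Per-individual slopes would be
needed to reconcile the pair, so the package treats the PLC as a derived
per-curve quantity and never asserts the pair jointly.

## The drydown simulator

`simulate_drydown_ode()` integrates the capacitance-buffered balance

$$C\,\frac{d\Psi_l}{dt} = K(\Psi_l)(\Psi_s(t) - \Psi_l) - E_c$$

with $\Psi_s(t)$ declining linearly (default $-0.5 \to -6$ MPa over 5
days, the emulated bench protocol) using `deSolve`'s stiff-capable
`lsoda`. Runaway onset is flagged as the first time the quasi-steady root
ceases to exist — $\max_{\Psi_l} S < E_c$ — refined by root-finding in
time; a slope heuristic would confound fast tracking with true loss of
equilibrium, so it is used only as a visual cross-check. The capacitance
$C$ is not a published quantity; the default, 50 mmol m$^{-2}$
MPa$^{-1}$, describes a thin, fast-equilibrating juvenile leaf (relaxation
time $C/K \approx 30$ s near the runaway point) for which the simulated
leaf tracks the quasi-steady branch to within 0.02 MPa of the analytic
fold at the study's ramp rate. Larger capacitances lag the fold
noticeably (square-root-type delay of a dynamic saddle-node): with
$C = 500$ the onset potential reads $\sim 0.04$ MPa wet of the closed
form. $C$ is a configuration parameter, never hard-coded, and should be
derived from the PV-curve slope when real PV data are at hand.

## Synthetic data: what it emulates, and what it does not

Every input the pipeline consumes can be generated under a fixed seed.

* **Vein network** (`build_leaf_geometry()`): a rectangular lamina with a
  5-px-wide vertical midrib, 8 major veins branching to the margins, and
  a jittered rectilinear HOV grid (1 px wide, i.e. 25 µm at the default
  scale, below the 50 µm HOV definition). Every HOV piece between
  crossings is a segment; its uniquely served area is the set of lamina
  pixels nearer to it than to any other HOV line — the pixel form of
  "half the distance to the nearest neighbouring vein" — and these areas
  tile the lamina. All vein orders keep a ≥2 px clearance from one
  another so that laterally spread optical flashes of different events
  can never touch; real vein junctions are connected, which is precisely
  why the emulation separates them (the detector must count *events*, not
  anatomical connectivity).
* **Event schedules** (`schedule_cavitation_events()`): trigger
  potentials are logistic draws matching per-order cumulative sigmoids
  (defaults $P50$ = −3.35 / −3.80 / −4.07 MPa for midrib / major / HOV;
  slopes 0.25, 0.25 and 0.202 MPa — the HOV slope is the one consistent
  with the emulated study's P20 of −3.79). Midrib and major segments
  receive normal event counts (means 9.4 and 4.53, rounded, floored at
  1), drawn per segment; each HOV segment cavitates exactly once, as a
  whole-segment event. Midrib/major events occupy disjoint axial
  sub-stripes (2–4 px long, 2 px gaps), the pixel analogue of individual
  vessels.
* **Image stacks** (`render_stack()`): events appear as transient
  brightenings (default amplitude 0.10 for 2 frames over Gaussian pixel
  noise of sd 0.02, i.e. flash SNR 5), the margin optionally tracks the
  width series, and the background is stationary. No optical physics, no
  illumination drift, no motion beyond shrink: detection performance on
  these stacks is an upper bound for real OVT sequences, which add
  registration error and nonstationary lighting.
* **Series**: the psychrometer ramp (linear + iid noise), leaf width via
  the printed calibration ($y = 6.1963\,\Psi + 106.22$, % of full
  hydration) applied to a leaf potential that decouples from the stem
  below a transition (piecewise slope multiplier 3 by default — the fast
  stand-in for the ODE-driven decoupling), Fv/Fm as a 0.80 plateau with a
  linear fall to 0.05 at −6 MPa below its breakpoint (the healthy plateau
  is a package default; only the death threshold, 0.2, is an observed
  quantity), gmin mass traces (exponentially closing stomatal phase, then
  the linear cuticular phase), PV curves (osmotic potential inverse in
  symplastic water, turgor linear to zero at the configured deficit), and
  rehydration records constructed so the two implied conductances of each
  record agree exactly unless noise or injected inconsistency is asked
  for.

## Optical quantification

`difference_stack()` is plain $|I_{t+1}-I_t|$. `detect_events()`
thresholds each difference frame, labels 4-connected components
(`EBImage::bwlabel`), and merges components that overlap across at most
`merge_window` frames (default 2), so a flash's onset and offset episodes
count once. Numerical choices that matter:

* **Threshold**: Otsu's method on a pooled sample of the difference
  histogram, floored at 2.75 robust noise standard deviations (the noise
  scale is the folded-Gaussian median of the stack). On a signal-free
  stack the histogram is unimodal and raw Otsu lands inside the noise
  mode; the floor is what makes "no events in pure noise" true. A fixed
  threshold override is available.
* **Speckle and dropout**: components smaller than 3 px are discarded
  before merging (supra-threshold noise pixels), and overlap is tested on
  the 1-px dilated component so that two episodes of one flash merge even
  when pixel dropout makes their detected subsets disjoint. The event
  footprint gap of 2 px in the generator is the matching guarantee that
  *distinct* events never merge this way.
* `min_area` (default 4 px) applies to the merged pixel union.

Vein order is assigned by majority overlap with the order mask, ties
toward the lower order; cumulative curves normalise cavitated area by the
order's final cumulative area (the OVT "% of total embolism" convention,
not anatomical xylem area); leaf width is the median of three transects
from the midrib edge to the margin; functional-area loss subtracts each
cavitated HOV segment's served tile (or, in brush mode, a stripe of
diameter equal to the mean HOV spacing).

A consequence of whole-segment HOV footprints worth knowing: the pooled,
area-weighted vulnerability curve of a synthetic leaf is dominated by HOV
area and sits near −3.9 MPa, drier than the −3.73 MPa leaf-level mean of
the emulated study. The pipeline therefore reports the leaf-level P50
from the rehydration-kinetics conductance curve (where −3.73 is a
generator parameter and is recovered), and reports the pooled optical
curve separately as `P50_veins_pooled`.

## Estimators

* **Breakpoint regression** (`fit_breakpoint()`): the iterative
  working-linear-model scheme — fit
  $y \sim x + (x-\psi)_+ + \mathbb{1}\{x>\psi\}$, update
  $\psi \leftarrow \psi - \hat\gamma/\hat\beta_2$ — with an exhaustive
  SSE grid search over interior candidates as fallback, a two-parameter
  F-test (plus an exact-fit shortcut) to report "no breakpoint" on
  straight lines rather than erroring, and a seeded nonparametric
  bootstrap for the standard error (closed-form SEs are
  implementation-specific across packages; the bootstrap is not). On
  noiseless two-segment data the iteration converges to the exact
  intersection of the two lines.
* **Cumulative-sigmoid fit** (`fit_cavitation_curve()`): least squares of
  $1/(1+e^{(\Psi-P50)/\alpha})$ via `minpack.lm`, plus an
  isotonic-regression smoother as a shape-agnostic cross-check (the
  emulated study smoothed with GAMs only to read off means; exact GAM
  reproduction is a non-goal). `extract_px()` inverts the sigmoid in
  closed form, $\Psi_p = P50 + \alpha\ln((100-p)/p)$, and refuses to
  extrapolate the smoother.
* **K$_{leaf}$ kinetics** (`kleaf_instance()`, `fit_kleaf_curve()`): two
  conductances per rehydration record, standardised to 20 °C via the
  Vogel viscosity ratio, flagged when they disagree by more than 10%;
  the 4-parameter sigmoid $y_0 + a/(1+e^{-(\Psi-x_0)/b})$ is fitted from
  a deterministic 8-start grid, and reduced for the runaway formulas as
  $K_{max} = y_0 + a$, $P50$ the potential where the curve crosses
  $K_{max}/2$ (which is $x_0$ when $y_0 = 0$), $\alpha = |b|$. How the
  original analysis folded $y_0$ into its per-plant slopes is not
  recoverable; this mapping is explicit and tested instead.
* **gmin** (`gmin_from_trace()`): the steady phase is the longest
  terminal window whose rolling slope varies by less than 5%; then
  $g_{min} = WL \cdot P_{atm}/\mathrm{VPD}$ with the mass slope converted
  to mmol m$^{-2}$ s$^{-1}$.
* **TLP** (`tlp_from_pv()`): grow the terminal line of $-1/\Psi$ against
  water deficit from the dry end while $r^2 \ge 0.995$ (min 4 points);
  TLP is the wettest point on the line, the osmotic potential at full
  turgor comes from the intercept. The linearity criterion is a package
  choice (none is published); its discreteness means recovery is exact
  only to the local spacing of the sampled points (≈0.05 MPa at the
  default 20-point design).

## The pipeline and its default conditions

`run_pipeline()` chains everything under one seed: 13 leaves and 6
fluorescence plants (the study sizes), 5-day ramps, per-order schedules,
optional rendering and re-detection (`optical$render = TRUE`; the default
uses the schedules directly, which is what the per-order statistics need
and is ~50× faster), stem event streams ($P50 = -3.97$, with slope 0.743
MPa chosen so the same sigmoid also reproduces the −5.45 MPa P88), PV,
gmin and rehydration traces, and assembles the trait table and the
threshold-coincidence comparison (pairwise residual matrices in MPa and
minutes, one-way ANOVA + Tukey HSD across vein orders). With
`couple_thresholds = TRUE` (default) the width and Fv/Fm breakpoints are
generated *at the runaway point of the configured hydraulics* — the
mechanistic claim under test — and the pipeline's three damage thresholds
then coincide within 0.15 MPa; with coupling off they fall at the
independently observed values (−3.62, −3.53). Rendering inside the
pipeline and the acceptance script uses shrink-free stacks: a moving
margin would clip late events near the leaf edge and bias per-segment
counts, while width measurement has its own shrink-enabled path.

Problem sizes in the tests and acceptance script (361-frame, 320-px
stacks at 20-min cadence; 100-point oracle sweeps; 6 or 13 replicate
series) were chosen so the full suite runs on a laptop in a few minutes
while leaving Monte-Carlo error well inside the reported spreads.

## Known limitations

* The geometry is a rectilinear caricature: no areoles, no vein
  tapering, no loopiness; served-area tiles are exact by construction
  rather than estimated from anatomy.
* Detection assumes stationary Gaussian noise and immobile leaves (up to
  programmed shrink); real OVT stacks need registration first.
* The ODE treats the leaf as one well-mixed compartment; within-leaf
  spatial propagation of embolism is represented only by the per-order
  schedules, not by the dynamics.
* Psychrometer fusion (two sensors plus pressure-chamber cross-checks)
  is out of scope: one stem series per plant is taken as given.
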