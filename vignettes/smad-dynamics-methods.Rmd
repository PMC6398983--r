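---
title: "Models and methods: adaptive SMAD signaling, FRAP inference, and colony wave analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smaddyn)
```

This vignette is the package's own account of its models, parameter choices
and numerical conventions. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The scientific setting

Human embryonic stem cells read the two branches of TGF-β superfamily
signaling differently. The BMP4 response of nuclear SMAD4 is sustained: it
tracks ligand concentration, with signaling duration at low doses limited by
depletion of the ligand from the medium. The Activin/Nodal response is
adaptive: nuclear SMAD4 peaks within the first hour and then relaxes to a
low maintained baseline (around 20% of the peak; the receptor-specific
SMAD2/3 adapts less, to about 60%). An adaptive pathway responds to the
*rate of increase* of its ligand, not its level — a sudden step elicits a
strong response where a slow staircase ramp to the same dose elicits almost
none, and repeated pulses separated by a few hours re-trigger full
responses. During self-organized patterning of micropatterned colonies the
same logic appears in space: after edge restriction of the BMP response, a
wave of Nodal-driven signaling travels inward at about one cell diameter
(10 µm) per hour, fast enough that each cell experiences a rapid local
increase, and mesendoderm (BRA) induction follows in its wake.

The package implements each quantitative piece of that argument as
simulation plus measurement, with synthetic data standing in for microscopy.

## Signaling models

### Negative feedback (Activin/Nodal-like)

$$\frac{dS}{dt} = \frac{\alpha\,O(L)}{1 + I/K_I} - \gamma\,(S - S_0),
\qquad
\frac{dI}{dt} = \beta\,(S - S_0) - \delta\,I,
\qquad O(L) = \frac{L}{L + K_L}$$

`S` is the nuclear:cytoplasmic SMAD4 ratio, `I` a lumped downstream
inhibitor. With no ligand the unique steady state is `(S₀, 0)`; a sustained
step overshoots and relaxes to a plateau above `S₀` that is maintained by
continued ligand exposure. The adaptation timescale is set by the inhibitor
decay rate δ and is therefore dose-independent, while peak and plateau grow
with dose — the fingerprint of this class of model.

These equations are this module's minimal realization of
inhibitor-feedback adaptation (occupancy-Hill activation, linear inhibitor
production, first-order decay); they are isolated behind `feedback_params()`
so an alternative form can be swapped in.

**Calibration.** The shipped defaults (`analysis/00_calibrate_feedback.R`)
fix the structure first — γ = 6/hr, δ = 0.85/hr, K_L = 20 ng/ml, K_I = 1,
S₀ = 1 — and then solve (α, β) so that a saturating 50 ng/ml step over a
12 hr window gives peak excess 1.0 ratio units with a late plateau at 20% of
it. The SMAD2/3 channel is the same system with weaker feedback: only K_I is
enlarged (to ≈ 1208) until the plateau is 60% of peak.

Two calibration constraints deserve comment because they pull against each
other in a two-variable feedback model:

* *Deep adaptation with fast recovery.* A 20% plateau needs the adapted
  inhibitor level to reach `I* = 4 K_I`, and re-triggering ≥ 80–85% of the
  peak after a 5 hr gap needs that inhibitor to decay almost completely in
  5 hr, hence δ ≥ ~0.85/hr. Maintaining `I*` against such fast decay
  requires strong production (large β), which also acts during the rise —
  so the peak becomes an early, sharp transient (a few minutes) rather than
  a ~1 hr hump, and the measured 1/e adaptation time is ~0.25 hr rather
  than the ~2 hr a slower inhibitor would give. We resolved the tension in
  favor of the quantitative constraints (plateau fractions, re-trigger at
  5 hr gaps, dose-independent timescale, ramp attenuation); the time-axis
  shape of the transient is the known casualty and should not be read
  quantitatively.
* *Ramp attenuation versus dose saturation.* For a staircase ramp to be
  strongly attenuated, each hourly increment must be sensed
  sub-saturatingly, so K_L must be comparable to the final dose (20 ng/ml
  here). The cost is a more graded dose-response than the sharply
  saturating one seen experimentally; the dose-response *shape* beyond the
  quoted plateau fractions is deliberately left as calibration freedom.

### Receptor depletion (the rejected alternative)

$$\frac{dR}{dt} = s - d_i R - k_b L R, \qquad
\frac{dR^*}{dt} = k_b L R - d_a R^*, \qquad S = \rho R^*$$

At saturating ligand the peak approaches the pre-stimulus pool `s/d_i`
converted to `R*`, and the adapted steady state is `s/d_a`, so the adapted
fraction of peak tends to **d_i/d_a**: the magnitude of adaptation is
governed by the ratio of the degradation rates of inactive and active
receptors. The same two rates set the timescales — adaptation relaxes at
`d_a`, recovery of responsiveness after ligand removal at `d_i` — so strong
adaptation forces slow recovery (ratio `d_a/d_i`). The acceptance suite
verifies both closed forms numerically across a parameter sweep; this is the
quantitative argument for rejecting upstream-depletion mechanisms, because
pulse experiments show a refractory period comparable to the adaptation
time, not an order of magnitude longer.

### Ligand depletion (BMP-like)

Between media changes the ligand decays as `L(t) = c·e^{−u(t−t_c)}` from the
concentration `c` set at the last change (default u = 0.15/hr), and the
response follows a switch-like occupancy `L^h/(L^h + L_thresh^h)` (h = 4,
L_thresh = 1 ng/ml) relaxed at rate γ. Signaling is sustained while `L` is
well above threshold and collapses when `L` crosses it at
`t = ln(L₀/L_thresh)/u`, so the duration of half-maximal signaling grows
logarithmically with dose — the observed dose-dependent duration at low BMP4
doses. The switch-like occupancy gives the near-full response at low doses;
its steepness h = 4 is a choice, not a fit.

### Target genes and qPCR units

Target transcription is first-order mRNA kinetics driven by signaling excess
above a threshold θ: adaptive-class genes have θ above the adapted baseline
(they see only the peak), sustained-class genes have θ below it (they are
maintained by the baseline — which is why the baseline matters
biologically). Clamping `S` to `S₀` at an inhibition time makes mRNA decay
at δ_m thereafter, the behavior used to justify fast mRNA turnover.
Measured expression is handled on the qPCR scale:
`normalize_ct(ct_target, ct_reference)` returns
`−ΔCt = −(Ct_target − Ct_ref)`, i.e. log2 expression relative to the
reference gene (ATP5O in the experiments this mirrors).

## FRAP model and inference

Free molecules exchange between cytoplasm and nucleus with import rate
`k_in` and export rate `k_out`; fractions `f_ns` (nuclear) and `f_cs`
(cytoplasmic) are sequestered — mobile within, but not between,
compartments on the recovery timescale. Book-keeping is in intensity units
with the effective volume ratio folded into the pre-bleach ratio `R`;
production and degradation are neglected (recovery is pure redistribution),
and sequestration exchange is frozen on the recovery timescale. The
pre-bleach steady state `k_in C_free = k_out N_free` fixes

$$R = \frac{k_{in}(1 - f_{cs})}{k_{out}(1 - f_{ns})}.$$

Bleaching multiplies all nuclear fluorescence by `(1 − b)` instantaneously.
The free pools then relax in closed form with the single exchange eigenvalue
`k = k_in + k_out` — which is why the recovery rate reflects kinetics, not
bleach depth — and the post-recovery ratio `R′` falls below `R` whenever
anything is sequestered: the bleached nuclear sequestered pool is never
replenished, and the cytoplasmic sequestered pool never contributes. `R′ = R`
exactly only when `f_ns = f_cs = 0`; this inequality is the data signature
that motivates the sequestration model.

`fit_recovery()` fits `I_nuc(t) = I_∞ − A e^{−k(t − t_bleach)}` to the
post-bleach samples (normalized by pre-bleach cytoplasmic intensity), reads
`R` from the pre-bleach ratio, `R′` from the final 10% of the trace (a
robust empirical plateau readout; its difference from the fitted-plateau
ratio is kept as a diagnostic), and the bleach depth from the fitted
post-bleach intercept. Fits with `k ≤ 0` or relative SE(k) > 100% are
flagged and excluded with a logged count.

From the forward model, `A = (1 − f_ns) R\,k_{out} b / k`, so the
closed-form inversion used by `infer_sequestration()` is

$$k_{out} = k - k_{in}, \qquad
f_{ns} = 1 - \frac{A k}{R\,k_{out} b}, \qquad
f_{cs} = 1 - \frac{k_{out}}{k_{in}}(1 - f_{ns})R,$$

applied to per-condition means of `(A, k, R, b)` over cells, with first-order
(delta-method) propagation of their standard errors, treated as independent.
`k_in` is fixed at 0.04/min by convention — the model only identifies rates
relative to a fixed import rate — so inferred export rates directly reflect
the measured exchange rates. Estimates outside `[0, 1]` are clipped and
flagged.

The FRAP ensemble generator jitters per-cell parameters (lognormal, CV 0.05)
around the condition values and records the *realized* per-cell parameters
and their means as the sidecar ground truth. Round-trip tests compare
estimates to those realized means: that is the actual truth of the generated
ensemble, and against it the propagated SE (dominated by parameter
dispersion) bounds the estimation error, making a 1-SE recovery check across
a 27-point grid meaningful.

## Image quantification conventions

* Signaling is the background-subtracted nuclear over cytoplasmic mean,
  `(nuc − bg)/(cyt − bg)`, per cell; purely nuclear markers are measured as
  nuclear mean normalized by the per-cell DAPI mean. The ratio is exactly
  invariant to adding an offset to, or positively rescaling, the whole image.
  Cells with non-positive cytoplasmic excess are excluded with a logged
  count.
* Coordinates use pixel centers with radii in µm via the pixel size; radial
  bins are 20 µm wide (a 700 µm colony spans 17–18 bins). Empty annuli carry
  `NA`, never zero, and all downstream steps drop missing values.
* Normalization rules: per-time min–max for SMAD1/pSMAD1 and SMAD2/3 (their
  extreme levels are similar over time; only the spatial pattern varies);
  SMAD4 display normalization anchors, per time, the maximum over positions
  interior to the innermost pSMAD1 half-maximum at 1 (that position reflects
  the peak of Nodal-dependent SMAD4); BRA is scaled globally by the maximum
  of the latest time because its absolute level grows. A constant row under
  min–max is set to 0 with a warning.
* Front tracking reports, per time row, the innermost radius where the
  linearly interpolated profile crosses the half-maximum level moving inward
  from the colony edge (the wave travels inward; the innermost crossing is
  reported if there are several). Velocity is the negated least-squares
  slope over the 25–40 hr window (the wave phase; configurable). Onset is
  the first time the half-maximum leaves the edge zone — the outermost 10%
  of the radius — by more than one radial bin.
* Front tracking is only applied from the edge-restriction time onward:
  during the uniform early phase a radial profile has no front, and min–max
  normalization of a structureless row would track noise. This windowing is
  a deliberate analysis choice, mirrored in the drivers.
* Segmentation of synthetic nuclear-marker images is Otsu thresholding plus
  distance-map watershed (to split touching nuclei), a fixed-width dilation
  ring per nucleus assigned by propagation as cytoplasm, and background
  taken beyond an extra exclusion margin so wide cells do not leak into the
  background estimate. Real-microscopy segmentation (learned pixel
  classification) is out of scope.

## The synthetic colony

The colony generator is phenomenological by design: the claim under test is
the *measurement* of rapidly changing signaling, not its spatial mechanism,
so the space–time program is written down directly (no reaction–diffusion).
A 700 µm colony responds uniformly (1 hr rise), restricts to an edge band
(logistic shoulder, 40 µm band), and from 25 hr an inward logistic wave
(10–90% width 40 µm) travels at 10 µm/hr. SMAD4 carries the edge component
and the wave combined saturatingly (`1 − (1−u_B)(1−u_W)`, so stacked drives
do not exceed the plateau); pSMAD1 is the edge component only; SMAD2/3 the
wave only; BRA integrates the wave occupancy with first-order gene kinetics
(production behind the front, decay 0.15/hr), giving the lagging expression
domain.

Two quantitative design choices:

* **Wave origin.** The wave starts at the inner boundary of the
  edge-restricted domain (colony radius − 50 µm), not at the colony rim. The
  wave emerges from the already-signaling edge domain, so its half-maximum
  front becomes distinguishable from the edge shoulder immediately; a
  rim-origin wave's front would spend its first ~5 hr hidden inside the edge
  band and its onset could not be read to ±1 hr by any half-maximum tracker.
* **Restriction margin.** "Restricted by ~12 hr" is treated as a completion
  bound: the interior decay constant is solved (given the band shape,
  amplitude and the actual measurement bins) so the inner-half/edge-band
  mean ratio crosses 0.5 at 85% of the stated time (~10.2 hr), leaving room
  for colony-to-colony variability while keeping restriction complete by
  12 hr. The programmed crossing time is emitted in the ground-truth
  sidecar.

Noise is structured the way colony-averaged data are: each of 4 colonies
gets a shared lognormal amplitude factor (CV 0.2) plus independent per-bin
lognormal noise (CV 0.03, the sampling error of a ~40-cell annulus), and
kymographs are colony averages. Shared amplitude factors largely cancel in
per-row normalization, which is why front positions are robust; purely
independent per-bin noise of the same total magnitude would not be.

The rendered-image closure places ~330 non-overlapping cells in the colony
disc (cells do not move), evaluates the SMAD4 field at each cell's radius
with a persistent per-cell amplitude factor (CV 0.2), renders 256×256 px
frames (nucleus disks, cytoplasm rings, Poisson shot noise plus 1% Gaussian
read noise), and pushes every frame through segmentation, per-cell
measurement and radial binning. Intensities are constructed so the noiseless
background-subtracted ratio equals the ground truth exactly; residual
segmentation-edge effects act approximately affinely on the measured ratio
and cancel in per-row normalization.

**What passing these closures does and does not show.** They show the
measurement chain (segmentation → ratio → profile → normalization → front
tracking) recovers programmed dynamics through realistic noise at realistic
sampling. They do not validate the generator against real microscopy: real
colonies have cell movement, division, uneven illumination, segmentation
errors correlated with signal, and colony-to-colony variance structure that
is only guessed here (error bars over N = 4–5 colonies in the data this
emulates).

## Numerical choices

* ODEs are integrated with `deSolve::lsoda` (stiff-capable, rtol 1e-6,
  atol 1e-9), restarted at every schedule breakpoint so discontinuous media
  changes are never smoothed across. Integration failures surface as errors
  with the interval echoed, not as silent warnings.
* A fixed-step classical RK4 integrator (`integrate_rk4`), also restarted at
  breakpoints, serves as the independent reference; the suite requires
  agreement to 1e-4 relative.
* The FRAP forward model is evaluated in closed form (the 2×2 exchange
  system's exponential); the test suite cross-checks the relaxation rate
  against a matrix-exponential oracle.
* Adaptation metrics: baseline is the mean of the final 10% of the window;
  the timescale is the first post-peak time at which the excess over
  baseline falls to 1/e of the peak-to-baseline excess. Monotone
  non-decreasing trajectories get baseline fraction 1 and an infinite
  timescale; flat trajectories are flagged "no response"; adapting
  trajectories whose window is shorter than 4 timescales raise an error
  rather than returning an unreliable baseline. Classification sentinels:
  baseline fraction ≥ 0.8 sustained, ≤ 0.5 adaptive, otherwise intermediate.
* Problem sizes used by the tests and acceptance script — 0.01 hr grids over
  12–34 hr windows, 20-cell FRAP ensembles over a 27-point grid, 4-colony
  kymographs at 0.5 hr × 20 µm resolution, and a 40-frame 256×256 px
  rendered colony — were chosen as the smallest sizes at which every
  measured quantity is stable to well within its test tolerance.

## Known limitations

* The feedback transient's time axis is compressed (minutes-scale peak), as
  discussed under calibration; only its amplitude ratios, dose trends and
  refractory behavior are calibrated.
* The Activin dose-response is more graded than the sharply saturating one
  observed experimentally (the K_L trade-off above).
* No Wnt co-stimulation, no spatial signaling mechanism, no cell tracking,
  no learned segmentation, and no modeling of slow sequestration exchange
  during FRAP recovery.
* All export rates are relative to the fixed `k_in = 0.04/min` convention;
  they are comparable across conditions but not absolute.
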