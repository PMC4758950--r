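---
title: "Models and methods: length-dependent motor feedback on microtubule dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: length-dependent motor feedback on microtubule dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtantenna)
```

This vignette is the package's own account of the models it implements, the
choices made where the design was genuinely open, and what the synthetic
data can and cannot establish about real assays.

## The two-state model and its summary statistics

A dynamic microtubule is modelled as a filament that grows at constant
speed $v_+$ until a catastrophe (Poisson, frequency $f_{+-}$ per minute of
growth), shrinks at $v_-$ until a rescue (Poisson, $f_{-+}$ per minute of
shrinkage) or until it reaches the stabilized seed (length zero), where it
renucleates. `simulate_dynamic_instability()` samples this process exactly
(exponential waiting times, event-resolved piecewise-linear trajectories).
Renucleation is instantaneous by default; an exponential nucleation delay
is available (`renucleation_delay`) but not used in the packaged
conditions, because the expected-length formula the package reproduces
assumes regrowth without delay.

Two ratios summarise the process: the catastrophe distance $v_+/f_{+-}$
and the rescue distance $v_-/f_{-+}$. When a frequency is zero the
corresponding distance is unbounded; the package represents this as `Inf`
(R's native tagged value for an unbounded magnitude, distinct from any
overflow) and prints dashes in reports. Under instant-reset cycling and
ignoring rescues, the expected length at time $t$ is
$L(t) = (v_+/f_{+-})(1 - e^{-t f_{+-}})$, implemented in
`expected_length()` with the $f_{+-} \to 0$ limit $v_+ t$ taken
explicitly. `simulate_reset_process()` is the Monte-Carlo counterpart used
as an independent oracle in the tests.

## The antenna feedback model

Processive motors land along the lattice at rate
$a\,c$ per µm (landing rate $a$, concentration $c$), walk to the plus end,
and detach with mean run length $\lambda$, giving the steady-state end
flux $J(L) = a c \lambda (1 - e^{-L/\lambda})$ (`antenna_end_flux()`; the
tests verify it against direct quadrature of the landing-survival
integral).

`simulate_coupled()` resolves individual motors: Poisson landing
(time-inhomogeneous, because the filament length changes linearly between
events — sampled by inverting the integrated hazard, a quadratic),
deterministic walking at the dynamic-lattice velocity, exponential
detachment at rate `velocity_lattice / run_length`, a plus-end pool capped
at `end_capacity`, and exponential end release. With end occupancy $N$ out
of capacity $N_{sat}$ the filament's instantaneous rates are linear in
occupancy:

$$v = v_0 + (v_{max} - v_0)\,N/N_{sat}, \qquad
  f = f_0 - (f_0 - f_{min})\,N/N_{sat}.$$

Design choices in this model, made where the measurements constrain only
the endpoints:

* **Coupling through end occupancy, not raw flux.** End residence produces
  the observed accumulation (up to ~12 motors), and a pool with first-order
  release is the minimal mechanism that converts length-dependent flux
  into a bounded, saturating signal. The linear map in $N/N_{sat}$ is the
  parsimonious choice.
* **Arrivals at a full pool are released** immediately (the pool is a
  finite number of end sites).
* **At a catastrophe the end pool is released**, and a shrinking end
  annihilates the lattice motors it meets (collision times are computed
  exactly; every motor provably collides before the filament reaches
  zero). The data do not constrain motor fate on shrinking ends; this is
  the simplest consistent rule.
* **Continuous drift instead of discrete 8-nm stepping.** Every statistic
  analysed here depends only on the velocity and the exponential
  dissociation, so discrete stepping would add cost without changing any
  assayed quantity.
* **Landing rate** $a$ is not measured. The default
  0.6 µm⁻¹ nM⁻¹ min⁻¹ was calibrated once so that the occupancy model's
  initial length dependence ($a c \tau_{end} \approx 0.3\,cL$ motors at
  short lengths) matches the initial slope of the measured growth law
  ($N_{sat} cL / A \approx 0.3\,cL$), and end occupancy saturates near the
  observed ~12 motors at the highest concentration. It is a model
  constant, not a fitted quantity.
* **Photobleaching** is off by default in the coupled model (the growth
  assays use unlabelled motors); it is a first-class competing risk in the
  single-molecule simulator, where it matters.

Motor conservation is enforced by an explicit ledger (every landed motor
is accounted for as detached, bleached, end-released, overflow-released,
released by shrinkage or catastrophe, or still present); the invariant is
asserted in the tests, and internal state inconsistencies raise errors
rather than being clamped.

`simulate_length_law()` is the companion model in which $v$ and $f$ follow
the explicit laws in the antenna product $cL$ directly. It is the
generating model matched to the length-binned analysis and the length-law
fit; growth is integrated on a 2-s grid with per-step thinning of the
catastrophe propensity (step probability ≤ 0.01 at the rates used, so the
discretisation error is far below all acceptance tolerances).

### The adopted length-law form

The measured growth law is reported through its parameters
($v_0 = 0.294$, $v_{max} = 1.03$ µm/min, $A = 39.8$ µm·nM) with $A$ in
units of length × concentration. The package adopts

$$v(L, c) = v_0 + (v_{max} - v_0)\,\frac{cL}{A + cL},$$

the unique single-saturation-constant form that is dimensionally
consistent with $A$'s units, saturates at high $cL$, and reduces to $v_0$
at $c = 0$. It is implemented as a plain function
(`growth_rate_vs_length()`) so an alternative form can be swapped in. The
catastrophe law mirrors it downward with the same $A$ by default
($f_0$, $f_{min}$ independently configurable); the measurements establish
the direction and the endpoints of catastrophe suppression, not its
functional form.

## What the synthetic assays emulate — and what they do not

`generate_assay()` samples trajectories at a fixed frame interval and adds
independent Gaussian tip-localization noise:

* **Observation window 10 min**, matching the dynamic assays.
* **Frame interval 2 s** (acquisition rates are not published). At 2 s a
  27.6 µm/min shrinkage moves ≈ 0.9 µm per frame, so shrinkage phases of a
  few µm span only a handful of frames — deliberately, since the analysis
  stage must cope with that.
* **Localization noise SD 0.05 µm**, a diffraction-limited tip-tracking
  scale (also unpublished).
* **Microtubule counts** per condition are chosen so the expected number
  of growth phases matches the published per-condition event counts
  (`fixture_n_microtubules()`), so standard errors are comparable to the
  printed ones.
* Yeast conditions print no shrinkage or rescue columns; fixtures assume a
  porcine-like shrinkage (27.6 µm/min) and zero rescue, and the manifest
  records the assumption.

The generator does **not** emulate: kymograph pixelation or any image
formation, stage drift, uneven illumination, seed-attachment geometry,
microtubule aging (the multi-step catastrophe process that makes real
catastrophe frequency rise with growth time — visible in the published
short/long catastrophe-length asymmetry at 0 nM), motor crowding on the
lattice, or GTP-cap kinetics. Passing parameter-recovery tests therefore
shows that the analysis pipeline is unbiased for the stated generative
model at realistic noise and sampling, not that it is robust to every
artefact of real microscopy data.

## The trace-analysis pipeline and its numerical choices

`segment_traces()` decomposes each trace with a two-stage detector:

1. **Stage 1 — resolvable shrinkage.** Frame-to-frame drops below
   −max(0.2 µm, 4.5σ√2) (σ = noise SD estimated from the median absolute
   lag-1 difference) are flagged; runs of flagged intervals are shrinkage
   phases (a single-interval run must drop 0.3 µm in total). Because a
   true shrinkage step (~0.9 µm/frame) dwarfs the noise, genuine phases
   yield strictly consecutive flagged intervals, and separate runs a few
   frames apart are genuinely separate events (rescue–regrow–catastrophe
   successions).
2. **Stage 2 — sub-frame catastrophes.** A catastrophe whose shrinkage
   fits inside one frame still leaves a *persistent* downward level shift,
   because regrowth restarts from a lower level. These are found by
   recursive binary segmentation of the detrended trace with a two-window
   mean-difference statistic (window 30 frames, threshold 4.2σ of the
   statistic, absolute floor 0.06 µm). Detrending uses a long-lag
   displacement median first (immune to the level shifts being sought),
   then a second pass with the pooled least-squares slope of the clean
   sub-spans, whose error is negligible against the floor.

The absolute floor defines the detector's **resolution**: events whose
total excursion is below ≈ 0.06 µm (about the localization noise SD) are
information-theoretically invisible at these settings. Two consequences
are handled explicitly:

* Phase-slope fits use only frames that provably lie within one phase
  (the interior of shrink runs; growth spans with boundary frames
  dropped). Growth slopes enter the rate average only when fitted over at
  least 6 frames (`min_fit_frames`): fragments of 3–5 frames created
  around transitions carry noise far above the between-phase spread, and a
  kymograph analyst would likewise skip phases too short to measure.
  Durations and event counts still include every segment.
* `estimate_dynamics()` corrects the catastrophe count for sub-resolution
  events: with near-exponential shrinkage excursions the missed fraction
  is $1 - e^{-\delta/x_0}$, with $x_0$ estimated from the truncated-mean
  identity $E[X \mid X > \delta] = \delta + x_0$ on the detected
  excursions (applied only with ≥ 10 detected excursions and capped at
  25%). The reported `missed_fraction` makes the correction visible.

Rescues are distinguished from full depolymerization by the post-event
level (threshold 0.25 µm, checked against the minimum of the following
frames so that a shrinkage continuing after a noisy valley is not
misread); shrinkage running into the end of the record is censored and
produces no terminal event. Pauses are not a phase class: near-zero
slopes stay within their flanking growth phase, and a record with no
events and no resolvable slope is flagged `all_noise`.

**Frequency denominators.** The catastrophe frequency defaults to events
per minute of *growth* (`freq_denominator = "growth_time"`), which is the
definition consistent with the ratio identity distance = rate/frequency
that the published table footnotes state; with shrinkage occupying ~1% of
the observation time the alternative total-time convention differs by less
than the printed precision, and both are implemented. The rescue chain
follows the published construction: rescue distance = total shrinkage
distance / number of rescues, rescue frequency = shrinkage rate / rescue
distance, so the ratio identities hold exactly by construction.

## Fitting choices

* `fit_exponential()` defaults to the censored maximum-likelihood estimate
  (mean = sum of all records / number uncensored), which is the sample
  mean for uncensored data — an identity the tests assert. The histogram
  least-squares mode (optionally excluding the first bin, where short runs
  are under-represented in camera-limited data) reproduces the
  amplitude-and-mean fit used on the published histograms.
* `fit_saturation()` anchors the plateau at the highest-dose response by
  default. On the published growth-rate tables the free 3-parameter
  hyperbola is weakly identified — the top of the dose-response is defined
  by a single highest dose, and the free fit returns a half-max with a
  standard error larger than itself (the tests assert this). Anchoring
  resolves the degeneracy with the data's own endpoint; the free mode is
  retained (`plateau = "free"`) and is the right choice for well-sampled
  synthetic data, where it recovers exact parameters.
* `fit_length_law()` fits the adopted $v(L, c)$ jointly across
  concentrations, weighted by $1/SE^2$. With data at $c = 0$ only,
  $v_{max}$ and $A$ are structurally unidentifiable; the fit degrades to
  the weighted mean rate and is flagged rather than erroring.
* `tubulin_kinetics_regression()` converts the weighted-regression slope
  (µm min⁻¹ µM⁻¹) to a second-order association rate constant with the
  standard lattice packing convention of 1625 dimers per µm (13
  protofilaments × 125 dimers/µm at 8 nm per dimer) — required to
  reconcile speed-per-concentration slopes with printed µM⁻¹ s⁻¹ values.

## Reproducibility

All simulators accept a seed; a root seed expands into per-microtubule
substreams by drawing sub-seeds (`sample.int`) from the root-seeded
stream, so bundles regenerate byte-identically and single trajectories are
reproducible in isolation. The bundle manifest separates assay metadata
(readable by the analysis stage) from generating parameters (never read by
it), which the tests enforce by deleting the generator block before
analysis.

## Problem sizes

The packaged analyses use 10-minute assays with per-condition microtubule
counts matched to the published event counts (roughly 20–90 filaments per
condition, ~300 frames each), 10⁵ trials for the Monte-Carlo reset
process, and 10⁴ single-molecule runs for the exponential fits — sizes at
which every acceptance band (3 standard errors at the published counts) is
resolvable on a laptop in seconds to a few minutes.

## Known limitations

* The detector's resolution means catastrophe statistics in regimes with
  very short excursions (catastrophe distance ≲ 0.5 µm) rely on the
  truncation correction; at the published conditions the correction stays
  below ~8%.
* Shrinkage speeds below ≈ 6 µm/min at the default 2-s frames fall under
  the stage-1 drop threshold and are then only seen as level shifts
  (slopes unresolved); slower sampling intervals should be configured for
  slow-shrinkage data.
* The occupancy model and the explicit $cL$ law are two different closures
  of the same feedback idea; they agree in direction and endpoints but not
  point-for-point, and no measurement here distinguishes them.
* Catastrophe aging (rising hazard with growth time) is intentionally not
  modelled; the homogeneous-Poisson assumption is what the Poisson
  standard-error rule in the published analysis presumes.
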