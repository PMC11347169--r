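---
title: "Kinetic analysis of flow-stretching replication traces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of flow-stretching replication traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowstretch)
library(dplyr)
```

## The measurement

In a flow-stretching assay a single DNA molecule is tethered between a glass
surface and a paramagnetic bead, and laminar flow stretches the tether at a
constant low force (2.6 pN here). Enzymatic activity that converts one form
of DNA into another (primer extension converting ssDNA to dsDNA, a helicase
converting dsDNA to two ssDNA strands) changes the tether's end-to-end
length, and the bead reports that change. Bead position is sampled at 2 Hz.

Two calibrations connect bead displacement to enzymatic progress:

* **Force.** For a tethered bead, the equipartition theorem gives
  `F = kBT * L / Var(y)`, where `L` is the tether extension and `Var(y)` the
  variance of the transverse (perpendicular-to-flow) bead position.
  `equipartition_force()` implements this with mean subtraction (making it
  invariant to the choice of transverse origin) and a bootstrap standard
  error.
* **Elasticity.** Force-extension curves are fitted with the worm-like chain
  interpolation formula
  `F = (kBT/P) (1/(4(1 - x/L)^2) - 1/4 + x/L)`
  (`wlc_force()`, `fit_wlc()`). At the working force the conversion factor
  between displacement and nucleotides is 3.76 nt/nm; it is carried as a
  per-substrate constant by `substrate_geometry()`, together with the sign
  of the bead displacement that enzymatic progress produces on that
  substrate. The default thermal energy is 4.11 pN nm (25 °C); pass
  `kBT_pN_nm = 4.21` for 32 °C work.

A trace in the bp domain is therefore signed enzymatic progress versus time,
with baseline Gaussian noise whose SD is characterized from unreplicated
molecules (`characterize_noise()`). Every baseline category examined has an
SD below 200 bp, and 200 bp is adopted as the spatial resolution: a DNA
length change smaller than that is not reliably observable. If a noisier
instrument produced baseline SDs above 200 bp, the resolution would be the
largest fitted SD rounded up to the next 100 bp — an extension of the rule
beyond the regime the assay actually operates in.

## Segmentation model

The operational definitions are:

* a **pause** is at least six consecutive samples (3 s at 2 Hz) whose
  fluctuations are within the baseline noise and whose slope magnitude is
  below the category threshold rate;
* the **threshold rate** is one tenth of the category's mean rate, rounded
  to one significant figure (0.1 bp/s for slow unwinding, 0.5 bp/s for
  leading-strand synthesis);
* an **event** (activity burst) is a stretch of forward progress of at least
  the spatial resolution whose rate reaches the threshold; its rate is the
  slope of the unsmoothed trace, its single-step processivity the DNA
  length change, its lifetime the duration;
* **multi-step** quantities sum all events of a trace, with interior pauses
  included in the multi-step lifetime but not in single-step lifetimes.

Applying the pause definition literally — scanning for flat runs — is
well-posed only at high signal-to-noise. At the noise level of this assay a
six-sample window rises by about 3 bp at 1 bp/s, against 150 bp of noise:
locally, a slow burst *is* flat. `detect_pauses()` keeps the literal rule
for QC and clean data; `segment_trace()` instead treats segmentation as a
change-point problem, in three stages:

1. **Optimal piecewise-linear partition.** A penalized dynamic program
   (PELT-style pruning, O(1) range least squares from cumulative sums)
   minimizes the sum of per-piece residual SSEs plus `3 sigma^2 log n` per
   breakpoint. A global criterion matters here: the two boundaries of a
   slow burst are individually marginal but jointly decisive, which defeats
   greedy merging or splitting.
2. **Plateau assembly.** Pieces consistent with zero slope and baseline
   noise (chi-square flatness at the 99% level, at least six samples) are
   plateaus; adjacent plateaus whose level gap is below the resolution are
   merged, because a sub-resolution level change is unobservable. What
   remains between plateaus — including bare level jumps faster than one
   sample — is a candidate transition. Transitions containing significant
   slopes of both signs (unwinding followed by re-annealing) are split at
   the sign change.
3. **Continuity-constrained ramp fits.** Each transition is fitted with
   `y(t) = l1 + delta * clamp((t - tau1)/(tau2 - tau1), 0, 1)`, profiling
   the two breakpoints (coordinate descent on the sample grid, then a
   continuous Nelder-Mead polish; bursts faster than one sampling interval
   are reported at that resolution limit). The clamped model carries its
   own plateaus, so the fit pins the event's size (`delta`, the plateau
   level difference) and rate (`delta / (tau2 - tau1)`) even where the
   partition merged an event with its neighboring baseline. This matters
   quantitatively: breakpoints of a *discontinuous* piecewise-linear fit
   jitter by many samples at this noise level, and a free level offset lets
   the fit absorb that jitter, which systematically dilutes slopes toward
   zero. Continuity removes the offset and with it the bias. One exception:
   for bursts spanning at most eight samples the breakpoint-interval rate
   is multiplicative in a noisy fitted duration and badly right-skewed, so
   such bursts report the OLS slope over their samples plus one flanking
   sample on each side instead — additive noise, anchored by the plateau
   levels, and markedly tighter against simulated truth.

A transition whose fitted `|delta|` falls below the resolution, or whose
rate falls below the threshold, dissolves into the surrounding flat.
Surviving transitions become events; negative-progress transitions after
the final event on the shortening-unwinding substrate become re-annealing.
Flat stretches bracketed by events on both sides and satisfying the pause
rules are pauses; all other flats are baseline. Segments tile the trace
exactly.

One more pass handles restarts that the partition missed: if a fitted event
contains an interior run satisfying the pause rules, the event is split and
each half is re-fitted against the interior flat, but only when the
two-ramp model lowers the SSE by more than `4 sigma^2 log n` (the partition
penalty for the extra breakpoints). Without that guard, short runs that
merely look flat inside a genuine continuous ramp — at this SNR a ~25 s
stretch of a 5 bp/s ramp passes any flatness test — would shred real
events. When both halves of an accepted split fall below the resolution the
whole region dissolves: the interior pause is real, so the region is two
unobservable changes, not one event.

The two-pass threshold procedure (`two_pass_segment()`) first segments with
a threshold of zero, where events need only a statistically significant
level change and plateaus a statistically insignificant slope, collects all
event rates, fits a Gaussian to their histogram, derives the category
threshold by the one-tenth rule, and re-segments. On simulated
leading-strand ensembles the recovered threshold is the working 0.5 bp/s.

## Ensemble statistics

Rates are summarized by a nonlinear least-squares Gaussian fit to the rate
histogram (`fit_rate_gaussian()`, default bin width mean/8), with the
sample mean and SD reported alongside; for heavy-tailed conditions the
arithmetic mean is reported separately (`arithmetic_rate()`) and can exceed
the Gaussian peak several-fold. The headline rate estimate is guarded
(`robust_rate_mean()`): the unconstrained histogram fit is accepted only
when its mean lies within the central 10-90% of the sample, and the sample
median takes over otherwise — contaminated rate samples can otherwise
drive the fit arbitrarily far, including below zero.

Processivities, lifetimes, and pause durations are summarized by
`fit_exponential()`, which excludes observations and histogram bins below
the observability cutoff — the spatial resolution for length changes, 3 s
for durations — because events there are censored by the baseline noise.
Two estimators of the decay constant are computed. The *reported* value is
the left-truncated maximum-likelihood estimate
`mean(x - cutoff | x >= cutoff)`, which is unbiased for exponential data at
any cutoff (memorylessness) and, in simulation at this assay's ensemble
sizes (30-150 observations), carries roughly half the sampling variance of
the alternative. The binned least-squares fit of `A exp(-x/mu)` to the
first-bin-excluded histogram is fitted alongside (`lsq_mean`) as a shape
cross-check; the two agree within 15% on clean exponential samples of
n >= 100, and a large disagreement flags non-exponential structure.
Restart-pause durations are left-bounded at 3 s by the pause definition, so
their reported mean is `3 s + decay constant` (the shifted-exponential
mean); unshifted quantities report the decay constant itself.

`summarize_condition()` assembles these fits into one row per condition
together with the restart fraction (traces with at least two events among
traces with at least one), and `compare_conditions()` aligns conditions
with fold changes against a reference.

## The simulator

`simulate_trace()` generates traces from an explicit kinetic model: a
leading baseline; then bursts whose lengths are exponential (mean
`proc_mean`, clamped to the remaining template) and whose rates are drawn
per burst from a truncated normal (or a normal-plus-exponential-tail
mixture for the fork-protection-complex condition); after each burst the
complex restarts with probability `p_restart` after a pause drawn as
`3 s + Exp(pause_mean - 3)`, and otherwise terminates; on the bare-fork
substrate termination is followed by re-annealing back to the start level.
The bp-domain path is sampled at 2 Hz, i.i.d. Gaussian noise is added, and
the geometry maps progress to bead displacement. Ground-truth intervals are
recorded so segmentation can be validated against them. Ensembles derive
per-trace seeds from a master seed in one documented step
(`sample.int` after `set.seed(master)`), so trace *i* is reproducible on
its own.

Choices where the measured conditions leave freedom, fixed once and not
revisited:

* Per-burst rate SD is 0.3 x the mean for every preset; published
  histograms constrain the means tightly but not the widths.
* The pause-duration family is a 3 s-shifted exponential, consistent with
  the 3 s detection limit; restart is Bernoulli per stop, making burst
  counts geometric.
* Baseline noise is i.i.d. Gaussian with SD 150 bp for every preset
  (every measured baseline SD lies below the 200 bp resolution).
* Re-annealing on the bare-fork substrate proceeds at 5 bp/s, fast enough
  to be visually distinct from unwinding.
* The heavy tail of the FPC rate mixture is `mean + Exp(80 bp/s)` with
  weight 0.25, which reproduces the qualitative signature of that
  condition: an arithmetic mean several-fold above the Gaussian peak.
* Template lengths are 7.2 knt (circular phage template), 13.5 kb
  (bare-fork and SSB substrates), and 7 kb (RPA-compatible substrates).

What the generator does *not* emulate: drift or slow baseline wander
(an optional linear drift is deliberately omitted from defaults),
correlated noise from bead-flow coupling, tracking artifacts, multiple
tethers, or sequence-dependent kinetics. Passing tests therefore show that
the analysis recovers parameters under the stated statistical structure,
not that it is robust to every pathology of real instruments.

The MST module simulates a 16-point two-fold titration from 250 nM final
(a 500 nM top stock mixed 1:1 with 20 nM labeled target) and fits the
ligand-depletion (quadratic) isotherm
`FB = ((K + A + T) - sqrt((K + A + T)^2 - 4 A T)) / (2T)`,
the appropriate form when the labeled-target concentration (20 nM) is
comparable to the dissociation constant (single-digit nM). Plateau signals
are free parameters by default and can be fixed.

## Numerical choices

* Range OLS statistics come from cumulative sums; the flatness and noise
  floors use `max(noise_sd, 0.05)` bp so that noise-free traces remain
  well-posed against floating-point rounding.
* The partition penalty is `3 sigma^2 log n` per breakpoint and the
  interior-split guard `4 sigma^2 log n`; both were calibrated on simulated
  ensembles with known truth — the partition penalty against spurious
  breakpoints in pure-noise baselines, the split guard against false
  interior pauses inside continuous ramps (details above).
* Nonlinear fits use Levenberg-Marquardt (`minpack.lm::nlsLM`) with
  analytic-free starts taken from sample statistics; degenerate inputs
  (constant rates, flat MST curves, all-censored values) raise errors
  rather than returning numbers.
* Histogram fits evaluate the model at bin centers; for the exponential
  this is exact up to a constant factor absorbed in the amplitude.

## Known limitations

* **Censoring couples the observables.** About half of the bursts in the
  leading-strand conditions fall below the 200 bp resolution. Such bursts
  are invisible, so a measured inter-event pause can span pause + invisible
  burst + pause. With the generative pause mean set to the measured 182 s,
  the *measured* restart-pause mean on simulated data is ~250-300 s. This
  is a structural property of analyzing near-resolution kinetics, not a
  segmentation defect — recovering 182 s would require every burst to be
  observable. The same censoring is why apparent single-step processivity
  fits recover the decay constant (via first-bin exclusion) while apparent
  rates carry a few-percent dilution from sub-resolution restarts, and it
  is the reason the assay's own kinetics are reported as "apparent"
  throughout.
* Measured event rates are diluted by a few percent when a restart pause
  shorter than the split guard can resolve hides inside an event; Gaussian
  rate fits on simulated leading-strand ensembles recover the generative
  mean to within about 10%, most of which is this effect.
* Problem sizes in the test-suite and in the reproduction script follow the
  study's event and trace counts (51-151 events, 39-120 traces, five
  replicate master seeds), which keeps every stage's statistical error
  within the stated recovery tolerances.
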