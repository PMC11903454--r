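---
title: "Self-organized positioning of peristaltic wave origins: model and methods"
author: "peristalsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organized positioning of peristaltic wave origins: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peristalsim)
```

## The model

`peristalsim` treats the embryonic caecum as a one-dimensional chain of
resettable integrate-and-fire contraction clocks coupled by finite-range
stochastic waves, with a slow activity-dependent adaptation of each clock's
period. Three processes, on three timescales:

1. **Latent rhythm (minutes).** Region $i$ accumulates phase $\phi_i$ at
   unit rate and contracts spontaneously when $\phi_i$ reaches its latent
   period $T_i$ — the intrinsic inter-contraction interval this region would
   exhibit in isolation. Cycle-to-cycle variability is multiplicative
   lognormal noise on the period (cv 0.05 by default), redrawn whenever the
   clock restarts; without some jitter a fully entrained region would
   never escape, whereas intact preparations show rare spontaneous
   contractions in suppressed regions.
2. **Waves and phase resetting (seconds).** A spontaneous ("active")
   contraction launches a wave in both directions. The wave advances one
   region per conduction delay (default 1 s/region — the value only needs to
   be far below the shortest latent period, so that event ordering rather
   than conduction speed shapes the dynamics) and crosses each inter-region
   boundary independently with survival probability $q$, giving a truncated
   geometric range with closed-form mean $(1-q^L)/(1-q)$
   (`expected_range()`, inverted by `calibrate_survival()`). On arrival the
   wave forces a "passive" contraction and resets the host clock partially:
   $\phi \to (1-\rho)\,\phi$. Experimentally induced ("forced")
   contractions — a mechanical tap, an optogenetic pulse — behave like wave
   arrivals; optogenetic firings additionally launch waves, a tap on an
   isolated fragment does not.
3. **Adaptation (days).** The current period relaxes with first-order
   kinetics (time constant `timescale_h`, default 24 h) toward
   $T_i\,(1 + k\,r)$, capped at `period_ceiling_factor` (default 2) times
   baseline, where $r$ is the exponentially averaged recent passive+forced
   contraction rate (window 1 h). This is the long-term suppression law —
   the more passing waves a region experiences, the slower the rhythm it
   acquires — and it recovers to baseline when exposure ceases. Only
   passive and forced contractions drive $r$; whether a region's own active
   contractions also contribute is unresolved experimentally, and the
   passive+forced reading is the mechanistically minimal one (adaptation as
   a response to *imposed* stretch).

Entrainment ("macroscopic lateral inhibition") is emergent: with full reset
($\rho=1$) and reliable conduction, a uniquely fastest clock resets all its
neighbours every cycle before they can fire, so it remains the only source
of active contractions and every region contracts at the winner's rate.
This winner-take-all theorem is checked in the test suite against an
independent fixed-time-step (0.01 s) reference simulator on randomized
chains.

### Partial versus complete reset

The idealized model says a forced contraction makes the clock "count from
zero" ($\rho = 1$), yet the measured prolongation of the interrupted
interval is 30.75 s for a tap delivered 40 s into the cycle — a shortfall
compatible with partial resetting, measurement noise, or phase-dependent
resetting; the data do not distinguish these. The package therefore makes
the reset efficacy a parameter: the default $\rho = 30.75/40 = 0.76875$
reproduces the measured mean delay exactly in the noise-free tap protocol
(`run_tap()`), and $\rho = 1$ reproduces the idealized cartoon. The delay
equals $\rho \times$ offset independently of the latent period.

## Stage calibration

Only a handful of quantitative anchors exist, all honoured by the presets
(`stage_preset("e9" | "e10" | "e12")`):

| anchor | value | preset mechanism |
|---|---|---|
| intact P1 OPW rate | 8.9 (E9), 26 (E10), 59.6 (E12) per h | P1 latent period, minus a small offset compensating resets by rare proximally travelling escape waves |
| intact P2 rate | 4.1 (E9), 4.4 (E10), 1.2 (E12) per h | escape events on cycles where the P1-origin wave fails its first boundary: rate $\approx$ P1 rate $\times (1-q_{P1})$ |
| P2 rate after P1 removal (E12) | 35.6 per h | P2 latent period (94.5 s, i.e. its latent rate net of resets by distal waves) |
| P1-origin mean range (E10) | over 4.6 regions | $q_{P1}$(E10) from `calibrate_survival(4.8, 8)`, representing "over 4.6" |
| other-origin range | 2–3 regions | chain-level survival 0.61 (E10/E12), 0.50 (E9) |

Two consequences of this calibration are worth making explicit. First, the
E12 P1-origin survival is pinned by the intact P2 escape rate
($q = 1 - 1.2/59.6 = 0.98$), not by range data, which exist only for E10;
we read the difference as maturation of conduction between E10 and E12.
Second, the anchors are mutually in tension: an isolated P2 interval of
roughly 50 s (~72/h) is quoted in the tap experiment, while the
post-P1-removal rate is 35.6/h. The presets prioritize the explicitly
printed rates, so the E12 P2 latent period is 94.5 s; the tap protocol's
delay statistic is unaffected, since it does not depend on the period.

Latent periods of regions without printed anchors are interpolated
assumptions, chosen slowest in the mid-chain where passing-wave exposure is
highest (the complementary-gradient picture) and fastest at the endpoints.
With those defaults the intact E10/E9 P2 rates come out ~20% below their
printed anchors (about 3.5 vs 4.4 per h at E10): escape waves from
mid-chain regions occasionally reset P2 during exactly the P1-wave gaps
that would otherwise let it fire. We accepted this residual rather than
suppressing mid-chain activity entirely, which would contradict the
observation that low-frequency waves do originate outside P1 at E10.

```{r calibration-check}
rates <- run_intact(stage_preset("e12", seed = 1), duration_h = 1)$rates
as.data.frame(rates)
```

## Numerical implementation

The simulator (`simulate_chain()`) is event-driven: the next event is the
minimum over scheduled spontaneous firings, wave-front arrivals and forced
stimuli; ties are broken stimulus-first, then arrivals, then firings, in
region order, so runs are deterministic given `(config, seed, stimuli)`.
All randomness (jitter draws, per-boundary survival Bernoulli trials) comes
from one seeded stream, and the caller's RNG state is restored afterwards.

Degenerate-input conventions:

* **Refractoriness.** A region cannot contract twice within `refractory_s`
  (default 5 s). A wave arriving during refractoriness records no event and
  applies no reset but continues propagating — terminating it would make a
  wave's range depend on unrelated recent activity and double-counting
  artifacts would follow. A spontaneous firing falling inside the
  refractory window is postponed to its end.
* **Collisions.** Two fronts meeting head-on annihilate (default): a front
  dies if it enters a region visited by an opposite-direction front within
  the last 1.5 conduction delays, the behaviour expected of excitable
  tissue with a refractory wake. `pass_through` is available for
  sensitivity analyses. Conduction velocity and collision behaviour are not
  experimentally constrained; both are declared modelling choices.
* **Adaptation integration.** Between events the exposure estimate decays
  exponentially; the period multiplier is advanced with the exact solution
  of the first-order relaxation under a piecewise-constant target evaluated
  at each inter-event interval's start. With a one-day time constant and
  sub-minute event spacing the discretization error is negligible, and the
  closed form is cross-checked in the tests against 0.01-h Euler
  integration.
* **Bisection tolerance.** `calibrate_survival()` bisects the monotone
  closed-form mean range to an absolute tolerance of 1e-9.

The independent reference engine (`simulate_chain_stepwise()`) advances on
a fixed 0.01-s grid. It is deliberately restricted to configurations where
the two engines' random draws coincide trivially (no jitter, survival 0 or
1, no adaptation): on those the engines must agree event-for-event within
one step, and the tests enforce this on randomized chains. Stochastic
survival is validated differently, against the enumerated truncated
geometric distribution.

## Synthetic recordings and the measurement chain

`events_to_trace()` renders an event log as 1-Hz per-region intensity
series, emulating the video-derived recordings: each contraction adds a
raised-cosine transient (width 6 s, amplitude 1), plus sinusoidal baseline
drift (period 600 s, amplitude 0.5, region-shifted phase) and Gaussian
noise (sd 0.1, i.e. amplitude/noise = 10). The transient shape, width and
drift are declared fixture choices — nothing is known about the true pulse
morphology — so round-trip results validate the *pipeline*, not the
recordings. Real recordings additionally contain motion artifacts,
amplitude variability between contractions, and non-stationary drift, none
of which are modelled; passing the round-trip tests therefore shows the
analysis chain is internally consistent at the stated SNR, not that it
would perform identically on real video.

`detect_contractions()` removes the baseline (piecewise-linear segments of
~100 s by default; segments are equal-length so no short trailing stub can
absorb a transient into its own trend), standardizes, and keeps local
maxima above 3 standardized units separated by at least 4 s (just under the
5-s refractory period). These defaults come from a fixture SNR study: at
the default SNR the detector recovers event counts exactly, and recall
degrades monotonically as noise grows (asserted in the tests). The peak
primitive is `pracma::findpeaks()`. `assign_waves()` then chains detections
across adjacent regions whose lags match the conduction delay within a
tolerance (default 1.5 s, accommodating 1-Hz quantization), greedily and
nearest-in-time with monotone arrival order; the earliest event of a chain
is the origin (active), the rest passive. On intact-chain bundles this
recovers ≥95% of active/passive labels and ≥90% of wave origins.

`estimate_delay()` excludes detections within 3 s of the known tap time
(the forced transient itself), then takes $T$ as the mean of up to three
control intervals preceding the interrupted cycle and $\tau$ as the
interval spanning the tap. `paired_t()` implements the classical paired
t statistic, with the documented conventions $t=0, p=1$ for identically
zero differences and $t=\pm\infty, p=0$ for constant nonzero differences
(base `t.test()` refuses constant data, which the protocols can produce).

## Protocol replicas and problem sizes

* `run_intact()` / `run_fragments()` — whole-chain monitoring vs
  single-region isolation. Fragmentation unveils every region's latent
  rhythm; with survival 0 the intact chain and the fragments coincide
  exactly.
* `run_ablated()` — contiguous removal from one end (mirroring surgery);
  removing P1 at E12 releases P2 to ~35.6 contractions/h within the run.
* `run_tap()` — interruption of an isolated fragment; `T` is measured on
  the cycles preceding the tap (three by default), matching a
  within-specimen before/after comparison.
* `run_paced()` — periodic forced firing (default cadence 30 s) that
  launches waves; pulses start half an interval in so an hour of pacing at
  30 s delivers exactly 120 waves downstream when conduction is reliable.
* `run_development()` — multi-day culture with adaptation, optional
  ablation or pacing, then a fragment assay of the acquired latent rate
  over 1 h after a 10-min settling period (the post-dissection
  equilibration of the real assay, abstracted to a parameter). The assay
  fragment inherits the adapted period as its baseline, freezing further
  adaptation during the 1-h readout — recovery over 1 h would in any case
  be ~4% of the acquired change given the one-day time constant.

Paired designs reuse one seed for control and intervention so differences
isolate the intervention. Figure-level magnitudes of the multi-day
experiments are not reproducible as numbers (they were reported only
graphically), so the suite asserts directions and orderings: ablation of
P1–P2 lowers D2's wave exposure and raises its acquired rate in every pair,
pacing does the reverse, and acquired rate relates rank-negatively to
exposure.

Problem sizes were chosen to keep the full suite and the acceptance script
comfortably small while leaving the statistics well-resolved: 10-h windows
for rate anchors (the escape statistic P2 ≈ 1.2/h is a rare-event count, so
a 10-h window carries Poisson-scale spread of ±0.3/h around its calibrated
expectation), a 45-h E10 run for the ≥1,000-wave range census, three-day
cultures for adaptation protocols, and 1-h bundles for the
detection round-trips.

## Known limitations

* The chain is 1-D with equal-sized regions; no tissue geometry, smooth
  muscle biophysics, interstitial-cell network structure or molecular
  signalling.
* Conduction delay, collision behaviour and the adaptation functional form
  are modelling choices constrained only by sign/timescale information.
* Latent periods of non-anchored regions are interpolated assumptions, and
  the intact E9/E10 P2 rates sit ~20% below their soft anchors (see
  calibration section).
* The synthetic traces are a fixture, not a model of the recordings'
  optics; detector defaults are fixture-derived, not reconstructions of the
  original analysis settings.
* Only the excised caecum is modelled; interactions with the attached
  intestinal tract are out of scope.
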