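# peristalsim

Event-driven simulation and analysis of how **origins of peristaltic waves
(OPWs)** become positioned along the embryonic chicken caecum.

## The scientific problem

When peristalsis first emerges in the embryonic gut, contraction waves arise
at randomly scattered sites; by later stages they are generated almost
exclusively at specific locations (in the caecum, its endpoints). Every
region of the caecum in fact possesses its own *latent rhythm* — an intrinsic
spontaneous contraction frequency unveiled when the region is cut free — so
the question is how an initially uniform chain of autonomous contraction
clocks organizes itself into a sharp spatial pattern of wave origins.

`peristalsim` formalizes the two-step self-organization account of this
patterning as a quantitative model and provides in-silico replicas of the
experiments that probe it:

1. **Long-term suppression by passing waves.** Waves propagating over a
   region force *passive* contractions there, and the more passing waves a
   region experiences, the slower the latent rhythm it acquires (a slow,
   activity-dependent lengthening of its intrinsic period, over days).
   Because wave exposure peaks in the mid-chain, this carves a spatial
   gradient of latent rhythm that is complementary to the wave-exposure
   gradient.
2. **Macroscopic lateral inhibition by entrainment.** A forced contraction
   resets the host region's clock, so a region with a faster clock
   continuously resets its slower neighbours before they can fire: the
   fastest clock survives as the winner (the OPW), and the neighbours'
   latent rhythms stay masked (seconds-to-minutes timescale).

## The model

A caecum is a 1-D chain of regions (P1–P3, D1–D5 at E10/E12; P1–P2, D1–D4 at
E9). Region *i* is a resettable integrate-and-fire clock: phase `phi_i`
accumulates at unit rate and the region contracts spontaneously ("active"
contraction, an OPW generation) when `phi_i` reaches its latent period `T_i`
(with lognormal cycle-to-cycle jitter, cv 0.05). An active contraction
launches a bidirectional wave that advances one region per conduction delay
and crosses each boundary independently with survival probability `q` (so
the propagation range is truncated-geometric with mean `(1 - q^L)/(1 - q)`).
A wave arriving at a region forces a passive contraction and a *partial
phase reset*

    phi  ->  (1 - rho) * phi,      rho = 0.76875 by default,

which delays the region's next spontaneous firing by `rho * phi` — 30.75 s
for a stimulus delivered 40 s into the cycle, with `rho = 1` available as
the idealized count-from-zero reset. Passive and forced contractions also
drive the slow adaptation law: the current period relaxes (time constant
~1 day) toward `T_i * (1 + k r)`, capped at twice baseline, where `r` is the
recent passive+forced contraction rate. Stage presets (`e9`, `e10`, `e12`)
are calibrated so intact simulations reproduce the observed stage-wise
hourly OPW rates (P1: 8.9 → 26 → 59.6 per h, P2 falling to ~1.2 per h at
E12), the release of P2 to ~35.6 per h when P1 is removed, and the >4.6-region
mean range of P1-origin waves at E10.

The package also synthesizes 1-Hz per-region intensity recordings from event
logs (raised-cosine transients, baseline drift, Gaussian noise) and
implements the measurement chain used on such recordings: detrending +
standardized peak detection, wave reconstruction across regions,
active/passive classification, rate and propagation-range summaries,
interruption-delay estimation, and paired t statistics.

## Worked example

```r
library(peristalsim)

cfg <- stage_preset("e12", seed = 1)
res <- run_intact(cfg, duration_h = 1)
print(res$sim)
#> caecum_sim: stage E12, 8 regions, 1 h simulated, seed 1
#> events: 465 (active 63, passive 402); waves launched: 63
print(as.data.frame(res$rates), row.names = FALSE)
#>  label active_per_h passive_per_h forced_per_h total_per_h
#>     P1           59             0            0          59
#>     P2            1            58            0          59
#>     P3            0            59            0          59
#>     D1            0            58            0          58
#>     D2            0            58            0          58
#>     D3            0            57            0          57
#>     D4            0            57            0          57
#>     D5            3            55            0          58
```

P1, the fastest clock, generates ~59 OPWs per hour; its waves force ~58
passive contractions per hour everywhere else, masking those regions' latent
rhythms (P2 escapes only once in this hour). Removing P1 releases P2:

```r
rel <- run_ablated(cfg, "P1", duration_h = 10)$rates
rel$active_per_h[rel$label == "P2"]
#> [1] 35.5
```

And a mechanical tap delivered 40 s into an isolated fragment's cycle delays
its next spontaneous contraction by `rho * 40`:

```r
p2 <- stage_preset("e12")$regions[2, ]
run_tap(region_params(0, "P2", p2$latent_period_s, jitter_cv = 0), 40)
#> tap interruption: T = 94.50 s, tau = 125.25 s, delay = 30.75 s (tap at +40.0 s)
```

Longer-horizon protocols (`run_development`, `run_paced`) expose the slow
adaptation step, and `generate_bundle()` + `detect_contractions()` +
`assign_waves()` give an end-to-end synthetic-recording analysis pipeline. A
command-line wrapper is installed at `inst/cli/peristalsim` with subcommands
`simulate`, `fragment`, `ablate`, `tap`, `pace`, `develop`, `synth`,
`analyze` and `calibrate`.

See `vignettes/opw-patterning.Rmd` for the full model description,
parameter meanings, calibration rationale and limitations.

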