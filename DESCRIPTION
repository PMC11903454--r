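Package: peristalsim
Title: Self-Organized Positioning of Peristaltic Wave Origins in the Embryonic Gut
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation and analysis of how origins of peristaltic
    waves (OPWs) become positioned along the embryonic chicken caecum. Models
    each gut region as a resettable integrate-and-fire contraction clock with a
    region-intrinsic latent rhythm, couples the chain through finite-range
    stochastic passing waves that phase-reset the regions they traverse
    (macroscopic lateral inhibition by entrainment), and adds slow
    activity-dependent lengthening of the latent period driven by passing-wave
    exposure. Includes in-silico replicas of fragmentation, ablation,
    tap-interruption, optogenetic-pacing and multi-day development protocols; a
    synthetic 1-Hz intensity-trace generator emulating video-derived recordings;
    and a measurement chain (peak detection, wave reconstruction, active/passive
    classification, rate and propagation-range summaries, interruption-delay
    estimation, paired t statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
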