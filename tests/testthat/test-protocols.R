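test_that("a fully decoupled chain behaves as its fragments", {
  cfg <- stage_preset("e12", seed = 3,
                      overrides = list(jitter_cv = 0,
                                       coupling = list(survival_prob = 0),
                                       adaptation = list(gain_k = 0)))
  cfg$regions$survival_prob <- 0
  intact <- run_intact(cfg, 1)$rates
  frags <- run_fragments(cfg, 1)
  expect_equal(as.data.frame(intact), as.data.frame(frags),
               ignore_attr = TRUE)
  expect_true(all(intact$passive_per_h == 0))
})

test_that("fragmentation unveils a nonzero latent rhythm in every region", {
  for (stage in c("e9", "e10", "e12")) {
    rates <- run_fragments(stage_preset(stage, seed = 2), 1)
    expect_true(all(rates$active_per_h > 0), info = stage)
  }
  # noise-free fragments tick at exactly their latent rate
  cfg <- stage_preset("e12", seed = 1, overrides = list(jitter_cv = 0))
  rates <- run_fragments(cfg, 1)
  expect_equal(rates$active_per_h,
               floor(3600 / cfg$regions$latent_period_s))
  # P1 faster than P2, D5 faster than D4 (as observed at E12)
  expect_gt(rates$active_per_h[rates$label == "P1"],
            rates$active_per_h[rates$label == "P2"])
  expect_gt(rates$active_per_h[rates$label == "D5"],
            rates$active_per_h[rates$label == "D4"])
})

test_that("ablation protocol validates removals and reduces to intact when empty", {
  cfg <- stage_preset("e12", seed = 4)
  whole <- run_intact(cfg, 1)
  none <- run_ablated(cfg, character(0), 1)
  expect_identical(whole$sim$events, none$sim$events)
  expect_error(run_ablated(cfg, "P2", 1), "contiguous")
  expect_error(run_ablated(cfg, c("P1", "P3"), 1), "contiguous")
  # removing all but one region leaves that region at its latent rate
  cfg0 <- stage_preset("e12", seed = 4, overrides = list(jitter_cv = 0))
  solo <- run_ablated(cfg0, c("P1", "P2", "P3", "D1", "D2", "D3", "D4"), 1)
  expect_equal(solo$rates$active_per_h,
               floor(3600 / cfg0$regions$latent_period_s[8]))
})

test_that("removing P1 releases P2 from entrainment", {
  cfg <- stage_preset("e12", seed = 6)
  intact <- run_intact(cfg, 2)$rates
  released <- run_ablated(cfg, "P1", 2)$rates
  p2_intact <- intact$active_per_h[intact$label == "P2"]
  p2_released <- released$active_per_h[released$label == "P2"]
  expect_lt(p2_intact, 5)
  expect_gt(p2_released, 30)
})

test_that("tap protocol reproduces the reset law", {
  p <- 101.1
  frag <- function(rho) region_params(0, "P2", p, jitter_cv = 0,
                                      reset_efficacy = rho)
  expect_equal(run_tap(frag(1), 40)$delay_s, 40)
  expect_equal(run_tap(frag(0), 40)$delay_s, 0)
  est <- run_tap(frag(0.76875), 40)
  expect_equal(est$delay_s, 30.75)
  expect_equal(est$tau_s, est$T_s + 30.75)
  # delay is independent of the latent period in noise-free mode
  slow <- region_params(0, "X", 250, jitter_cv = 0, reset_efficacy = 0.76875)
  expect_equal(run_tap(slow, 40)$delay_s, 30.75)
  expect_error(run_tap(frag(1), 150), "tap_offset_s")
})

test_that("periodic pacing delivers waves to the observer at the pacing rate", {
  # pacer R2 drives R1 and R3; all clocks too slow to interfere
  cfg <- make_chain(c(10000, 9000, 11000), survival = 1, rho = 1)
  res <- run_paced(cfg, "R2", 30, 1, "R3")
  expect_equal(res$passing_per_h, 120)
  expect_equal(res$rates$passive_per_h[res$rates$label == "R3"], 120)
  expect_equal(res$rates$forced_per_h[res$rates$label == "R2"], 120)
  expect_error(run_paced(cfg, "R2", 30, 1, "R2"), "distinct")
  expect_error(run_paced(cfg, "R2", 2, 1, "R3"), "refractory")
})

test_that("development protocol: adaptation is driven by passing-wave exposure", {
  cfg <- stage_preset("e10", seed = 8)
  # disabling adaptation makes ablation irrelevant for the acquired rate
  cfg0 <- stage_preset("e10", seed = 8,
                       overrides = list(adaptation = list(gain_k = 0)))
  d_ctrl0 <- run_development(cfg0, 1, assay_label = "D2")
  d_abl0 <- run_development(cfg0, 1, ablate_labels = c("P1", "P2"),
                            assay_label = "D2")
  expect_equal(d_ctrl0$adapted_period_s, d_abl0$adapted_period_s)
  # with adaptation on, less exposure -> shorter acquired period
  d_ctrl <- run_development(cfg, 1, assay_label = "D2")
  d_abl <- run_development(cfg, 1, ablate_labels = c("P1", "P2"),
                           assay_label = "D2")
  expect_lt(d_abl$passing_per_h, d_ctrl$passing_per_h)
  expect_lt(d_abl$adapted_period_s, d_ctrl$adapted_period_s)
  expect_error(run_development(cfg, 1, ablate_labels = "D2",
                               assay_label = "D2"), "assay")
})

test_that("removing the proximal pacemakers releases P3 (compensatory OPWs)", {
  for (seed in c(2, 9)) {
    cfg <- stage_preset("e10", seed = seed)
    p3_intact <- run_intact(cfg, 2)$rates
    p3_abl <- run_ablated(cfg, c("P1", "P2"), 2)$rates
    expect_gt(p3_abl$active_per_h[p3_abl$label == "P3"],
              p3_intact$active_per_h[p3_intact$label == "P3"])
  }
})
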