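test_that("an uncoupled noise-free clock fires exactly floor(D/T) times", {
  cfg <- make_chain(50)
  s <- simulate_chain(cfg, 3600)
  expect_equal(nrow(s$events), 72)
  expect_true(all(s$events$kind == "active"))
  expect_equal(s$events$time_s, seq(50, 3600, by = 50))
  for (T in c(37, 101.1)) {
    s2 <- simulate_chain(make_chain(T), 3600)
    expect_equal(nrow(s2$events), floor(3600 / T))
  }
})

test_that("a faster region fully entrains a slower neighbour (vs stepwise oracle)", {
  cfg <- make_chain(c(50, 100))
  s <- simulate_chain(cfg, 1000)
  o <- simulate_chain_stepwise(cfg, 1000)
  byk <- function(e) table(e$region_label, e$kind)
  expect_equal(byk(s$events), byk(o$events))
  # identical event sequence within one oracle step
  expect_equal(s$events$kind, o$events$kind)
  expect_lt(max(abs(s$events$time_s - o$events$time_s)), 0.02)
  # the slow region never fires actively after region 0's first cycle
  r2 <- s$events[s$events$region_label == "R2", ]
  expect_true(all(r2$kind == "passive"))
})

test_that("winner-take-all entrainment holds on randomized separated chains", {
  for (seed in 1:4) {
    n <- sample(3:8, 1)
    cfg <- make_separated_chain(n, seed = seed * 17)
    periods <- cfg$regions$latent_period_s
    t_fast <- min(periods)
    burn <- max(periods) + n * cfg$coupling$conduction_delay_s
    horizon <- burn + 20 * t_fast
    s <- simulate_chain(cfg, horizon)
    late <- s$events[s$events$time_s > burn, ]
    act <- late[late$kind == "active", ]
    expect_true(all(act$region_label == cfg$regions$label[which.min(periods)]),
                info = paste("seed", seed))
    # every region contracts at the fastest intrinsic rate
    counts <- table(factor(late$region_label, levels = cfg$regions$label))
    expect_true(all(abs(as.integer(counts) - 20) <= 1),
                info = paste("seed", seed))
    # the stepwise oracle reproduces the same event log
    o <- simulate_chain_stepwise(cfg, horizon)
    expect_equal(nrow(o$events), nrow(s$events))
    expect_lt(max(abs(o$events$time_s - s$events$time_s)), 0.02)
  }
})

test_that("event-driven and fixed-step engines agree on random deterministic configs", {
  for (seed in 1:4) {
    set.seed(seed * 31)
    n <- sample(3:8, 1)
    periods <- sample(seq(40, 200, by = 7), n)
    rhos <- round(stats::runif(n, 0.3, 1), 2)
    survs <- sample(c(0, 1), n, replace = TRUE)
    regions <- lapply(seq_len(n), function(i)
      region_params(i - 1L, paste0("R", i), periods[i], jitter_cv = 0,
                    reset_efficacy = rhos[i], refractory_s = 5,
                    survival_prob = survs[i]))
    cfg <- chain_config("rand", regions,
                        coupling = coupling_params(survival_prob = 0),
                        adaptation = adaptation_params(gain_k = 0),
                        seed = seed)
    s <- simulate_chain(cfg, 400)
    o <- simulate_chain_stepwise(cfg, 400)
    expect_equal(table(s$events$region_label, s$events$kind),
                 table(o$events$region_label, o$events$kind),
                 info = paste("seed", seed))
    expect_lt(max(abs(s$events$time_s - o$events$time_s)), 0.02)
  }
})

test_that("event and wave logs are mutually consistent", {
  cfg <- stage_preset("e10", seed = 5)
  s <- simulate_chain(cfg, 2 * 3600)
  ev <- s$events
  # every active event launches exactly one wave (no stimuli here)
  expect_equal(sum(ev$kind == "active"), nrow(s$waves))
  # passive events tally with per-wave passive counts
  expect_equal(sum(ev$kind == "passive"), sum(s$waves$n_passive))
  # each passive event's wave visits its region
  pas <- ev[ev$kind == "passive", ]
  w <- s$waves[match(pas$wave_id, s$waves$wave_id), ]
  expect_true(all(pas$region_index >= w$prox_reach &
                    pas$region_index <= w$dist_reach))
  # refractory gap holds per region
  for (lab in cfg$regions$label) {
    tt <- sort(ev$time_s[ev$region_label == lab])
    if (length(tt) > 1)
      expect_gte(min(diff(tt)), cfg$regions$refractory_s[1])
  }
})

test_that("with a single wave source, every wave converts range - 1 passive contractions", {
  # only region 1 is active (others far slower), survival 1: no collisions,
  # no refractory skips, so the conservation law holds exactly
  cfg <- make_chain(c(60, rep(5000, 4)))
  s <- simulate_chain(cfg, 3610)  # margin lets the final wave complete
  w <- s$waves[s$waves$origin_label == "R1", ]
  expect_true(all(w$n_passive == w$range - 1))
  expect_true(all(w$range == 5))
})

test_that("zero reset efficacy decouples rates from wave traffic", {
  periods <- c(50, 70, 90)
  cfg <- make_chain(periods, survival = 1, rho = 0, refractory = 0)
  s <- simulate_chain(cfg, 3600)
  act <- table(factor(s$events$region_label[s$events$kind == "active"],
                      levels = cfg$regions$label))
  expect_equal(as.integer(act), floor(3600 / periods))
  # plenty of passive traffic was present nonetheless
  expect_gt(sum(s$events$kind == "passive"), 100)
})

test_that("waves traverse refractory regions without recording contractions", {
  # middle region with a 30-s refractory skips most arrivals, yet the distal
  # region keeps receiving every wave
  regions <- list(
    region_params(0, "A", 10, jitter_cv = 0, reset_efficacy = 1,
                  refractory_s = 2),
    region_params(1, "B", 1000, jitter_cv = 0, reset_efficacy = 1,
                  refractory_s = 30),
    region_params(2, "C", 1000, jitter_cv = 0, reset_efficacy = 1,
                  refractory_s = 2))
  cfg <- chain_config("refr", regions,
                      coupling = coupling_params(survival_prob = 1),
                      adaptation = adaptation_params(gain_k = 0), seed = 1)
  s <- simulate_chain(cfg, 600)
  nB <- sum(s$events$region_label == "B" & s$events$kind == "passive")
  nC <- sum(s$events$region_label == "C" & s$events$kind == "passive")
  tB <- s$events$time_s[s$events$region_label == "B"]
  expect_gte(min(diff(tB)), 30)
  expect_gt(nC, 2 * nB)           # C saw waves that B could not register
  expect_equal(nC, 59)            # one per wave arriving inside the window
})

test_that("identical (config, seed, stimuli) reproduce byte-identical logs", {
  cfg <- stage_preset("e12", seed = 11)
  stim <- data.frame(time_s = c(100, 400), region = "D3",
                     launches_wave = TRUE)
  s1 <- simulate_chain(cfg, 3600, stimuli = stim)
  s2 <- simulate_chain(cfg, 3600, stimuli = stim)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$waves, s2$waves)
  s3 <- simulate_chain(cfg, 3600, stimuli = stim, seed = 12)
  expect_false(identical(s1$events, s3$events))
  # forced events present and wave-launching
  expect_equal(sum(s1$events$kind == "forced"), 2)
})

test_that("simulator validates inputs", {
  cfg <- make_chain(c(50, 100))
  expect_error(simulate_chain(cfg, -5), "duration_s")
  expect_error(simulate_chain(cfg, 100,
                              stimuli = data.frame(time_s = 10, region = "Z")),
               "unknown region")
  expect_error(simulate_chain(cfg, 100,
                              stimuli = data.frame(time_s = 500, region = "R1")),
               "within")
})
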