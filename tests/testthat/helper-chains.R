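# Builders for small deterministic chains used across tests.

# Chain with explicit latent periods; deterministic by default (no jitter,
# no adaptation), survival/efficacy shared by all regions.
make_chain <- function(periods, survival = 1, rho = 1, jitter = 0,
                       refractory = 5, delay = 1, seed = 1,
                       gain_k = 0, collision = "annihilate") {
  regions <- lapply(seq_along(periods), function(i)
    region_params(i - 1L, paste0("R", i), periods[i], jitter_cv = jitter,
                  reset_efficacy = rho, refractory_s = refractory))
  chain_config("test", regions,
               coupling = coupling_params(conduction_delay_s = delay,
                                          survival_prob = survival,
                                          collision_rule = collision),
               adaptation = adaptation_params(gain_k = gain_k),
               seed = seed)
}

# Random small chain whose periods are separated by more than the chain
# transit time, with a unique fastest region: entrainment settles within the
# fastest region's first cycle.
make_separated_chain <- function(n, seed, rho = 1, survival = 1) {
  set.seed(seed)
  periods <- 50 + (0:(n - 1)) * (n + 10)
  periods <- sample(periods)
  make_chain(periods, survival = survival, rho = rho, seed = seed + 100)
}

# Match detected events to ground-truth events (same region, within tol);
# returns fraction with the correct active/passive label and the fraction of
# multi-region waves assigned the true origin.
score_assignment <- function(assignment, truth_sim, tol = 3) {
  ev <- assignment$events
  truth <- truth_sim$events
  matched <- 0; correct <- 0
  for (i in seq_len(nrow(ev))) {
    tr <- truth[truth$region_label == ev$region_label[i], ]
    if (!nrow(tr)) next
    j <- which.min(abs(tr$time_s - ev$time_s[i]))
    if (abs(tr$time_s[j] - ev$time_s[i]) <= tol) {
      matched <- matched + 1
      true_kind <- if (tr$kind[j] == "forced") "active" else tr$kind[j]
      if (true_kind == ev$kind[i]) correct <- correct + 1
    }
  }
  tw <- truth_sim$waves
  aw <- assignment$waves
  n_orig <- 0; ok_orig <- 0
  for (i in seq_len(nrow(tw))) {
    j <- which.min(abs(aw$start_time_s - tw$start_time_s[i]))
    if (abs(aw$start_time_s[j] - tw$start_time_s[i]) <= tol) {
      n_orig <- n_orig + 1
      if (aw$origin_label[j] == tw$origin_label[i]) ok_orig <- ok_orig + 1
    }
  }
  list(matched = matched, n_events = nrow(ev),
       label_accuracy = correct / matched,
       origin_accuracy = ok_orig / n_orig, n_waves_scored = n_orig)
}
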