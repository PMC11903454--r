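#' Intact-caecum monitoring protocol
#'
#' Simulates the whole chain and summarizes per-region hourly contraction
#' rates; active contractions count as OPW generations.
#'
#' @param config A [chain_config()].
#' @param duration_h Observation span, hours.
#' @return A list with `sim` (the [simulate_chain()] result) and `rates`
#'   (per-region hourly rate summary).
#' @examples
#' run_intact(stage_preset("e12", seed = 1), duration_h = 1)$rates
#' @export
run_intact <- function(config, duration_h) {
  stopifnot(duration_h > 0)
  sim <- simulate_chain(config, duration_h * 3600)
  rates <- summarize_rates(sim$events, window = c(0, sim$duration_s),
                           labels = config$regions$label)
  list(sim = sim, rates = rates)
}

#' Fragmentation protocol: every region isolated
#'
#' Chops the chain into single-region fragments and simulates each in
#' isolation, unveiling every region's latent rhythm (no waves cross
#' boundaries, so each fragment contracts at its intrinsic rate).
#'
#' @inheritParams run_intact
#' @return A per-region hourly rate summary; the individual fragment
#'   simulations are attached as attribute `"sims"`.
#' @export
run_fragments <- function(config, duration_h) {
  stopifnot(duration_h > 0)
  sims <- lapply(seq_len(config$n_regions), function(i) {
    frag <- fragment_config(config, i, seed = config$seed + i)
    simulate_chain(frag, duration_h * 3600)
  })
  ev <- do.call(rbind, lapply(sims, `[[`, "events"))
  # restore chain-wide region identity (each fragment is indexed 0 internally)
  ev$region_label <- rep(config$regions$label,
                         vapply(sims, function(s) nrow(s$events), 0L))
  ev$region_index <- config$regions$index[match(ev$region_label,
                                                config$regions$label)]
  rates <- summarize_rates(ev, window = c(0, duration_h * 3600),
                           labels = config$regions$label)
  attr(rates, "sims") <- sims
  rates
}

# Single-region chain inheriting one region's parameters (optionally with its
# latent period overridden, e.g. by an adapted value).
fragment_config <- function(config, row, seed, latent_period_s = NULL) {
  r <- config$regions[row, ]
  chain_config(stage = paste0(config$stage, ":", r$label),
               regions = list(region_params(
                 index = 0L, label = r$label,
                 latent_period_s = if (is.null(latent_period_s))
                   r$latent_period_s else latent_period_s,
                 jitter_cv = r$jitter_cv,
                 reset_efficacy = r$reset_efficacy,
                 refractory_s = r$refractory_s,
                 survival_prob = r$survival_prob)),
               coupling = config$coupling,
               adaptation = config$adaptation,
               seed = seed)
}

#' Surgical-ablation protocol
#'
#' Removes a contiguous run of regions from one end of the chain (mirroring
#' surgical removal, e.g. of P1) and simulates the truncated chain. Removing
#' a fast proximal pacemaker releases its neighbour from entrainment, whose
#' active rate then rises toward its latent rate.
#'
#' @inheritParams run_intact
#' @param removed_labels Character vector of region labels to remove; must be
#'   contiguous from the proximal or distal end (interior removals rejected).
#' @return As [run_intact()], for the remaining regions.
#' @examples
#' run_ablated(stage_preset("e12", seed = 1), "P1", duration_h = 1)$rates
#' @export
run_ablated <- function(config, removed_labels, duration_h) {
  if (length(removed_labels) == 0) return(run_intact(config, duration_h))
  rows <- unname(vapply(removed_labels, function(l) region_row(config, l), 0L))
  n <- config$n_regions
  rows <- sort(rows)
  from_prox <- identical(rows, seq_len(length(rows)))
  from_dist <- identical(rows, seq.int(n - length(rows) + 1L, n))
  if (!from_prox && !from_dist)
    stop("removed regions must be contiguous from one end of the chain")
  if (length(rows) >= n) stop("cannot remove every region")
  keep <- setdiff(seq_len(n), rows)
  regions <- lapply(seq_along(keep), function(i) {
    r <- config$regions[keep[i], ]
    region_params(index = i - 1L, label = r$label,
                  latent_period_s = r$latent_period_s,
                  jitter_cv = r$jitter_cv,
                  reset_efficacy = r$reset_efficacy,
                  refractory_s = r$refractory_s,
                  survival_prob = r$survival_prob)
  })
  truncated <- chain_config(stage = config$stage, regions = regions,
                            coupling = config$coupling,
                            adaptation = config$adaptation,
                            seed = config$seed)
  run_intact(truncated, duration_h)
}

#' Tap-interruption protocol on an isolated fragment
#'
#' Replays the rhythm-interruption experiment: an isolated fragment is left
#' to contract spontaneously for `n_cycles` control cycles (their mean
#' interval defines `T`), then a forced contraction (mechanical tap, which
#' does not launch a wave in a single-region context) is delivered
#' `tap_offset_s` after the next spontaneous contraction. The interval
#' spanning the interruption defines `tau`; the reported delay is `tau - T`,
#' which equals `reset_efficacy * tap_offset_s` in the noise-free case.
#'
#' @param fragment_params A [region_params()] describing the fragment (e.g.
#'   the P2 row of a stage preset).
#' @param tap_offset_s Tap time after the anchoring spontaneous contraction,
#'   seconds; must fall before the next spontaneous contraction.
#' @param n_cycles Number of control cycles used to estimate `T`.
#' @param seed Integer seed.
#' @return An object of class `delay_estimate`: list with `T_s`, `tau_s`,
#'   `delay_s`, `tap_offset_s`, `tap_time_s` and the tapped simulation as
#'   `sim`.
#' @examples
#' p2 <- region_params(0, "P2", 101.1, jitter_cv = 0)
#' run_tap(p2, 40)$delay_s
#' @export
run_tap <- function(fragment_params, tap_offset_s, n_cycles = 3, seed = 1L) {
  stopifnot(inherits(fragment_params, "region_params"))
  if (tap_offset_s <= 0 || tap_offset_s >= fragment_params$latent_period_s)
    stop("tap_offset_s must satisfy 0 < tap_offset_s < latent_period_s")
  p <- fragment_params$latent_period_s
  cfg <- chain_config(stage = "fragment",
                      regions = list(region_params(
                        index = 0L, label = fragment_params$label,
                        latent_period_s = p,
                        jitter_cv = fragment_params$jitter_cv,
                        reset_efficacy = fragment_params$reset_efficacy,
                        refractory_s = fragment_params$refractory_s)),
                      adaptation = adaptation_params(gain_k = 0),
                      seed = seed)
  horizon <- (n_cycles + 4) * p * 2
  free <- simulate_chain(cfg, horizon)
  fires <- free$events$time_s[free$events$kind == "active"]
  if (length(fires) < n_cycles + 2)
    stop("fragment did not produce enough control cycles")
  ctrl <- diff(fires[seq_len(n_cycles + 1)])
  T_s <- mean(ctrl)
  anchor <- fires[n_cycles + 1]
  tap_time <- anchor + tap_offset_s
  if (fires[n_cycles + 2] <= tap_time)
    stop("tap falls after the next spontaneous contraction; reduce tap_offset_s")
  tapped <- simulate_chain(cfg, tap_time + 4 * p,
                           stimuli = data.frame(time_s = tap_time,
                                                region = fragment_params$label,
                                                launches_wave = FALSE))
  tf <- tapped$events$time_s[tapped$events$kind == "active"]
  t_next <- tf[tf > tap_time][1]
  if (is.na(t_next)) stop("no spontaneous contraction after the tap")
  tau_s <- t_next - anchor
  structure(list(T_s = T_s, tau_s = tau_s, delay_s = tau_s - T_s,
                 tap_offset_s = tap_offset_s, tap_time_s = tap_time,
                 sim = tapped),
            class = "delay_estimate")
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("tap interruption: T = %.2f s, tau = %.2f s, delay = %.2f s (tap at +%.1f s)\n",
              x$T_s, x$tau_s, x$delay_s, x$tap_offset_s))
  invisible(x)
}

#' Periodic pacing protocol (optogenetic-style forced firing)
#'
#' Injects forced contractions at one region at a fixed interval; each forced
#' contraction launches a wave (as an optogenetically evoked OPW does), and
#' the passing-wave rate experienced by an observer region is reported.
#'
#' @inheritParams run_intact
#' @param paced_label Label of the paced region.
#' @param interval_s Pacing interval, seconds (must be at least the paced
#'   region's refractory period).
#' @param observe_label Label of the observed region (distinct from the paced
#'   one).
#' @return A list with `sim`, `passing_per_h` (waves per hour traversing the
#'   observed region, own-origin waves excluded) and `rates`.
#' @export
run_paced <- function(config, paced_label, interval_s, duration_h,
                      observe_label) {
  pr <- region_row(config, paced_label)
  or <- region_row(config, observe_label)
  if (pr == or) stop("paced and observed regions must be distinct")
  if (interval_s < config$regions$refractory_s[pr])
    stop("pacing interval must be >= the paced region's refractory period")
  dur <- duration_h * 3600
  # first pulse at half an interval so the final wave lands inside the window
  times <- seq(interval_s / 2, dur, by = interval_s)
  stim <- data.frame(time_s = times, region = paced_label,
                     launches_wave = TRUE)
  sim <- simulate_chain(config, dur, stimuli = stim)
  list(sim = sim,
       passing_per_h = passing_exposure(sim, observe_label) / duration_h,
       rates = summarize_rates(sim$events, window = c(0, dur),
                               labels = config$regions$label))
}

# Number of waves traversing a region that did not originate it.
passing_exposure <- function(sim, label) {
  idx <- sim$config$regions$index[region_row(sim$config, label)]
  w <- sim$waves
  sum(w$prox_reach <= idx & w$dist_reach >= idx & w$origin_region != idx)
}

#' Multi-day development protocol with post-culture fragment assay
#'
#' Runs a long (days) simulation with period adaptation active — optionally
#' after removing regions from one end, which lowers the passing-wave traffic
#' experienced downstream — then isolates the assay region and measures its
#' acquired latent rate over a 1-h window following a settling period,
#' mirroring a 3-day organ culture followed by a fragment assay.
#'
#' @inheritParams run_ablated
#' @param days Culture duration in days (>= 1).
#' @param ablate_labels Optional labels removed before culture (must not
#'   include the assay region).
#' @param assay_label Region assayed after culture.
#' @param stimuli Optional forced-contraction schedule applied during culture
#'   (e.g. optogenetic pacing), passed to [simulate_chain()].
#' @param settle_s Settling time preceding the assay window, seconds.
#' @param assay_h Assay window, hours.
#' @return A list with `passing_per_h` (passing-wave exposure of the assay
#'   region during culture), `assay_rate_per_h` (acquired latent rate of the
#'   isolated assay fragment), `adapted_period_s`, plus the culture and assay
#'   simulations.
#' @export
run_development <- function(config, days, ablate_labels = NULL,
                            assay_label = "D2", stimuli = NULL,
                            settle_s = 600, assay_h = 1) {
  if (days < 1) stop("days must be >= 1")
  if (assay_label %in% ablate_labels)
    stop("assay region cannot be ablated")
  cfg <- config
  if (!is.null(ablate_labels) && length(ablate_labels)) {
    rows <- sort(unname(vapply(ablate_labels,
                               function(l) region_row(config, l), 0L)))
    n <- config$n_regions
    if (!identical(rows, seq_len(length(rows))) &&
        !identical(rows, seq.int(n - length(rows) + 1L, n)))
      stop("ablated regions must be contiguous from one end")
    keep <- setdiff(seq_len(n), rows)
    regions <- lapply(seq_along(keep), function(i) {
      r <- config$regions[keep[i], ]
      region_params(index = i - 1L, label = r$label,
                    latent_period_s = r$latent_period_s,
                    jitter_cv = r$jitter_cv,
                    reset_efficacy = r$reset_efficacy,
                    refractory_s = r$refractory_s,
                    survival_prob = r$survival_prob)
    })
    cfg <- chain_config(stage = config$stage, regions = regions,
                        coupling = config$coupling,
                        adaptation = config$adaptation, seed = config$seed)
  }
  culture <- simulate_chain(cfg, days * 86400, stimuli = stimuli)
  row <- region_row(cfg, assay_label)
  adapted <- culture$final_config$regions$latent_period_s[row]
  frag <- fragment_config(cfg, row, seed = cfg$seed + 7919L,
                          latent_period_s = adapted)
  assay <- simulate_chain(frag, settle_s + assay_h * 3600)
  n_act <- sum(assay$events$kind == "active" &
                 assay$events$time_s > settle_s)
  list(passing_per_h = passing_exposure(culture, assay_label) / (days * 24),
       assay_rate_per_h = n_act / assay_h,
       adapted_period_s = adapted,
       culture = culture, assay = assay)
}
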