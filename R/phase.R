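#' Phase reset by a forced or passive contraction
#'
#' A contraction imposed on a region (by a passing wave, a mechanical tap or
#' an optogenetic pulse) restarts the region's contraction clock: a fraction
#' `reset_efficacy` of the accumulated phase is erased, so the next
#' spontaneous contraction is delayed by `reset_efficacy * elapsed_phase_s`.
#' Efficacy 1 is the idealized count-from-zero reset; the default chain
#' efficacy 0.76875 reproduces a 30.75 s delay for a stimulus delivered 40 s
#' into the cycle.
#'
#' @param elapsed_phase_s Accumulated phase at the moment of the forced
#'   contraction, seconds (>= 0).
#' @param reset_efficacy Fraction of phase erased, in `[0, 1]`.
#' @return Remaining phase in seconds: `(1 - reset_efficacy) * elapsed_phase_s`.
#' @examples
#' reset_phase(33, 1)    # complete reset
#' reset_phase(40, 0.76875)
#' @export
reset_phase <- function(elapsed_phase_s, reset_efficacy) {
  if (any(elapsed_phase_s < 0)) stop("elapsed_phase_s must be >= 0")
  if (any(reset_efficacy < 0 | reset_efficacy > 1))
    stop("reset_efficacy must lie in [0, 1]")
  (1 - reset_efficacy) * elapsed_phase_s
}

#' Slow activity-dependent lengthening of the latent period
#'
#' First-order relaxation of the current period toward
#' `baseline_period_s * min(1 + gain_k * passive_rate, period_ceiling_factor)`
#' with time constant `timescale_h`, integrated over `dt_h` hours under a
#' constant passive rate. This is the long-term suppression law: the more
#' frequently a region experiences passing waves, the slower the rhythm it
#' acquires; with zero exposure the period relaxes back to baseline.
#'
#' @param baseline_period_s Baseline (unadapted) latent period, seconds.
#' @param passive_rate Exponentially averaged recent passive+forced
#'   contraction rate, events/hour (>= 0).
#' @param params An [adaptation_params()].
#' @param dt_h Exposure duration, hours (> 0).
#' @param current_period_s Current (possibly already adapted) period, seconds.
#' @return Updated period in seconds.
#' @examples
#' p <- adaptation_params()
#' adapt_period(100, 0, p, 10, 100)   # fixed point at baseline
#' @export
adapt_period <- function(baseline_period_s, passive_rate, params, dt_h,
                         current_period_s) {
  stopifnot(inherits(params, "adaptation_params"))
  if (baseline_period_s <= 0 || current_period_s <= 0)
    stop("periods must be > 0")
  if (dt_h <= 0) stop("dt_h must be > 0")
  if (passive_rate < 0) stop("passive_rate must be >= 0")
  target <- baseline_period_s *
    min(1 + params$gain_k * passive_rate, params$period_ceiling_factor)
  target + (current_period_s - target) * exp(-dt_h / params$timescale_h)
}

#' Mean propagation range of a wave under per-boundary survival
#'
#' A wave crosses each successive boundary independently with probability
#' `survival_prob` and can visit at most `reachable_regions` regions (the
#' origin included), so its range follows a truncated geometric law
#' `P(range = k) = q^(k-1) (1-q)` for `k < L` and `P(range = L) = q^(L-1)`.
#' The mean has closed form `(1 - q^L) / (1 - q)` (and `L` when `q = 1`).
#'
#' @param survival_prob Per-boundary continuation probability `q` in `[0, 1]`.
#' @param reachable_regions Number of regions reachable from the origin in
#'   the travel direction, origin included (`L >= 1`).
#' @return Expected number of distinct regions visited.
#' @examples
#' expected_range(0, 8)  # dies at the first boundary
#' expected_range(1, 8)  # always reaches the end
#' @export
expected_range <- function(survival_prob, reachable_regions) {
  if (survival_prob < 0 || survival_prob > 1)
    stop("survival_prob must lie in [0, 1]")
  L <- as.integer(reachable_regions)
  if (L < 1) stop("reachable_regions must be >= 1")
  if (survival_prob == 1) return(as.numeric(L))
  (1 - survival_prob^L) / (1 - survival_prob)
}

#' Survival probability achieving a target mean propagation range
#'
#' Inverts [expected_range()] by bisection on the monotone closed form,
#' to an absolute tolerance of 1e-9 on the mean range.
#'
#' @param target_mean_range Desired mean range, in `[1, reachable_regions]`.
#' @param reachable_regions Number of reachable regions, origin included.
#' @return Per-boundary survival probability `q`.
#' @examples
#' q <- calibrate_survival(4.6, 8)
#' expected_range(q, 8)
#' @export
calibrate_survival <- function(target_mean_range, reachable_regions) {
  L <- as.integer(reachable_regions)
  if (L < 1) stop("reachable_regions must be >= 1")
  if (target_mean_range < 1 || target_mean_range > L)
    stop("target_mean_range must lie in [1, reachable_regions]")
  if (target_mean_range == 1) return(0)
  if (target_mean_range == L) return(1)
  lo <- 0; hi <- 1
  while (hi - lo > 1e-15) {
    mid <- (lo + hi) / 2
    if (expected_range(mid, L) < target_mean_range) lo <- mid else hi <- mid
  }
  q <- (lo + hi) / 2
  if (abs(expected_range(q, L) - target_mean_range) > 1e-9)
    stop("bisection failed to reach tolerance")  # cannot happen on [1, L]
  q
}
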