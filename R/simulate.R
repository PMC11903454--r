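#' Event-driven simulation of the caecum contraction-clock chain
#'
#' Simulates a 1-D chain of resettable integrate-and-fire contraction clocks
#' coupled by finite-range stochastic waves. Each region accumulates phase at
#' unit rate; on reaching its (jittered, adaptation-scaled) period it emits an
#' active contraction (an OPW generation), restarts its clock and launches a
#' bidirectional wave. A wave front advances one region per conduction delay
#' and continues across each boundary with the origin's survival probability;
#' on arrival it forces a passive contraction that partially resets the host
#' clock (entrainment / macroscopic lateral inhibition), unless the host is
#' refractory, in which case the front passes without a recorded contraction.
#' Forced stimuli (taps, optogenetic pulses) behave like wave arrivals and may
#' themselves launch waves. Passive+forced contractions drive the slow period
#' adaptation of [adapt_period()]. The run is deterministic given
#' `(config, seed, stimuli)`.
#'
#' @param config A [chain_config()].
#' @param duration_s Simulated span in seconds (> 0); events at exactly
#'   `duration_s` are included.
#' @param stimuli Optional data frame of forced contractions with columns
#'   `time_s`, `region` (label or 0-based index) and optionally
#'   `launches_wave` (logical, default `TRUE`; use `FALSE` for a mechanical
#'   tap on an isolated fragment).
#' @param seed Integer seed; defaults to `config$seed`. The caller's RNG
#'   state is preserved.
#' @return An object of class `caecum_sim`: a list with `events` (time-sorted
#'   data frame: `time_s`, `region_index`, `region_label`, `kind`,
#'   `wave_id`), `waves` (one row per launched wave: origin, start time,
#'   direction, proximal/distal reach, `range` = distinct regions visited,
#'   `n_passive`, terminal region), `config`, `final_config` (latent periods
#'   replaced by their adapted values), `adapt_mult`, `duration_s`, `seed`.
#' @examples
#' cfg <- stage_preset("e12", seed = 1)
#' sim <- simulate_chain(cfg, 3600)
#' summary(sim)
#' @export
simulate_chain <- function(config, duration_s, stimuli = NULL,
                           seed = config$seed) {
  stopifnot(inherits(config, "chain_config"))
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be a positive finite number")
  reg <- config$regions
  n <- config$n_regions
  if (any(!is.finite(reg$latent_period_s)))
    stop("non-finite latent period in config")

  stim <- normalize_stimuli(stimuli, config, duration_s)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  delay <- config$coupling$conduction_delay_s
  annihilate <- identical(config$coupling$collision_rule, "annihilate")
  k_gain <- config$adaptation$gain_k
  ceiling_f <- config$adaptation$period_ceiling_factor
  tau_s <- config$adaptation$timescale_h * 3600
  win_h <- config$adaptation$rate_window_h
  win_s <- win_h * 3600

  base <- reg$latent_period_s
  cv <- reg$jitter_cv
  sdlog <- sqrt(log(1 + cv^2))
  rho <- reg$reset_efficacy
  refr <- reg$refractory_s
  q_origin <- ifelse(is.na(reg$survival_prob),
                     config$coupling$survival_prob, reg$survival_prob)

  # region state
  mult <- rep(1, n)          # adaptation multiplier of the period
  rate <- rep(0, n)          # exponentially averaged passive+forced rate, /h
  state_t <- rep(0, n)       # time of last rate/adaptation update
  phase0 <- rep(0, n)        # phase at phase_t
  phase_t <- rep(0, n)
  thr <- numeric(n)          # current firing threshold (jittered period)
  next_fire <- numeric(n)
  last_ev <- rep(-Inf, n)
  last_visit_t <- rep(-Inf, n)
  last_visit_dir <- rep(0L, n)

  draw_jit <- function(i) {
    if (cv[i] > 0) stats::rlnorm(1, meanlog = -sdlog[i]^2 / 2,
                                 sdlog = sdlog[i]) else 1
  }
  for (i in seq_len(n)) {
    thr[i] <- base[i] * mult[i] * draw_jit(i)
    next_fire[i] <- thr[i]
  }

  upd_state <- function(j, t) {
    dt <- t - state_t[j]
    if (dt <= 0) return(invisible())
    target <- min(1 + k_gain * rate[j], ceiling_f)
    mult[j] <<- target + (mult[j] - target) * exp(-dt / tau_s)
    rate[j] <<- rate[j] * exp(-dt / win_s)
    state_t[j] <<- t
    invisible()
  }
  restart_clock <- function(j, t, remaining) {
    phase0[j] <<- remaining
    phase_t[j] <<- t
    thr[j] <<- base[j] * mult[j] * draw_jit(j)
    next_fire[j] <<- t + max(thr[j] - remaining, 0)
    invisible()
  }

  # event log, grown in chunks
  cap <- 4096L; n_ev <- 0L
  ev_t <- numeric(cap); ev_r <- integer(cap)
  ev_k <- character(cap); ev_w <- integer(cap)
  push_event <- function(t, r, kind, wid) {
    if (n_ev == cap) {
      cap <<- cap * 2L
      length(ev_t) <<- cap; length(ev_r) <<- cap
      length(ev_k) <<- cap; length(ev_w) <<- cap
    }
    n_ev <<- n_ev + 1L
    ev_t[n_ev] <<- t; ev_r[n_ev] <<- r
    ev_k[n_ev] <<- kind; ev_w[n_ev] <<- wid
    invisible()
  }

  # wave log
  wcap <- 1024L; n_wv <- 0L
  wv_origin <- integer(wcap); wv_start <- numeric(wcap)
  wv_prox <- integer(wcap); wv_dist <- integer(wcap)
  wv_npass <- integer(wcap); wv_q <- numeric(wcap)
  grow_waves <- function() {
    wcap <<- wcap * 2L
    length(wv_origin) <<- wcap; length(wv_start) <<- wcap
    length(wv_prox) <<- wcap; length(wv_dist) <<- wcap
    length(wv_npass) <<- wcap; length(wv_q) <<- wcap
    invisible()
  }

  # active wave fronts
  fr_wave <- integer(0); fr_reg <- integer(0)
  fr_dir <- integer(0); fr_time <- numeric(0)
  launch_wave <- function(origin, t) {
    if (n_wv == wcap) grow_waves()
    n_wv <<- n_wv + 1L
    wid <- n_wv
    wv_origin[wid] <<- origin; wv_start[wid] <<- t
    wv_prox[wid] <<- origin; wv_dist[wid] <<- origin
    wv_npass[wid] <<- 0L; wv_q[wid] <<- q_origin[origin]
    for (d in c(-1L, 1L)) {
      nxt <- origin + d
      if (nxt >= 1L && nxt <= n && stats::runif(1) < wv_q[wid]) {
        fr_wave <<- c(fr_wave, wid); fr_reg <<- c(fr_reg, nxt)
        fr_dir <<- c(fr_dir, d); fr_time <<- c(fr_time, t + delay)
      }
    }
    wid
  }
  drop_front <- function(k) {
    fr_wave <<- fr_wave[-k]; fr_reg <<- fr_reg[-k]
    fr_dir <<- fr_dir[-k]; fr_time <<- fr_time[-k]
    invisible()
  }

  do_contraction <- function(j, t, kind, wid) {
    upd_state(j, t)
    # only passive/forced contractions feed the adaptation drive
    if (kind != "active") rate[j] <<- rate[j] + 1 / win_h
    push_event(t, j, kind, wid)
    last_ev[j] <<- t
    invisible()
  }

  si <- 1L
  repeat {
    t_stim <- if (si <= nrow(stim)) stim$time_s[si] else Inf
    t_front <- if (length(fr_time)) min(fr_time) else Inf
    t_fire <- min(next_fire)
    t <- min(t_stim, t_front, t_fire)
    if (t > duration_s) break

    if (t_stim <= t_front && t_stim <= t_fire) {
      j <- stim$row[si]; lw <- stim$launches_wave[si]; si <- si + 1L
      if (t - last_ev[j] >= refr[j]) {
        do_contraction(j, t, "forced", NA_integer_)
        if (lw) launch_wave(j, t)
        ph <- phase0[j] + (t - phase_t[j])
        restart_clock(j, t, reset_phase(ph, rho[j]))
      }
    } else if (t_front <= t_fire) {
      k <- which.min(fr_time)
      w <- fr_wave[k]; j <- fr_reg[k]; d <- fr_dir[k]
      drop_front(k)
      if (annihilate && last_visit_dir[j] == -d &&
          t - last_visit_t[j] <= 1.5 * delay) {
        # head-on collision: the front dies in the opposing wave's wake
      } else {
        if (j < wv_prox[w]) wv_prox[w] <- j
        if (j > wv_dist[w]) wv_dist[w] <- j
        last_visit_t[j] <- t; last_visit_dir[j] <- d
        if (t - last_ev[j] >= refr[j]) {
          do_contraction(j, t, "passive", w)
          wv_npass[w] <- wv_npass[w] + 1L
          ph <- phase0[j] + (t - phase_t[j])
          restart_clock(j, t, reset_phase(ph, rho[j]))
        }
        nxt <- j + d
        if (nxt >= 1L && nxt <= n && stats::runif(1) < wv_q[w]) {
          fr_wave <- c(fr_wave, w); fr_reg <- c(fr_reg, nxt)
          fr_dir <- c(fr_dir, d); fr_time <- c(fr_time, t + delay)
        }
      }
    } else {
      j <- which.min(next_fire)
      if (t < last_ev[j] + refr[j]) {
        next_fire[j] <- last_ev[j] + refr[j]   # refractory postponement
      } else {
        do_contraction(j, t, "active", NA_integer_)
        launch_wave(j, t)
        restart_clock(j, t, 0)
      }
    }
  }

  for (i in seq_len(n)) upd_state(i, duration_s)

  idx <- seq_len(n_ev)
  events <- data.frame(time_s = ev_t[idx],
                       region_index = reg$index[ev_r[idx]],
                       region_label = reg$label[ev_r[idx]],
                       kind = ev_k[idx],
                       wave_id = ev_w[idx],
                       stringsAsFactors = FALSE)
  ord <- order(events$time_s, events$region_index)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL

  widx <- seq_len(n_wv)
  range_w <- wv_dist[widx] - wv_prox[widx] + 1L
  dist_ext <- wv_dist[widx] - wv_origin[widx]
  prox_ext <- wv_origin[widx] - wv_prox[widx]
  terminal <- ifelse(dist_ext >= prox_ext, wv_dist[widx], wv_prox[widx])
  waves <- data.frame(wave_id = widx,
                      origin_region = reg$index[wv_origin[widx]],
                      origin_label = reg$label[wv_origin[widx]],
                      start_time_s = wv_start[widx],
                      direction = direction_label(wv_origin[widx], n),
                      prox_reach = reg$index[pmax(wv_prox[widx], 1L)],
                      dist_reach = reg$index[pmin(wv_dist[widx], n)],
                      range = range_w,
                      n_passive = wv_npass[widx],
                      terminal_region = reg$index[terminal],
                      stringsAsFactors = FALSE)

  final_config <- config
  final_config$regions$latent_period_s <- base * mult

  structure(list(events = events, waves = waves,
                 config = config, final_config = final_config,
                 adapt_mult = stats::setNames(mult, reg$label),
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "caecum_sim")
}

direction_label <- function(origin_row, n) {
  ifelse(origin_row == 1L, "distal",
         ifelse(origin_row == n, "proximal", "both"))
}

normalize_stimuli <- function(stimuli, config, duration_s) {
  if (is.null(stimuli) || NROW(stimuli) == 0)
    return(data.frame(time_s = numeric(0), row = integer(0),
                      launches_wave = logical(0)))
  stopifnot(is.data.frame(stimuli), all(c("time_s", "region") %in% names(stimuli)))
  if (any(stimuli$time_s < 0 | stimuli$time_s > duration_s))
    stop("stimulus times must lie within [0, duration_s]")
  rows <- vapply(seq_len(nrow(stimuli)),
                 function(i) region_row(config, stimuli$region[[i]]), 0L)
  lw <- if ("launches_wave" %in% names(stimuli))
    as.logical(stimuli$launches_wave) else rep(TRUE, nrow(stimuli))
  out <- data.frame(time_s = stimuli$time_s, row = rows, launches_wave = lw)
  out[order(out$time_s), , drop = FALSE]
}

#' @export
print.caecum_sim <- function(x, ...) {
  cat(sprintf("caecum_sim: stage %s, %d regions, %.3g h simulated, seed %d\n",
              x$config$stage, x$config$n_regions, x$duration_s / 3600, x$seed))
  tab <- table(x$events$kind)
  cat(sprintf("events: %d (%s); waves launched: %d\n",
              nrow(x$events),
              paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "),
              nrow(x$waves)))
  invisible(x)
}

#' @export
summary.caecum_sim <- function(object, ...) {
  rs <- summarize_rates(object$events, window = c(0, object$duration_s),
                        labels = object$config$regions$label)
  cat(sprintf("Per-region hourly contraction rates over %.3g h:\n",
              object$duration_s / 3600))
  print(rs, row.names = FALSE)
  invisible(rs)
}

#' Raster plot of a simulated event log
#'
#' Regions on the vertical axis (proximal at top), time on the horizontal;
#' active contractions are drawn as filled red points, passive as grey and
#' forced as blue.
#'
#' @param x A `caecum_sim`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.caecum_sim <- function(x, ...) {
  ev <- x$events
  n <- x$config$n_regions
  cols <- c(active = "firebrick", passive = "grey60", forced = "dodgerblue3")
  graphics::plot(ev$time_s, n - ev$region_index,
                 col = cols[ev$kind], pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = n - x$config$regions$index,
                 labels = x$config$regions$label, las = 1)
  graphics::legend("topright", legend = names(cols), col = cols,
                   pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}
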