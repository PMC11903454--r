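#' Fixed-time-step reference simulation of the chain
#'
#' A deliberately simple brute-force integrator used to validate the
#' event-driven engine: time advances on a fixed grid (default 0.01 s), every
#' region's phase is incremented each step, wave fronts are queued with their
#' due times, and contractions are emitted when thresholds are crossed. Event
#' times are reported on the grid, so the two engines agree to within one
#' step on configurations where their random draws coincide trivially, i.e.
#' `jitter_cv = 0` everywhere and survival probabilities of 0 or 1.
#'
#' Adaptation is outside the scope of this reference engine
#' (`gain_k` must be 0); the closed form of [adapt_period()] is validated
#' separately against small-step numerical integration.
#'
#' @inheritParams simulate_chain
#' @param dt Step size in seconds.
#' @return A list with `events` and `waves` data frames in the same layout
#'   as [simulate_chain()].
#' @export
simulate_chain_stepwise <- function(config, duration_s, stimuli = NULL,
                                    dt = 0.01, seed = config$seed) {
  stopifnot(inherits(config, "chain_config"))
  reg <- config$regions
  n <- config$n_regions
  if (config$adaptation$gain_k != 0)
    stop("the stepwise reference engine requires gain_k = 0")
  if (any(reg$jitter_cv != 0))
    stop("the stepwise reference engine requires jitter_cv = 0")
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
  q_origin <- ifelse(is.na(reg$survival_prob),
                     config$coupling$survival_prob, reg$survival_prob)
  base <- reg$latent_period_s; rho <- reg$reset_efficacy
  refr <- reg$refractory_s

  phase <- rep(0, n); last_ev <- rep(-Inf, n)
  last_visit_t <- rep(-Inf, n); last_visit_dir <- rep(0L, n)
  fr_wave <- integer(0); fr_reg <- integer(0)
  fr_dir <- integer(0); fr_due <- numeric(0)

  ev <- list(t = numeric(0), r = integer(0), k = character(0), w = integer(0))
  wv <- list(origin = integer(0), start = numeric(0),
             prox = integer(0), dist = integer(0), npass = integer(0))

  survives <- function(q) q > 0 && (q >= 1 || stats::runif(1) < q)
  launch <- function(origin, t) {
    wid <- length(wv$origin) + 1L
    wv$origin[wid] <<- origin; wv$start[wid] <<- t
    wv$prox[wid] <<- origin; wv$dist[wid] <<- origin
    wv$npass[wid] <<- 0L
    for (d in c(-1L, 1L)) {
      nxt <- origin + d
      if (nxt >= 1L && nxt <= n && survives(q_origin[origin])) {
        fr_wave <<- c(fr_wave, wid); fr_reg <<- c(fr_reg, nxt)
        fr_dir <<- c(fr_dir, d); fr_due <<- c(fr_due, t + delay)
      }
    }
    wid
  }
  emit <- function(t, r, kind, wid) {
    i <- length(ev$t) + 1L
    ev$t[i] <<- t; ev$r[i] <<- r; ev$k[i] <<- kind; ev$w[i] <<- wid
    invisible()
  }

  si <- 1L
  steps <- ceiling(duration_s / dt)
  for (step in seq_len(steps)) {
    t <- step * dt
    if (t > duration_s + dt / 2) break
    phase <- phase + dt

    while (si <= nrow(stim) && stim$time_s[si] <= t) {
      j <- stim$row[si]; lw <- stim$launches_wave[si]; si <- si + 1L
      if (t - last_ev[j] >= refr[j]) {
        emit(t, j, "forced", NA_integer_)
        last_ev[j] <- t
        if (lw) launch(j, t)
        phase[j] <- (1 - rho[j]) * phase[j]
      }
    }

    due <- which(fr_due <= t)
    for (k in due) {
      w <- fr_wave[k]; j <- fr_reg[k]; d <- fr_dir[k]
      if (annihilate && last_visit_dir[j] == -d &&
          t - last_visit_t[j] <= 1.5 * delay) next
      if (j < wv$prox[w]) wv$prox[w] <- j
      if (j > wv$dist[w]) wv$dist[w] <- j
      last_visit_t[j] <- t; last_visit_dir[j] <- d
      if (t - last_ev[j] >= refr[j]) {
        emit(t, j, "passive", w)
        wv$npass[w] <- wv$npass[w] + 1L
        last_ev[j] <- t
        phase[j] <- (1 - rho[j]) * phase[j]
      }
      nxt <- j + d
      if (nxt >= 1L && nxt <= n && survives(q_origin[wv$origin[w]])) {
        fr_wave <- c(fr_wave, w); fr_reg <- c(fr_reg, nxt)
        fr_dir <- c(fr_dir, d); fr_due <- c(fr_due, t + delay)
      }
    }
    if (length(due)) {
      fr_wave <- fr_wave[-due]; fr_reg <- fr_reg[-due]
      fr_dir <- fr_dir[-due]; fr_due <- fr_due[-due]
    }

    for (j in seq_len(n)) {
      if (phase[j] >= base[j] - dt / 2 && t - last_ev[j] >= refr[j]) {
        emit(t, j, "active", NA_integer_)
        last_ev[j] <- t
        launch(j, t)
        phase[j] <- 0
      }
    }
  }

  events <- data.frame(time_s = ev$t, region_index = reg$index[ev$r],
                       region_label = reg$label[ev$r], kind = ev$k,
                       wave_id = ev$w, stringsAsFactors = FALSE)
  ord <- order(events$time_s, events$region_index)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  widx <- seq_along(wv$origin)
  waves <- data.frame(wave_id = widx,
                      origin_region = reg$index[wv$origin],
                      origin_label = reg$label[wv$origin],
                      start_time_s = wv$start,
                      range = wv$dist - wv$prox + 1L,
                      n_passive = wv$npass,
                      stringsAsFactors = FALSE)
  list(events = events, waves = waves, duration_s = duration_s, dt = dt)
}
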