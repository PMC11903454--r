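#' Synthetic-trace rendering parameters
#'
#' Controls how an event log is rendered into per-region intensity time
#' series emulating 1-Hz video-derived recordings: each contraction adds a
#' raised-cosine transient, a slow sinusoidal baseline drift and seeded
#' Gaussian noise are superimposed. Transient morphology is a declared
#' fixture choice (the recordings' true pulse shape is not modelled).
#'
#' @param fs_hz Sampling rate, Hz (default 1, matching 1-s time-lapse
#'   imaging).
#' @param kernel_width_s Transient duration, seconds (>= 2 samples).
#' @param kernel_amp Transient amplitude, arbitrary intensity units.
#' @param drift_amp Baseline wander amplitude.
#' @param drift_period_s Baseline wander period, seconds.
#' @param noise_sd Additive Gaussian noise SD (default amplitude/10).
#' @param seed Integer seed for the noise stream.
#' @return A list of class `trace_params`.
#' @export
trace_params <- function(fs_hz = 1, kernel_width_s = 6, kernel_amp = 1,
                         drift_amp = 0.5, drift_period_s = 600,
                         noise_sd = 0.1, seed = 1L) {
  if (fs_hz <= 0) stop("fs_hz must be > 0")
  if (kernel_width_s < 2 / fs_hz)
    stop("kernel_width_s must span at least 2 samples")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(fs_hz = fs_hz, kernel_width_s = kernel_width_s,
                 kernel_amp = kernel_amp, drift_amp = drift_amp,
                 drift_period_s = drift_period_s, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "trace_params")
}

#' Render an event log as per-region intensity traces
#'
#' Inverse of the study's measurement step: where the study converted videos
#' of contracting regions into intensity values and detected peaks, this
#' synthesizes the intensity values from a known (ground-truth) event log so
#' the detection pipeline can be validated end-to-end. Each event adds a
#' raised-cosine transient centred at its time; region-specific sinusoidal
#' drift and Gaussian noise are added on top. Deterministic given the seed;
#' noise-free traces are additive over event sets.
#'
#' @param events Event data frame (`time_s`, `region_label`) or a numeric
#'   vector of event times for a single unnamed region.
#' @param params A [trace_params()].
#' @param duration_s Trace length, seconds; all events must fall inside.
#' @param region_labels Region order of the output columns (defaults to the
#'   labels present in `events`).
#' @return An object of class `intensity_trace`: list with `times_s`,
#'   `values` (samples x regions matrix), `region_labels`, `fs_hz`.
#' @export
events_to_trace <- function(events, params = trace_params(), duration_s,
                            region_labels = NULL) {
  stopifnot(inherits(params, "trace_params"))
  if (is.numeric(events))
    events <- data.frame(time_s = events,
                         region_label = rep("R1", length(events)))
  if (is.null(region_labels)) region_labels <- unique(events$region_label)
  if (!length(region_labels)) region_labels <- "R1"
  if (nrow(events) && (min(events$time_s) < 0 ||
                       max(events$time_s) > duration_s))
    stop("events must lie within [0, duration_s]")
  tgrid <- seq(0, duration_s, by = 1 / params$fs_hz)
  nt <- length(tgrid)
  half <- params$kernel_width_s / 2
  vals <- matrix(0, nrow = nt, ncol = length(region_labels))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  for (j in seq_along(region_labels)) {
    tc <- events$time_s[events$region_label == region_labels[j]]
    for (t0 in tc) {
      i0 <- max(1L, ceiling((t0 - half) * params$fs_hz) + 1L)
      i1 <- min(nt, floor((t0 + half) * params$fs_hz) + 1L)
      if (i1 >= i0) {
        tt <- tgrid[i0:i1]
        vals[i0:i1, j] <- vals[i0:i1, j] + 0.5 * params$kernel_amp *
          (1 + cos(2 * pi * (tt - t0) / params$kernel_width_s))
      }
    }
    if (params$drift_amp > 0)
      vals[, j] <- vals[, j] + params$drift_amp *
        sin(2 * pi * tgrid / params$drift_period_s + (j - 1))
    if (params$noise_sd > 0)
      vals[, j] <- vals[, j] + stats::rnorm(nt, sd = params$noise_sd)
  }
  structure(list(times_s = tgrid, values = vals,
                 region_labels = region_labels, fs_hz = params$fs_hz),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("intensity_trace: %d regions x %d samples at %g Hz (%.3g h)\n",
              length(x$region_labels), length(x$times_s), x$fs_hz,
              utils::tail(x$times_s, 1) / 3600))
  invisible(x)
}

#' Plot intensity traces
#'
#' @param x An `intensity_trace`.
#' @param regions Labels to draw (default all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.intensity_trace <- function(x, regions = x$region_labels, ...) {
  j <- match(regions, x$region_labels)
  off <- (seq_along(j) - 1) * (max(x$values[, j]) - min(x$values[, j]))
  graphics::matplot(x$times_s, sweep(x$values[, j, drop = FALSE], 2, -off),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "intensity (offset)", ...)
  graphics::legend("topright", legend = regions, lty = 1,
                   col = seq_along(j), bty = "n", cex = 0.8)
  invisible(x)
}

#' Scenario fixture factory: simulation plus rendered traces
#'
#' Runs one of the canonical protocols and renders its event log into
#' intensity traces, returning both so that analysis output can be scored
#' against ground truth.
#'
#' @param scenario One of `"intact"`, `"fragment"`, `"tap"`, `"paced"`,
#'   `"development"`.
#' @param stage Stage preset label (`"e9"`, `"e10"`, `"e12"`).
#' @param seed Integer seed driving both the simulation and the noise.
#' @param duration_h Rendered span in hours (default 1). The development
#'   scenario simulates `6 + duration_h` hours with adaptation and renders
#'   the final `duration_h`.
#' @param trace_par A [trace_params()] (its seed is overridden by `seed`).
#' @return A list with `trace` (an `intensity_trace`; for `"fragment"`, one
#'   trace per region rendered jointly), `truth` (the generating
#'   `caecum_sim`), and scenario extras (`tap` for the tap scenario).
#' @export
generate_bundle <- function(scenario = c("intact", "fragment", "tap",
                                         "paced", "development"),
                            stage = "e10", seed = 1L, duration_h = 1,
                            trace_par = trace_params()) {
  scenario <- match.arg(scenario)
  trace_par$seed <- as.integer(seed) + 1000L
  cfg <- stage_preset(stage, seed = seed)
  dur <- duration_h * 3600
  if (scenario == "intact") {
    sim <- simulate_chain(cfg, dur)
    trace <- events_to_trace(sim$events, trace_par, dur,
                             region_labels = cfg$regions$label)
    list(trace = trace, truth = sim)
  } else if (scenario == "fragment") {
    rates <- run_fragments(cfg, duration_h)
    sims <- attr(rates, "sims")
    ev <- do.call(rbind, lapply(seq_along(sims), function(i) {
      e <- sims[[i]]$events
      e$region_label <- cfg$regions$label[i]
      e
    }))
    trace <- events_to_trace(ev, trace_par, dur,
                             region_labels = cfg$regions$label)
    list(trace = trace, truth = sims, rates = rates)
  } else if (scenario == "tap") {
    row <- region_row(cfg, "P2")
    p2 <- do.call(region_params, as.list(cfg$regions[row, ]))
    tap <- run_tap(p2, 40, seed = seed)
    dur_tap <- tap$sim$duration_s
    trace <- events_to_trace(tap$sim$events, trace_par, dur_tap,
                             region_labels = "P2")
    list(trace = trace, truth = tap$sim, tap = tap)
  } else if (scenario == "paced") {
    res <- run_paced(cfg, paced_label = "D4", interval_s = 30,
                     duration_h = duration_h, observe_label = "D2")
    trace <- events_to_trace(res$sim$events, trace_par, dur,
                             region_labels = cfg$regions$label)
    list(trace = trace, truth = res$sim, paced = res)
  } else { # development
    sim <- simulate_chain(cfg, (6 + duration_h) * 3600)
    ev <- sim$events
    start <- 6 * 3600
    ev <- ev[ev$time_s > start, ]
    ev$time_s <- ev$time_s - start
    trace <- events_to_trace(ev, trace_par, dur,
                             region_labels = cfg$regions$label)
    list(trace = trace, truth = sim, window_start_s = start)
  }
}
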