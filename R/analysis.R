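#' Per-region hourly contraction-rate summary
#'
#' @param events Event data frame with columns `time_s`, `region_label`,
#'   `kind` (as produced by [simulate_chain()] or [assign_waves()]).
#' @param window Numeric `c(start_s, end_s)` observation window; events with
#'   `start < time_s <= end` are counted.
#' @param labels Optional region labels fixing row order (defaults to order
#'   of first appearance).
#' @return A data frame of class `rate_summary` with per-region
#'   `active_per_h`, `passive_per_h`, `forced_per_h` and `total_per_h`.
#' @export
summarize_rates <- function(events, window, labels = NULL) {
  stopifnot(is.data.frame(events), length(window) == 2)
  if (diff(window) <= 0) stop("empty observation window")
  hours <- diff(window) / 3600
  if (is.null(labels)) labels <- unique(events$region_label)
  ev <- events[events$time_s > window[1] & events$time_s <= window[2], ]
  count <- function(lab, kind)
    sum(ev$region_label == lab & ev$kind == kind) / hours
  out <- data.frame(label = labels,
                    active_per_h = vapply(labels, count, 0, kind = "active"),
                    passive_per_h = vapply(labels, count, 0, kind = "passive"),
                    forced_per_h = vapply(labels, count, 0, kind = "forced"),
                    stringsAsFactors = FALSE)
  out$total_per_h <- out$active_per_h + out$passive_per_h + out$forced_per_h
  rownames(out) <- NULL
  attr(out, "window") <- window
  class(out) <- c("rate_summary", "data.frame")
  out
}

#' Contraction-detector settings
#'
#' @param detrend `"segmented"` (piecewise-linear baseline removal over
#'   `segment_s` windows, robust to slow specimen drift; default) or
#'   `"linear"` (single least-squares line).
#' @param min_prominence_z Peak threshold in standardized (z) units after
#'   detrending.
#' @param min_separation_s Minimum spacing between accepted peaks, seconds;
#'   kept below the 5-s contraction refractory period.
#' @param segment_s Segment length for segmented detrending, seconds.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(detrend = c("segmented", "linear"),
                            min_prominence_z = 3,
                            min_separation_s = 4,
                            segment_s = 100) {
  detrend <- match.arg(detrend)
  if (min_prominence_z <= 0) stop("min_prominence_z must be > 0")
  if (min_separation_s <= 0) stop("min_separation_s must be >= one sample")
  structure(list(detrend = detrend, min_prominence_z = min_prominence_z,
                 min_separation_s = min_separation_s, segment_s = segment_s),
            class = "detector_params")
}

remove_trend <- function(x, t, params) {
  if (params$detrend == "linear") {
    stats::lm.fit(cbind(1, t), x)$residuals
  } else {
    # equal-length segments close to segment_s, so no short trailing stub
    # can absorb a transient into its local trend fit
    nseg <- max(1, round((max(t) - min(t)) / params$segment_s))
    breaks <- seq(min(t), max(t), length.out = nseg + 1)
    seg <- findInterval(t, breaks, rightmost.closed = TRUE)
    res <- x
    for (s in unique(seg)) {
      i <- which(seg == s)
      if (length(i) > 2) {
        res[i] <- stats::lm.fit(cbind(1, t[i]), x[i])$residuals
      } else {
        res[i] <- x[i] - mean(x[i])
      }
    }
    res
  }
}

#' Detect contraction events in intensity traces
#'
#' Implements the measurement chain used on the 1-Hz video-derived intensity
#' recordings: remove the baseline trend, standardize to zero mean and unit
#' variance, and keep local maxima exceeding `min_prominence_z` standardized
#' units with at least `min_separation_s` spacing. Detections are invariant
#' under affine intensity transforms and under addition of a linear trend.
#'
#' @param trace An [events_to_trace()] result (class `intensity_trace`).
#' @param params A [detector_params()].
#' @return A named list (one element per region label) of sorted event times
#'   in seconds.
#' @export
detect_contractions <- function(trace, params = detector_params()) {
  stopifnot(inherits(trace, "intensity_trace"),
            inherits(params, "detector_params"))
  t <- trace$times_s
  if (length(t) < 3) stop("trace must contain at least 3 samples")
  dts <- diff(t)
  if (max(dts) - min(dts) > 1e-9) stop("trace must be uniformly sampled")
  fs <- trace$fs_hz
  min_dist <- max(1L, as.integer(round(params$min_separation_s * fs)))
  out <- lapply(seq_along(trace$region_labels), function(j) {
    x <- remove_trend(trace$values[, j], t, params)
    s <- stats::sd(x)
    if (s == 0) return(numeric(0))
    z <- (x - mean(x)) / s
    pk <- pracma::findpeaks(z, minpeakheight = params$min_prominence_z,
                            minpeakdistance = min_dist)
    if (is.null(pk)) return(numeric(0))
    sort(t[pk[, 2]])
  })
  stats::setNames(out, trace$region_labels)
}

#' Reconstruct waves from per-region event times
#'
#' Greedily chains detected events across adjacent regions whose inter-region
#' lags match the conduction delay within `max_lag_s`. The earliest event of
#' a chain is the origin (an active contraction); events reached from it are
#' passive; unchained events are active singletons (range 1). Chains extend
#' from the origin in both directions, with monotone non-decreasing arrival
#' times and contiguous region indices, and every event joins at most one
#' wave.
#'
#' @param event_times Named list of sorted event-time vectors, one per region
#'   in proximal-to-distal order (as from [detect_contractions()]).
#' @param conduction_delay_s Expected per-boundary lag, seconds.
#' @param max_lag_s Lag tolerance per boundary, seconds (at least the
#'   sampling interval of the upstream detector).
#' @return An object of class `wave_assignment`: list with `events` (columns
#'   `time_s`, `region_index`, `region_label`, `kind`, `wave_id`) and
#'   `waves` (origin, start time, reach, `range`).
#' @export
assign_waves <- function(event_times, conduction_delay_s = 1,
                         max_lag_s = 1.5) {
  stopifnot(is.list(event_times), !is.null(names(event_times)))
  labels <- names(event_times)
  n <- length(labels)
  ev <- data.frame(
    time_s = unlist(event_times, use.names = FALSE),
    row = rep(seq_len(n), lengths(event_times)))
  ev <- ev[order(ev$time_s, ev$row), , drop = FALSE]
  m <- nrow(ev)
  wave_id <- rep(NA_integer_, m)
  ord <- seq_len(m)
  wv_origin <- integer(0); wv_start <- numeric(0)
  wv_prox <- integer(0); wv_dist <- integer(0)

  next_link <- function(r, t0, d) {
    # nearest unassigned event in region r+d within the lag window
    cand <- which(is.na(wave_id) & ev$row == r + d &
                    ev$time_s >= t0 &
                    abs(ev$time_s - t0 - conduction_delay_s) <= max_lag_s)
    if (!length(cand)) return(NA_integer_)
    cand[which.min(abs(ev$time_s[cand] - t0 - conduction_delay_s))]
  }
  wid <- 0L
  for (i in ord) {
    if (!is.na(wave_id[i])) next
    wid <- wid + 1L
    wave_id[i] <- wid
    prox <- dist <- ev$row[i]
    for (d in c(-1L, 1L)) {
      r <- ev$row[i]; t0 <- ev$time_s[i]
      while (r + d >= 1L && r + d <= n) {
        j <- next_link(r, t0, d)
        if (is.na(j)) break
        wave_id[j] <- wid
        r <- r + d; t0 <- ev$time_s[j]
        if (r < prox) prox <- r
        if (r > dist) dist <- r
      }
    }
    wv_origin[wid] <- ev$row[i]; wv_start[wid] <- ev$time_s[i]
    wv_prox[wid] <- prox; wv_dist[wid] <- dist
  }
  origin_of <- wv_origin[wave_id]
  start_of <- wv_start[wave_id]
  events <- data.frame(time_s = ev$time_s,
                       region_index = ev$row - 1L,
                       region_label = labels[ev$row],
                       kind = ifelse(ev$row == origin_of &
                                       ev$time_s == start_of,
                                     "active", "passive"),
                       wave_id = wave_id,
                       stringsAsFactors = FALSE)
  waves <- data.frame(wave_id = seq_len(wid),
                      origin_region = wv_origin - 1L,
                      origin_label = labels[wv_origin],
                      start_time_s = wv_start,
                      prox_reach = wv_prox - 1L,
                      dist_reach = wv_dist - 1L,
                      range = wv_dist - wv_prox + 1L,
                      stringsAsFactors = FALSE)
  structure(list(events = events, waves = waves, labels = labels),
            class = "wave_assignment")
}

#' Propagation-range census and passing-wave exposure
#'
#' Summarizes wave ranges by origin region and counts, for every region, the
#' number of waves that traversed it without originating there (its
#' passing-wave exposure).
#'
#' @param x A `wave_assignment` (from [assign_waves()]) or a `caecum_sim`
#'   (ground-truth wave log).
#' @return A list with `by_origin` (per-origin wave count and mean range) and
#'   `exposure` (per-region passing-wave counts).
#' @export
range_census <- function(x) {
  if (inherits(x, "caecum_sim")) {
    waves <- x$waves
    labels <- x$config$regions$label
  } else if (inherits(x, "wave_assignment")) {
    waves <- x$waves
    labels <- x$labels
  } else stop("x must be a wave_assignment or caecum_sim")
  by_origin <- do.call(rbind, lapply(labels, function(l) {
    w <- waves[waves$origin_label == l, ]
    data.frame(origin_label = l, n_waves = nrow(w),
               mean_range = if (nrow(w)) mean(w$range) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  idx <- seq_along(labels) - 1L
  exposure <- data.frame(
    label = labels,
    n_passing = vapply(idx, function(i)
      sum(waves$prox_reach <= i & waves$dist_reach >= i &
            waves$origin_region != i), 0L),
    stringsAsFactors = FALSE)
  list(by_origin = by_origin, exposure = exposure)
}

#' Interruption-delay estimation from an event-time series
#'
#' Given spontaneous contraction times around a known interruption (tap),
#' computes `T` (mean of up to `n_control` control intervals preceding the
#' interrupted cycle), `tau` (the interval spanning the tap) and the delay
#' `tau - T`. Detections within `exclude_tol_s` of the tap (the forced
#' transient itself) are discarded first.
#'
#' @param event_times Sorted vector of detected contraction times, seconds.
#' @param tap_time_s Known tap time, seconds.
#' @param n_control Maximum number of control intervals averaged into `T`.
#' @param exclude_tol_s Half-width of the exclusion window around the tap.
#' @return A `delay_estimate` list with `T_s`, `tau_s`, `delay_s`,
#'   `tap_offset_s`.
#' @export
estimate_delay <- function(event_times, tap_time_s, n_control = 3,
                           exclude_tol_s = 3) {
  tt <- sort(event_times)
  tt <- tt[abs(tt - tap_time_s) > exclude_tol_s]
  before <- tt[tt < tap_time_s]
  after <- tt[tt > tap_time_s]
  if (!length(before) || !length(after))
    stop("tap is not bracketed by spontaneous contractions")
  t_prev <- max(before); t_next <- min(after)
  ctrl <- diff(before)
  if (!length(ctrl))
    stop("no control interval precedes the interrupted cycle")
  ctrl <- utils::tail(ctrl, n_control)
  T_s <- mean(ctrl)
  tau_s <- t_next - t_prev
  structure(list(T_s = T_s, tau_s = tau_s, delay_s = tau_s - T_s,
                 tap_offset_s = tap_time_s - t_prev),
            class = "delay_estimate")
}

#' Paired t statistic
#'
#' Classical paired t test on the differences `x - y`, with p-value from the
#' t distribution with `n - 1` degrees of freedom. Degenerate zero-variance
#' differences follow the documented convention: all-zero differences give
#' `t = 0, p = 1`; constant nonzero differences give `t = +/-Inf, p = 0`.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 2`.
#' @return A list with `t`, `p`, `df` and `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t_stat <- md / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  list(t = t_stat, p = p, df = n - 1, mean_diff = md)
}
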