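#' Write a chain configuration to a YAML file
#'
#' @param config A [chain_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "chain_config"))
  regions <- lapply(seq_len(config$n_regions), function(i) {
    r <- as.list(config$regions[i, ])
    if (is.na(r$survival_prob)) r$survival_prob <- NULL
    r
  })
  obj <- list(stage = config$stage, seed = config$seed,
              coupling = unclass(config$coupling),
              adaptation = unclass(config$adaptation),
              regions = regions)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a chain configuration from a YAML file
#'
#' Two schemas are accepted. A preset file names a stage preset and optional
#' overrides:
#' ```yaml
#' preset: e12
#' seed: 7
#' regions:
#'   P1: {latent_period_s: 10}
#' ```
#' A full file (as written by [save_config()]) spells out `stage`, `seed`,
#' `coupling`, `adaptation` and the per-region parameter list. Unknown keys
#' raise an error naming the offending key path.
#'
#' @param path YAML file path.
#' @return A fully resolved [chain_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$preset)) {
    overrides <- obj[setdiff(names(obj), c("preset", "seed"))]
    stage_preset(obj$preset, seed = if (is.null(obj$seed)) 1L else obj$seed,
                 overrides = if (length(overrides)) overrides else NULL)
  } else {
    required <- c("stage", "regions")
    missing <- setdiff(required, names(obj))
    if (length(missing))
      stop("config is missing key(s): ", paste(missing, collapse = ", "))
    allowed <- c("stage", "seed", "coupling", "adaptation", "regions")
    bad <- setdiff(names(obj), allowed)
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    regions <- lapply(seq_along(obj$regions), function(i) {
      r <- obj$regions[[i]]
      bad <- setdiff(names(r), c("index", "label", "latent_period_s",
                                 "jitter_cv", "reset_efficacy",
                                 "refractory_s", "survival_prob"))
      if (length(bad))
        stop(sprintf("unknown key(s) at regions[%d]: %s", i,
                     paste(bad, collapse = ", ")))
      do.call(region_params, r)
    })
    coupling <- if (is.null(obj$coupling)) coupling_params() else
      do.call(coupling_params, obj$coupling)
    adaptation <- if (is.null(obj$adaptation)) adaptation_params() else
      do.call(adaptation_params, obj$adaptation)
    chain_config(stage = obj$stage, regions = regions, coupling = coupling,
                 adaptation = adaptation,
                 seed = if (is.null(obj$seed)) 1L else obj$seed)
  }
}

#' Write an event log to CSV
#'
#' Columns `time_s`, `region_index`, `region_label`, `kind`, `wave_id`
#' (empty for active/forced events). RFC-4180, header row, UTF-8.
#'
#' @param x A `caecum_sim` or an event data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(x, path) {
  ev <- if (inherits(x, "caecum_sim")) x$events else x
  utils::write.csv(ev, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a wave log to CSV
#'
#' Columns `wave_id`, `origin_region`, `origin_label`, `start_time_s`,
#' `range`, `terminal_region`.
#'
#' @inheritParams write_event_csv
#' @export
write_wave_csv <- function(x, path) {
  wv <- if (inherits(x, "caecum_sim")) x$waves else x
  keep <- intersect(c("wave_id", "origin_region", "origin_label",
                      "start_time_s", "direction", "range",
                      "n_passive", "terminal_region"), names(wv))
  utils::write.csv(wv[, keep], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a per-region rate summary to CSV
#'
#' @param rates A `rate_summary` (see [summarize_rates()]).
#' @param path Output file path.
#' @export
write_rate_csv <- function(rates, path) {
  utils::write.csv(as.data.frame(rates), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write/read intensity traces as CSV
#'
#' Column `time_s` followed by one intensity column per region label.
#'
#' @param trace An `intensity_trace`.
#' @param path File path.
#' @return For [read_trace_csv()], an `intensity_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  df <- data.frame(time_s = trace$times_s, trace$values)
  names(df) <- c("time_s", trace$region_labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be time_s")
  t <- df$time_s
  if (length(t) < 2) stop("trace too short")
  fs <- 1 / stats::median(diff(t))
  structure(list(times_s = t,
                 values = as.matrix(df[, -1, drop = FALSE]),
                 region_labels = names(df)[-1], fs_hz = fs),
            class = "intensity_trace")
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline run byte-identically:
#' the command, the fully resolved configuration snapshot, the seed, the
#' simulated span, the output files and the package version.
#'
#' @param path Output JSON path.
#' @param command Character command/subcommand description.
#' @param config The resolved [chain_config()] (or `NULL`).
#' @param seed Integer seed used.
#' @param duration_s Simulated span, seconds (or `NA`).
#' @param outputs Character vector of files written by the run.
#' @export
write_manifest <- function(path, command, config, seed, duration_s,
                           outputs) {
  snapshot <- if (is.null(config)) NULL else list(
    stage = config$stage, seed = config$seed,
    coupling = unclass(config$coupling),
    adaptation = unclass(config$adaptation),
    regions = config$regions)
  obj <- list(command = command,
              package = "peristalsim",
              version = as.character(utils::packageVersion("peristalsim")),
              seed = seed, duration_s = duration_s,
              outputs = outputs, config = snapshot)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
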