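#' Define a stimulation protocol
#'
#' A protocol specifies the current time course of one stimulation condition
#' (linear ramp-up, constant plateau, linear ramp-down) and the schedule of
#' online perception probes asked while the behavioural task runs.
#'
#' The conventional active protocol ramps up over 30 s, holds the target
#' current for 10 min and ramps down over 30 s; the fade-in/fade-out sham
#' holds it for only 20 s, so that early scalp sensations are matched but the
#' current is off for almost the whole session.
#'
#' @param name Label for the protocol (e.g. `"active"`, `"sham"`).
#' @param ramp_up_s Ramp-up duration in seconds (current rises linearly from 0).
#' @param plateau_s Plateau duration in seconds at `current_mA`.
#' @param ramp_down_s Ramp-down duration in seconds (linear fall back to 0).
#' @param current_mA Plateau current in milliamps.
#' @param probe_interval_s Seconds between consecutive probe points (default 30).
#' @param n_probes Number of probe points (default 32, spanning 16 min).
#'
#' @return An object of class `protocol_spec`.
#' @examples
#' active <- protocol_spec("active", 30, 600, 30, 2)
#' probe_schedule(active)
#' @export
protocol_spec <- function(name, ramp_up_s, plateau_s, ramp_down_s, current_mA,
                          probe_interval_s = 30, n_probes = 32) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in list(ramp_up_s, plateau_s, ramp_down_s, current_mA,
                 probe_interval_s, n_probes)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("protocol durations, current and probe settings must be single non-negative numbers")
  }
  if (n_probes != round(n_probes)) stop("n_probes must be an integer count")
  structure(
    list(name = name,
         ramp_up_s = as.numeric(ramp_up_s),
         plateau_s = as.numeric(plateau_s),
         ramp_down_s = as.numeric(ramp_down_s),
         current_mA = as.numeric(current_mA),
         probe_interval_s = as.numeric(probe_interval_s),
         n_probes = as.integer(n_probes)),
    class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("Protocol '%s': %g s ramp-up + %g s plateau + %g s ramp-down at %g mA\n",
              x$name, x$ramp_up_s, x$plateau_s, x$ramp_down_s, x$current_mA))
  cat(sprintf("  %d probes every %g s (window %g s)\n",
              x$n_probes, x$probe_interval_s, x$n_probes * x$probe_interval_s))
  invisible(x)
}

#' Total time during which any current flows
#'
#' @param spec A [protocol_spec()].
#' @return Seconds from stimulation onset to the end of the ramp-down.
#' @export
on_duration <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  spec$ramp_up_s + spec$plateau_s + spec$ramp_down_s
}

#' Default stimulation protocols
#'
#' The four protocols of the two-study layout: active (30 s + 10 min + 30 s)
#' and fade-in/fade-out sham (30 s + 20 s + 30 s), each at 1 mA and at 2 mA,
#' with 32 probes every 30 s.
#'
#' @return Named list of [protocol_spec()] objects
#'   (`active_1mA`, `sham_1mA`, `active_2mA`, `sham_2mA`).
#' @export
default_protocols <- function() {
  list(
    active_1mA = protocol_spec("active", 30, 600, 30, 1.0),
    sham_1mA   = protocol_spec("sham",   30,  20, 30, 1.0),
    active_2mA = protocol_spec("active", 30, 600, 30, 2.0),
    sham_2mA   = protocol_spec("sham",   30,  20, 30, 2.0)
  )
}

#' Read protocol specifications from a YAML or JSON config file
#'
#' The file holds a mapping from protocol id to fields matching the
#' [protocol_spec()] arguments; missing `probe_interval_s`/`n_probes` fall
#' back to the defaults (30 s, 32).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of `protocol_spec` objects.
#' @export
read_protocols <- function(path) {
  if (!file.exists(path)) stop("protocol config not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("protocol config must be .yaml/.yml or .json: ", path)
  if (!length(raw)) stop("protocol config is empty: ", path)
  out <- lapply(names(raw), function(id) {
    f <- raw[[id]]
    need <- c("name", "ramp_up_s", "plateau_s", "ramp_down_s", "current_mA")
    miss <- setdiff(need, names(f))
    if (length(miss))
      stop("protocol '", id, "' is missing fields: ", paste(miss, collapse = ", "))
    protocol_spec(f$name, f$ramp_up_s, f$plateau_s, f$ramp_down_s, f$current_mA,
                  probe_interval_s = f$probe_interval_s %||% 30,
                  n_probes = f$n_probes %||% 32)
  })
  names(out) <- names(raw)
  out
}

#' Probe time schedule of a protocol
#'
#' Probe k is timestamped at the end of its k-th interval, i.e. at
#' `k * probe_interval_s` seconds after stimulation onset; intervals are
#' closed at their right edge. With the defaults the probes fall at
#' 30, 60, ..., 960 s.
#'
#' @param spec A [protocol_spec()].
#' @return Numeric vector of `n_probes` probe times in seconds.
#' @export
probe_schedule <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (spec$n_probes == 0L) return(numeric(0))
  seq_len(spec$n_probes) * spec$probe_interval_s
}

#' Ideal response curve of a protocol
#'
#' The weighted-score time series of a hypothetical participant who reports
#' the stimulation state with 100% accuracy and maximal confidence: +10 at
#' every probe at which any current flows (ramps count as on), -10 otherwise.
#' Values sit at the extremes of the weighted-score scale so participant and
#' ideal series share one scale; the cross-correlation normalization is
#' scale-invariant, so this choice cannot affect coefficients.
#'
#' @param spec A [protocol_spec()].
#' @return An object of class `ideal_curve`: list with `values` (+10/-10 per
#'   probe) and `probe_times_s`.
#' @export
build_ideal_curve <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  times <- probe_schedule(spec)
  on <- times <= on_duration(spec) & on_duration(spec) > 0
  structure(list(values = ifelse(on, 10, -10), probe_times_s = times,
                 protocol = spec$name),
            class = "ideal_curve")
}

#' @export
print.ideal_curve <- function(x, ...) {
  cat(sprintf("Ideal response curve (%s): %d probes, %d on / %d off\n",
              x$protocol, length(x$values), sum(x$values > 0), sum(x$values < 0)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
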