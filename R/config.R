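# Tuning configuration: probe schedule, break thresholds, handle flags.

#' Synchronization tuning configuration
#'
#' Bundles every tuning parameter used by the probe scheduler, the clock
#' filter, break detection and dejittering. Defaults follow the conventional
#' acquisition-system settings: probe bursts of 10 exchanges spaced 10 ms
#' apart, repeated every 5 s, with measurements discarded when their
#' round-trip time exceeds 100 ms.
#'
#' @param time_probe_count Exchanges per probe burst (>= 1).
#' @param time_probe_interval Seconds between exchanges within a burst.
#' @param time_probe_max_rtt Seconds; exchanges with a larger round-trip time
#'   are discarded by the clock filter.
#' @param time_update_interval Seconds between probe bursts.
#' @param handle_jitter Apply per-segment timestamp regression (dejittering)?
#' @param handle_clock_sync Apply the smoothed clock-offset correction?
#' @param break_threshold_seconds Seconds; a gap larger than
#'   \code{max(break_threshold_seconds, break_threshold_samples / nominal_srate)}
#'   splits a stream into segments.
#' @param break_threshold_samples Count; see \code{break_threshold_seconds}.
#' @param force_default_timestamps Discard device-supplied stamps and restamp
#'   each sample at receipt on the recorder clock.
#' @param rls_forgetting Forgetting factor in (0, 1] for the online
#'   recursive-least-squares dejitter.
#' @param offset_jump_threshold Seconds; a step in consecutive clock-offset
#'   measurements larger than this starts a new piece of the offset model
#'   (reconnection to a different host).
#' @param boundary_interval Seconds of data between Boundary chunks written
#'   to XDF files.
#' @param srate_tolerance Relative deviation of the effective from the nominal
#'   sampling rate above which a diagnostic flag is raised.
#' @param buffer_capacity_seconds Outlet buffer capacity, in seconds of data
#'   at the nominal rate.
#' @param multicast_min_rtt,multicast_max_rtt Seconds; accepted round-trip-time
#'   window for discovery over multicast. Parsed from configuration files and
#'   carried for completeness; the in-process resolver does not use them.
#' @return An object of class \code{sync_config} (a named list).
#' @examples
#' cfg <- sync_config(time_probe_count = 5)
#' cfg$time_probe_interval
#' @export
sync_config <- function(time_probe_count = 10,
                        time_probe_interval = 0.010,
                        time_probe_max_rtt = 0.100,
                        time_update_interval = 5,
                        handle_jitter = TRUE,
                        handle_clock_sync = TRUE,
                        break_threshold_seconds = 1,
                        break_threshold_samples = 500,
                        force_default_timestamps = FALSE,
                        rls_forgetting = 1,
                        offset_jump_threshold = 1,
                        boundary_interval = 10,
                        srate_tolerance = 0.01,
                        buffer_capacity_seconds = 360,
                        multicast_min_rtt = 1.0,
                        multicast_max_rtt = 30) {
  stopifnot(time_probe_count >= 1,
            time_probe_interval >= 0,
            time_probe_max_rtt > 0,
            time_update_interval > 0,
            break_threshold_seconds > 0,
            break_threshold_samples > 0,
            rls_forgetting > 0, rls_forgetting <= 1,
            offset_jump_threshold > 0)
  structure(list(
    time_probe_count = as.integer(time_probe_count),
    time_probe_interval = time_probe_interval,
    time_probe_max_rtt = time_probe_max_rtt,
    time_update_interval = time_update_interval,
    handle_jitter = isTRUE(handle_jitter),
    handle_clock_sync = isTRUE(handle_clock_sync),
    break_threshold_seconds = break_threshold_seconds,
    break_threshold_samples = break_threshold_samples,
    force_default_timestamps = isTRUE(force_default_timestamps),
    rls_forgetting = rls_forgetting,
    offset_jump_threshold = offset_jump_threshold,
    boundary_interval = boundary_interval,
    srate_tolerance = srate_tolerance,
    buffer_capacity_seconds = buffer_capacity_seconds,
    multicast_min_rtt = multicast_min_rtt,
    multicast_max_rtt = multicast_max_rtt
  ), class = "sync_config")
}

#' @export
print.sync_config <- function(x, ...) {
  cat("<sync_config>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Map of [tuning] keys as they appear in lsl_api.cfg to sync_config fields.
# HandleJitter / HandleJitterRemoval are accepted as aliases.
.cfg_key_map <- c(
  TimeProbeMaxRTT = "time_probe_max_rtt",
  TimeProbeInterval = "time_probe_interval",
  TimeProbeCount = "time_probe_count",
  TimeUpdateInterval = "time_update_interval",
  MulticastMinRTT = "multicast_min_rtt",
  MulticastMaxRTT = "multicast_max_rtt",
  ForceDefaultTimestamps = "force_default_timestamps",
  HandleJitter = "handle_jitter",
  HandleJitterRemoval = "handle_jitter",
  HandleClockSync = "handle_clock_sync",
  BreakThresholdSeconds = "break_threshold_seconds",
  BreakThresholdSamples = "break_threshold_samples"
)

#' Parse an lsl_api.cfg-style configuration file
#'
#' Reads the plaintext `[tuning]` section of a configuration file. Keys use
#' the conventional spelling (\code{TimeProbeMaxRTT}, \code{TimeProbeInterval},
#' \code{TimeProbeCount}, \code{TimeUpdateInterval}, \code{MulticastMinRTT},
#' \code{MulticastMaxRTT}, \code{ForceDefaultTimestamps});
#' \code{HandleJitter} and \code{HandleJitterRemoval} are aliases for the
#' same flag. Lines outside \code{[tuning]} and unknown keys are ignored.
#'
#' @param path Path to the configuration file.
#' @param base A \code{sync_config} supplying values for keys the file does
#'   not set.
#' @return A \code{sync_config}.
#' @seealso [find_config()] for the directory lookup order.
#' @export
read_sync_config <- function(path, base = sync_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, ";")]
  section <- ""
  vals <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("^\\[|\\]$", "", ln))
      next
    }
    if (section != "tuning") next
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) next
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(.cfg_key_map)) next
    field <- .cfg_key_map[[key]]
    vals[[field]] <- if (field %in% c("force_default_timestamps",
                                      "handle_jitter", "handle_clock_sync")) {
      tolower(val) %in% c("1", "true", "yes", "on")
    } else {
      as.numeric(val)
    }
  }
  out <- unclass(base)
  out[names(vals)] <- vals
  do.call(sync_config, out)
}

#' Locate a configuration file
#'
#' Searches for \code{lsl_api.cfg} in the conventional order: the application
#' directory first, then the per-user directory \code{~/lsl_api/}, then the
#' system directory \code{/etc}. The first existing file wins.
#'
#' @param app_dir Application directory searched first (default: the working
#'   directory).
#' @param user_dir Per-user directory.
#' @param system_dir System-wide directory.
#' @param filename Configuration file name.
#' @return The path of the first file found, or \code{NULL} if none exists.
#' @export
find_config <- function(app_dir = ".",
                        user_dir = path.expand("~/lsl_api"),
                        system_dir = "/etc",
                        filename = "lsl_api.cfg") {
  for (d in c(app_dir, user_dir, system_dir)) {
    p <- file.path(d, filename)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Load the effective configuration
#'
#' Convenience wrapper: [find_config()] then [read_sync_config()], falling
#' back to defaults when no file is present.
#'
#' @inheritParams find_config
#' @return A \code{sync_config}.
#' @export
load_sync_config <- function(app_dir = ".",
                             user_dir = path.expand("~/lsl_api"),
                             system_dir = "/etc") {
  p <- find_config(app_dir, user_dir, system_dir)
  if (is.null(p)) sync_config() else read_sync_config(p)
}
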