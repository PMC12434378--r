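# Canned validation experiments: the two-stream shared-pulse study and the
# clock-filter accuracy study, both fully simulated with known ground truth.

#' Two-stream shared-pulse synchronization experiment
#'
#' Simulates the canonical cross-device timing validation: two regularly
#' sampled streams carry the same physical square wave — stream A on a
#' professional-style device that stamps each sample at capture, stream B on
#' a consumer-style device that stamps at chunk delivery — each behind its
#' own offset and slowly drifting host clock. The recording is synchronized,
#' rising-edge markers are extracted from both streams by half-maximum
#' threshold crossing, edges are paired, and the paired latency differences
#' are centered to their mean. The standard deviation of the centered
#' differences is the residual cross-stream jitter; with jitter handling
#' disabled the chunking sawtooth of stream B survives into it.
#'
#' @param duration Simulated recording length, seconds.
#' @param seed Root seed.
#' @param handle_jitter Enable per-segment timestamp regression.
#' @param srate Sampling rate of both streams, Hz.
#' @param pulse_period Square-wave period, seconds (2 Hz pulse by default).
#' @param chunk_period Stream B's chunk period, seconds.
#' @param clock_offsets Recorder-relative clock offsets of the two device
#'   hosts, seconds.
#' @param drifts Recorder-relative clock drifts (s per s).
#' @param timestamp_noise_std Per-sample stamping noise, seconds.
#' @param net [network_spec()] used for the probe exchanges.
#' @param cfg Base [sync_config()]; its \code{handle_jitter} flag is
#'   overridden by the argument.
#' @return List: \code{report} (an \code{offset_report}; \code{jitter_std}
#'   is the residual cross-stream jitter in seconds), \code{bundle} (the
#'   synchronized recording).
#' @export
two_stream_pulse_experiment <- function(duration = 600, seed = 1,
                                        handle_jitter = TRUE,
                                        srate = 2000, pulse_period = 0.5,
                                        chunk_period = 0.020,
                                        clock_offsets = c(0.5, 0.5),
                                        drifts = c(1e-5, 1e-5),
                                        timestamp_noise_std = 2e-4,
                                        net = network_spec(),
                                        cfg = sync_config()) {
  cfg$handle_jitter <- isTRUE(handle_jitter)
  wave <- square_wave(pulse_period)
  dev_a <- device_spec(stream_info("sigA", "EEG", 1, srate, "float32", "dev-a"),
                       stamp_mode = "capture", signal = wave,
                       timestamp_noise_std = timestamp_noise_std)
  dev_b <- device_spec(stream_info("sigB", "EMG", 1, srate, "float32", "dev-b"),
                       stamp_mode = "delivery", chunk_period = chunk_period,
                       signal = wave,
                       timestamp_noise_std = timestamp_noise_std)
  clocks <- list(virtual_clock(clock_offsets[1], drifts[1]),
                 virtual_clock(clock_offsets[2], drifts[2]))
  bundle <- simulate_session(list(dev_a, dev_b), clocks, net, cfg,
                             duration = duration, seed = seed)
  bundle <- synchronize_recording(bundle, cfg)
  ma <- extract_threshold_markers(bundle$streams$sigA$timestamps_sync,
                                  as.numeric(bundle$streams$sigA$values[, 1]))
  mb <- extract_threshold_markers(bundle$streams$sigB$timestamps_sync,
                                  as.numeric(bundle$streams$sigB$values[, 1]))
  report <- pairwise_offset_stats(ma, mb,
                                  max_pair_distance = pulse_period / 2)
  list(report = report, bundle = bundle)
}

#' Clock-filter accuracy experiment
#'
#' Runs repeated probe bursts between the recorder and a drifting device
#' clock through a spiky network and measures, for every burst, the error of
#' the retained minimum-RTT offset estimate against the true clock offset at
#' that instant. The maximum absolute error over all bursts is the headline
#' number: it stays bounded by the network's non-spiked delay asymmetry even
#' though individual exchanges are hit by large delay spikes.
#'
#' @param n_bursts Number of probe bursts.
#' @param seed Integer seed.
#' @param clock_offset,drift Device host clock parameters (seconds, s/s).
#' @param net [network_spec()]; the default is a LAN-like 0.2 ms base delay
#'   with exponential 0.5 ms jitter and 50 ms spikes at probability 0.1,
#'   symmetric paths.
#' @param cfg [sync_config()] (probe schedule; bursts are spaced
#'   \code{time_update_interval} apart).
#' @return List: \code{errors} (per-burst signed estimate minus truth,
#'   seconds), \code{max_abs_error} (seconds), \code{series} (the retained
#'   [offset_series()]).
#' @export
clock_filter_experiment <- function(n_bursts = 100, seed = 1,
                                    clock_offset = 0.5, drift = 1e-5,
                                    net = network_spec(),
                                    cfg = sync_config()) {
  recorder <- virtual_clock()
  device <- virtual_clock(clock_offset, drift)
  with_child_seed(seed, "clock-filter-experiment", {
    at <- ofs <- rtt <- err <- numeric(n_bursts)
    keep <- logical(n_bursts)
    for (i in seq_len(n_bursts)) {
      t0 <- (i - 1) * cfg$time_update_interval
      m <- tryCatch(run_probe_burst(recorder, device, net, cfg, t_start = t0),
                    streamsync_empty_burst = function(e) NULL)
      if (is.null(m)) next
      keep[i] <- TRUE
      at[i] <- m$at; ofs[i] <- m$ofs; rtt[i] <- m$rtt
      err[i] <- m$ofs - true_offset(device, attr(m, "truth_time"))
    }
    list(errors = err[keep],
         max_abs_error = max(abs(err[keep])),
         series = offset_series(at[keep], ofs[keep], rtt[keep]))
  })
}
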