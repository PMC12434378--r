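# Virtual clock / network / device simulator. Generates fully synthetic
# multi-stream recordings with known ground truth (clock parameters, setup
# offsets, network behavior) so every downstream stage is testable without
# hardware.

#' A virtual clock with offset, drift and read noise
#'
#' Models a host clock as \code{epoch_offset + (1 + drift) * t_true} plus
#' Gaussian read noise. Reads are clamped to be non-decreasing per clock as
#' long as the underlying true times do not run backwards (interleaved probe
#' exchanges may legitimately query the clock out of order; those reads are
#' not clamped against each other).
#'
#' @param epoch_offset Seconds the clock is ahead of true time at t = 0.
#' @param drift Dimensionless rate (s per s); 1e-5 is 10 ppm.
#' @param noise_std Standard deviation of read noise, seconds.
#' @return A \code{virtual_clock} object (an environment, so reads can keep
#'   monotonicity state).
#' @examples
#' ck <- virtual_clock(epoch_offset = 2.5, drift = 1e-5)
#' local_time(ck, 100)  # 102.501
#' @export
virtual_clock <- function(epoch_offset = 0, drift = 0, noise_std = 0) {
  stopifnot(noise_std >= 0)
  e <- new.env(parent = emptyenv())
  e$epoch_offset <- epoch_offset
  e$drift <- drift
  e$noise_std <- noise_std
  e$last_det <- -Inf
  e$last_out <- -Inf
  class(e) <- "virtual_clock"
  e
}

#' Read a virtual clock at given true times
#'
#' @param clock A [virtual_clock()].
#' @param t_true True times in seconds (non-negative).
#' @return Local clock readings, seconds. Uses the current RNG stream for
#'   read noise.
#' @export
local_time <- function(clock, t_true) {
  stopifnot(all(t_true >= 0))
  det <- clock$epoch_offset + (1 + clock$drift) * t_true
  n <- length(det)
  if (n == 0L) return(numeric())
  out <- det
  if (clock$noise_std > 0) {
    out <- out + stats::rnorm(n, 0, clock$noise_std)
    if (!is.unsorted(det)) {
      if (det[1L] >= clock$last_det) out[1L] <- max(out[1L], clock$last_out)
      out <- cummax(out)
    } else {
      for (i in seq_len(n)) {   # rare path: out-of-order reads
        if (det[i] >= clock$last_det) {
          out[i] <- max(out[i], clock$last_out)
          clock$last_det <- det[i]; clock$last_out <- out[i]
        }
      }
    }
  }
  if (det[n] >= clock$last_det) {
    clock$last_det <- det[n]; clock$last_out <- out[n]
  }
  out
}

#' True offset of a clock relative to true time
#'
#' Ground-truth helper: the noiseless clock reading minus true time,
#' \code{epoch_offset + drift * t_true}.
#'
#' @inheritParams local_time
#' @return Seconds.
#' @export
true_offset <- function(clock, t_true) {
  clock$epoch_offset + clock$drift * t_true
}

#' Network delay environment
#'
#' Per-direction transmission delay is
#' \code{base_delay +/- asymmetry/2 + Exp(jitter_scale) + spike}, where a
#' spike of \code{spike_magnitude} seconds occurs with probability
#' \code{spike_prob} — the random transmission-delay spikes the minimum-RTT
#' clock filter exists to suppress. Exponential jitter plus Bernoulli spikes
#' is a documented modeling choice; all parameters are surfaced here.
#'
#' @param base_delay Deterministic one-way delay, seconds.
#' @param jitter_scale Mean of the exponential jitter term, seconds (0 = no
#'   jitter).
#' @param spike_prob Probability of a delay spike per transmission.
#' @param spike_magnitude Added delay of a spike, seconds.
#' @param asymmetry Constant forward-minus-backward delay difference,
#'   seconds.
#' @return A \code{network_spec} (named list).
#' @export
network_spec <- function(base_delay = 0.0002, jitter_scale = 0.0005,
                         spike_prob = 0.1, spike_magnitude = 0.050,
                         asymmetry = 0) {
  stopifnot(base_delay >= 0, jitter_scale >= 0,
            spike_prob >= 0, spike_prob <= 1, spike_magnitude >= 0)
  structure(list(base_delay = base_delay, jitter_scale = jitter_scale,
                 spike_prob = spike_prob, spike_magnitude = spike_magnitude,
                 asymmetry = asymmetry),
            class = "network_spec")
}

#' Draw network transmission delays
#'
#' @param net A [network_spec()].
#' @param direction \code{"forward"} (initiator to responder) or
#'   \code{"backward"}.
#' @param n Number of delays to draw.
#' @return Non-negative delays in seconds, drawn from the current RNG stream.
#' @export
sample_delay <- function(net, direction = c("forward", "backward"), n = 1) {
  direction <- match.arg(direction)
  d <- net$base_delay + if (direction == "forward") net$asymmetry / 2 else -net$asymmetry / 2
  d <- rep(d, n)
  if (net$jitter_scale > 0) d <- d + stats::rexp(n, rate = 1 / net$jitter_scale)
  if (net$spike_prob > 0) {
    d <- d + net$spike_magnitude * (stats::runif(n) < net$spike_prob)
  }
  pmax(d, 0)
}

#' Simulated device description
#'
#' @param info A [stream_info()] describing the stream the device publishes.
#' @param srate Sampling rate in Hz; 0 declares an irregular (event/marker)
#'   stream.
#' @param chunk_period Seconds of data per transmitted chunk; 0 means
#'   per-sample transmission.
#' @param setup_offset The device-specific constant latency tau, seconds,
#'   between physical capture and software timestamping (buffers, wireless
#'   link, driver). Positive means the stamp trails capture; output
#'   transducers can have negative values.
#' @param timestamp_noise_std Std of the zero-mean stamping noise epsilon,
#'   seconds.
#' @param stamp_mode \code{"capture"}: each sample is stamped when captured
#'   (professional amplifiers); \code{"delivery"}: samples are stamped when
#'   their chunk is handed to the host (consumer devices), so stamps cluster
#'   at chunk boundaries.
#' @param dropout_windows List of \code{c(start, end)} true-time windows
#'   (half-open) during which the device emits nothing.
#' @param signal Function of true capture times returning sample values
#'   (vector for 1 channel or an n-by-channel matrix). Default: zeros.
#' @param event_times For irregular streams, the true event times.
#' @return A \code{device_spec} (named list).
#' @export
device_spec <- function(info, srate = info$nominal_srate, chunk_period = 0,
                        setup_offset = 0, timestamp_noise_std = 0,
                        stamp_mode = c("capture", "delivery"),
                        dropout_windows = list(),
                        signal = NULL, event_times = numeric()) {
  stamp_mode <- match.arg(stamp_mode)
  stopifnot(srate >= 0, chunk_period >= 0, timestamp_noise_std >= 0)
  if (srate == 0 && chunk_period > 0) {
    stop("irregular streams (srate = 0) emit per event; chunk_period > 0 is ambiguous")
  }
  structure(list(info = info, srate = srate, chunk_period = chunk_period,
                 setup_offset = setup_offset,
                 timestamp_noise_std = timestamp_noise_std,
                 stamp_mode = stamp_mode, dropout_windows = dropout_windows,
                 signal = signal, event_times = event_times),
            class = "device_spec")
}

.in_windows <- function(t, windows) {
  if (length(windows) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (w in windows) hit <- hit | (t >= w[1] & t < w[2])
  hit
}

#' Simulate one device's recorded stream
#'
#' Regular streams capture \code{floor(duration * srate)} samples at true
#' times \code{k / srate}, k = 0, 1, .... The observed stamp of a sample is
#' the device clock read at capture time (capture mode) or at its chunk's
#' delivery time (delivery mode), plus the setup offset tau and stamping
#' noise. Chunking always delays availability (the delivery time) but only
#' delivery-stamped devices let it contaminate the stamp itself. Samples
#' inside dropout windows are omitted, leaving gaps.
#'
#' @param dev A [device_spec()].
#' @param clock The device host's [virtual_clock()].
#' @param duration Simulated duration in seconds.
#' @return A \code{recorded_stream}: list with \code{info},
#'   \code{timestamps_raw}, \code{values}, \code{offsets} (NULL here; filled
#'   by [simulate_session()] or [record()]), \code{timestamps_sync},
#'   \code{segments}, and a \code{truth} entry holding \code{t_actual},
#'   delivery times, clock parameters and tau.
#' @export
simulate_device <- function(dev, clock, duration) {
  stopifnot(duration > 0)
  if (dev$srate > 0) {
    n <- floor(duration * dev$srate + 1e-9)
    t_actual <- (seq_len(n) - 1) / dev$srate
  } else {
    t_actual <- dev$event_times[dev$event_times < duration]
  }
  keep <- !.in_windows(t_actual, dev$dropout_windows)
  t_actual <- t_actual[keep]
  n <- length(t_actual)

  if (dev$chunk_period > 0) {
    delivery <- (floor(t_actual / dev$chunk_period) + 1) * dev$chunk_period
  } else {
    delivery <- t_actual
  }
  stamp_time <- if (dev$stamp_mode == "delivery") delivery else t_actual
  ts <- local_time(clock, stamp_time) + dev$setup_offset
  if (dev$timestamp_noise_std > 0) {
    ts <- ts + stats::rnorm(n, 0, dev$timestamp_noise_std)
  }

  vals <- if (is.null(dev$signal)) {
    matrix(0, nrow = n, ncol = dev$info$channel_count)
  } else {
    v <- dev$signal(t_actual)
    if (is.matrix(v)) v else matrix(v, nrow = n, ncol = dev$info$channel_count)
  }

  structure(list(
    info = dev$info,
    timestamps_raw = ts,
    values = vals,
    offsets = NULL,
    timestamps_sync = NULL,
    segments = NULL,
    truth = list(t_actual = t_actual, delivery = delivery,
                 epoch_offset = clock$epoch_offset, drift = clock$drift,
                 clock_noise_std = clock$noise_std,
                 setup_offset = dev$setup_offset,
                 timestamp_noise_std = dev$timestamp_noise_std,
                 stamp_mode = dev$stamp_mode)
  ), class = "recorded_stream")
}

#' Simulate a full multi-device recording session
#'
#' Runs every device against one recorder whose clock defines the reference
#' timebase (true time). Probe bursts between the recorder and each device
#' clock are executed every \code{cfg$time_update_interval} seconds through
#' the given network, yielding a per-stream clock-offset series exactly as a
#' recorder would collect it. Everything is reproducible from \code{seed}:
#' each device, each probe scheduler and the network draw from their own
#' label-derived sub-streams.
#'
#' @param devices List of [device_spec()].
#' @param clocks List of [virtual_clock()] (one per device). Clock state is
#'   reset at session start.
#' @param net A [network_spec()] for the probe exchanges.
#' @param cfg A [sync_config()].
#' @param duration Session length in seconds.
#' @param seed Root integer seed.
#' @return A \code{recording_bundle}: list with \code{streams} (each a
#'   \code{recorded_stream} with its \code{offsets} series filled),
#'   \code{duration} and \code{seed}.
#' @export
simulate_session <- function(devices, clocks, net = network_spec(),
                             cfg = sync_config(), duration = 60, seed = 1) {
  stopifnot(length(devices) >= 1, length(clocks) == length(devices))
  recorder <- virtual_clock()   # reference timebase
  streams <- vector("list", length(devices))
  for (i in seq_along(devices)) {
    ck <- clocks[[i]]
    ck$last_det <- -Inf; ck$last_out <- -Inf
    st <- with_child_seed(seed, paste0("device/", i),
                          simulate_device(devices[[i]], ck, duration))
    if (cfg$force_default_timestamps) {
      # recorder restamps at receipt: device stamps are discarded
      st$timestamps_raw <- local_time(recorder, st$truth$delivery)
    }
    # probe bursts recorder <-> device clock
    burst_times <- seq(0, duration, by = cfg$time_update_interval)
    st$offsets <- with_child_seed(seed, paste0("probe/", i), {
      at <- ofs <- rtt <- numeric(0)
      for (bt in burst_times) {
        m <- tryCatch(run_probe_burst(recorder, ck, net, cfg, t_start = bt),
                      streamsync_empty_burst = function(e) NULL)
        if (!is.null(m)) {
          at <- c(at, m$at); ofs <- c(ofs, m$ofs); rtt <- c(rtt, m$rtt)
        }
      }
      offset_series(at, ofs, rtt)
    })
    streams[[i]] <- st
  }
  names(streams) <- vapply(devices, function(d) d$info$name, character(1))
  structure(list(streams = streams, duration = duration, seed = seed),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> %d stream(s), %.6g s\n",
              length(x$streams), x$duration))
  for (nm in names(x$streams)) {
    s <- x$streams[[nm]]
    cat(sprintf("  %s [%s]: %d samples, srate %.6g, %d offset measurement(s)%s\n",
                nm, s$info$type, length(s$timestamps_raw),
                s$info$nominal_srate,
                if (is.null(s$offsets)) 0L else nrow(s$offsets),
                if (is.null(s$timestamps_sync)) "" else ", synchronized"))
  }
  invisible(x)
}

#' Periodic pulse (square-wave) test signal
#'
#' The validation signal: a square wave whose rising edges sit at exact
#' multiples of \code{period} in true time, sampled at \code{srate}.
#'
#' @param period Pulse period, seconds.
#' @param high_fraction Fraction of the period spent high, in (0, 1).
#' @param srate Sampling rate, Hz.
#' @param duration Signal length, seconds.
#' @param amplitude High level (low level is 0).
#' @return List with \code{timestamps} (true capture times) and
#'   \code{values}.
#' @export
pulse_signal <- function(period, high_fraction = 0.5, srate, duration,
                         amplitude = 1) {
  stopifnot(high_fraction > 0, high_fraction < 1, period > 0, srate > 0)
  n <- floor(duration * srate + 1e-9)
  t <- (seq_len(n) - 1) / srate
  phase <- (t / period) %% 1
  list(timestamps = t, values = amplitude * as.numeric(phase < high_fraction))
}

#' Square-wave generator as a function of true time
#'
#' Convenience for [device_spec()]'s \code{signal} argument: multiple devices
#' given the same generator sample the same physical signal, each on its own
#' grid.
#'
#' @inheritParams pulse_signal
#' @return A function mapping true times to signal values.
#' @export
square_wave <- function(period, high_fraction = 0.5, amplitude = 1) {
  force(period); force(high_fraction); force(amplitude)
  function(t) amplitude * as.numeric(((t / period) %% 1) < high_fraction)
}
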