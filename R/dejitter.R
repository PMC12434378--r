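# Post-hoc synchronization: clock-offset application, break detection,
# per-segment timestamp regression (dejittering) and diagnostics.
#
# The observed-timestamp model is
#     t_obs = t_actual + tau + OFS_bar + eps
# (capture time, device setup offset, smoothed clock offset, zero-mean
# stamping noise). Clock-offset application removes OFS_bar; per-segment
# regression of timestamp on sample index removes eps (and, for
# delivery-stamped devices, the chunking sawtooth). tau is not observable
# from the network layer and is handled by the validation module.

#' Detect breaks and split a stream into segments
#'
#' A break is declared between consecutive samples whenever their timestamp
#' difference exceeds
#' \code{max(break_threshold_seconds, break_threshold_samples / nominal_srate)}
#' — a dropout or reconnection. Irregular streams (nominal_srate = 0) are
#' never split: they form a single segment.
#'
#' @param timestamps Observed timestamps, seconds.
#' @param nominal_srate Declared sampling rate, Hz (0 = irregular).
#' @param cfg A [sync_config()] supplying the thresholds.
#' @return A data.frame with columns \code{start} and \code{end}: 1-based,
#'   half-open \code{[start, end)} sample-index ranges.
#' @export
detect_breaks <- function(timestamps, nominal_srate, cfg = sync_config()) {
  n <- length(timestamps)
  stopifnot(n >= 1)
  if (nominal_srate <= 0 || n == 1L) {
    return(data.frame(start = 1L, end = n + 1L))
  }
  thr <- max(cfg$break_threshold_seconds,
             cfg$break_threshold_samples / nominal_srate)
  cut <- which(diff(timestamps) > thr)
  data.frame(start = c(1L, cut + 1L), end = c(cut, n) + 1L)
}

#' Fit a segment's timestamp line and dejitter
#'
#' Ordinary least squares of the observed timestamps on the within-segment
#' sample index; the dejittered timestamp is the fitted value
#' \code{intercept + slope * (index - start)}. The reciprocal of the slope is
#' the segment's effective sampling rate. A length-1 segment is passed
#' through unchanged.
#'
#' @param timestamps Full timestamp vector, seconds.
#' @param start,end 1-based half-open segment bounds (as one row of
#'   [detect_breaks()]).
#' @return List with \code{segment} (a one-row data.frame: \code{start},
#'   \code{end}, \code{intercept}, \code{slope}, \code{effective_srate}) and
#'   \code{fitted} (the dejittered timestamps for this segment).
#' @export
regress_timestamps <- function(timestamps, start, end) {
  idx <- start:(end - 1L)
  y <- timestamps[idx]
  m <- length(idx)
  if (m == 1L) {
    seg <- data.frame(start = start, end = end, intercept = y, slope = NA_real_,
                      effective_srate = NA_real_)
    return(list(segment = seg, fitted = y))
  }
  x <- seq_len(m) - 1
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  seg <- data.frame(start = start, end = end, intercept = intercept,
                    slope = slope, effective_srate = 1 / slope)
  list(segment = seg, fitted = fitted)
}

#' Online recursive-least-squares timestamp dejitter
#'
#' The real-time counterpart of [regress_timestamps()]: a recursive
#' least-squares estimator of the line timestamp ~ index with exponential
#' forgetting. With \code{forgetting = 1} the estimate equals the batch OLS
#' solution on the same data (the recursion is initialized exactly from the
#' first two samples, so the equivalence is algebraic, not asymptotic);
#' forgetting < 1 down-weights the past and tracks slow rate changes.
#'
#' @param index Sample indices (need not start at 0).
#' @param timestamps Observed timestamps, seconds.
#' @param forgetting Forgetting factor in (0, 1].
#' @return List with final \code{intercept}, \code{slope}, and \code{trace}
#'   (a matrix of the running intercept/slope after each sample; NA until two
#'   distinct indices have been seen).
#' @export
rls_dejitter <- function(index, timestamps, forgetting = 1) {
  stopifnot(length(index) == length(timestamps),
            forgetting > 0, forgetting <= 1)
  n <- length(index)
  trace <- matrix(NA_real_, nrow = n, ncol = 2,
                  dimnames = list(NULL, c("intercept", "slope")))
  if (n == 0L) return(list(intercept = NA_real_, slope = NA_real_, trace = trace))
  if (n == 1L || index[2] == index[1]) {
    trace[, 1] <- timestamps[1]
    return(list(intercept = timestamps[1], slope = NA_real_, trace = trace))
  }
  # exact initialization from the first two samples
  x1 <- index[1]; x2 <- index[2]
  X <- rbind(c(1, x1), c(1, x2))
  G <- forgetting * (X[1, ] %o% X[1, ]) + (X[2, ] %o% X[2, ])
  P <- solve(G)
  theta <- P %*% (forgetting * X[1, ] * timestamps[1] + X[2, ] * timestamps[2])
  trace[1, ] <- c(timestamps[1], NA)
  trace[2, ] <- theta
  lam <- forgetting
  for (i in seq_len(n)[-(1:2)]) {
    x <- c(1, index[i])
    Px <- P %*% x
    k <- Px / (lam + sum(x * Px))
    theta <- theta + k * (timestamps[i] - sum(x * theta))
    P <- (P - k %*% crossprod(x, P)) / lam
    trace[i, ] <- theta
  }
  list(intercept = theta[1], slope = theta[2], trace = trace)
}

#' Map timestamps into the recorder timebase
#'
#' Subtracts the smoothed clock offset: with the recorder-side inlet as
#' probe initiator, the modeled offset is (outlet clock - recorder clock),
#' so \code{t_corrected = t_raw - OFS_bar(t_raw)}. Evaluation clamps beyond
#' the first/last measurement of each model piece.
#'
#' @param timestamps Raw timestamps on the outlet clock, seconds.
#' @param model An [fit_offset_model()] result.
#' @param cfg A [sync_config()]; when \code{handle_clock_sync} is FALSE the
#'   timestamps are returned unchanged.
#' @return Timestamps in the recorder timebase.
#' @export
apply_clock_offsets <- function(timestamps, model, cfg = sync_config()) {
  if (!cfg$handle_clock_sync) return(timestamps)
  stopifnot(inherits(model, "offset_model"), nrow(model) >= 1)
  timestamps - predict(model, timestamps)
}

#' Effective sampling rate of a stream
#'
#' The observed sample count divided by the recording length (last minus
#' first synchronized timestamp). A deviation from the declared nominal rate
#' beyond \code{cfg$srate_tolerance} flags a misbehaving device (a webcam
#' hopping between 30 and 60 fps, a lossy Bluetooth link) for which
#' timestamp smoothing would distort, not improve, the data.
#'
#' @param stream A \code{recorded_stream}.
#' @param cfg A [sync_config()].
#' @return A list: \code{effective_srate} (Hz), \code{nominal_srate},
#'   \code{flag} (TRUE when the deviation exceeds tolerance; always FALSE
#'   for irregular streams).
#' @export
effective_srate <- function(stream, cfg = sync_config()) {
  ts <- if (!is.null(stream$timestamps_sync)) stream$timestamps_sync else stream$timestamps_raw
  n <- length(ts)
  if (n < 2L) stop("effective sampling rate is undefined for fewer than 2 samples")
  eff <- n / (ts[n] - ts[1])
  nom <- stream$info$nominal_srate
  flag <- nom > 0 && abs(eff - nom) / nom > cfg$srate_tolerance
  list(effective_srate = eff, nominal_srate = nom, flag = flag)
}

#' Synchronize a recorded bundle
#'
#' The post-hoc import pipeline, per stream: (1) fit the piecewise-linear
#' clock-offset model from the stream's offset series and subtract it
#' (skipped when \code{handle_clock_sync} is FALSE or no measurements
#' exist); (2) detect breaks; (3) if \code{handle_jitter} is TRUE and the
#' stream is regularly sampled, replace each segment's timestamps by its
#' fitted line. Irregular streams are never regressed. The computation
#' always starts from the raw timestamps, so applying it twice equals
#' applying it once.
#'
#' @param bundle A \code{recording_bundle} (from [simulate_session()],
#'   [read_xdf()] or [record()]).
#' @param cfg A [sync_config()].
#' @return The bundle with each stream's \code{timestamps_sync},
#'   \code{segments}, \code{offset_model} and \code{diagnostics} filled.
#' @export
synchronize_recording <- function(bundle, cfg = sync_config()) {
  stopifnot(inherits(bundle, "recording_bundle"))
  bundle$streams <- lapply(bundle$streams, function(st) {
    ts <- st$timestamps_raw
    st$offset_model <- NULL
    if (cfg$handle_clock_sync && !is.null(st$offsets) && nrow(st$offsets) >= 1) {
      st$offset_model <- fit_offset_model(st$offsets, cfg$offset_jump_threshold)
      ts <- apply_clock_offsets(ts, st$offset_model, cfg)
    }
    if (length(ts) == 0L) {
      st$timestamps_sync <- ts
      st$segments <- data.frame(start = integer(), end = integer(),
                                intercept = numeric(), slope = numeric(),
                                effective_srate = numeric())
      return(st)
    }
    segs <- detect_breaks(ts, st$info$nominal_srate, cfg)
    if (cfg$handle_jitter && st$info$nominal_srate > 0) {
      fits <- lapply(seq_len(nrow(segs)), function(i) {
        regress_timestamps(ts, segs$start[i], segs$end[i])
      })
      for (i in seq_along(fits)) {
        idx <- segs$start[i]:(segs$end[i] - 1L)
        ts[idx] <- fits[[i]]$fitted
      }
      st$segments <- do.call(rbind, lapply(fits, `[[`, "segment"))
    } else {
      st$segments <- data.frame(start = segs$start, end = segs$end,
                                intercept = NA_real_, slope = NA_real_,
                                effective_srate = NA_real_)
    }
    st$timestamps_sync <- ts
    st$diagnostics <- if (length(ts) >= 2) effective_srate(st_with_sync(st, ts), cfg) else NULL
    st
  })
  bundle$sync_cfg <- cfg
  bundle
}

# small helper so effective_srate sees the freshly computed stamps
st_with_sync <- function(st, ts) { st$timestamps_sync <- ts; st }

#' Per-stream synchronization diagnostics
#'
#' @param bundle A synchronized \code{recording_bundle}.
#' @return A data.frame: one row per stream with sample count, segment
#'   count, effective and nominal sampling rate and the deviation flag.
#' @export
sync_diagnostics <- function(bundle) {
  rows <- lapply(names(bundle$streams), function(nm) {
    st <- bundle$streams[[nm]]
    d <- st$diagnostics
    data.frame(stream = nm,
               n_samples = length(st$timestamps_raw),
               n_segments = if (is.null(st$segments)) NA_integer_ else nrow(st$segments),
               effective_srate = if (is.null(d)) NA_real_ else d$effective_srate,
               nominal_srate = st$info$nominal_srate,
               srate_flag = if (is.null(d)) NA else d$flag)
  })
  do.call(rbind, rows)
}
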