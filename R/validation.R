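# Validation methodology: threshold-crossing marker extraction from a pulse
# signal, pairwise offset/jitter statistics between marker series, and the
# setup-offset (device latency) determination recipe.

#' Extract half-maximum threshold-crossing markers
#'
#' One marker per upward crossing of the half-maximum threshold
#' \code{(max + min) / 2}, with the crossing time linearly interpolated
#' between the bracketing samples. A refractory rule permits no second
#' marker until the signal has fallen below threshold again, so a noisy
#' plateau yields a single marker per pulse. Marker times are
#' amplitude-scale invariant.
#'
#' @param timestamps Sample timestamps, seconds.
#' @param signal Sample values (one channel).
#' @return Strictly increasing marker times (a \code{marker_series} numeric
#'   vector); empty for a signal with no rising excursion.
#' @examples
#' extract_threshold_markers(c(0.010, 0.011), c(0, 1))  # 0.0105
#' @export
extract_threshold_markers <- function(timestamps, signal) {
  stopifnot(length(timestamps) == length(signal))
  n <- length(signal)
  if (n < 2L) return(structure(numeric(0), class = "marker_series"))
  thr <- (max(signal) + min(signal)) / 2
  lo <- signal < thr
  hi <- signal >= thr
  if (all(lo) || all(hi) || max(signal) == min(signal)) {
    return(structure(numeric(0), class = "marker_series"))
  }
  i <- which(lo[-n] & hi[-1L])   # refractory is implicit: must dip below first
  t0 <- timestamps[i]; t1 <- timestamps[i + 1L]
  v0 <- signal[i]; v1 <- signal[i + 1L]
  tm <- t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
  structure(sort(tm), class = "marker_series")
}

#' Pairwise offset and jitter statistics between two marker series
#'
#' Pairs each marker in \code{a} with its nearest neighbor in \code{b}
#' within \code{max_pair_distance} (default: half the median inter-marker
#' period of \code{a}, preventing cross-period mispairing when the offset is
#' large). Reports the mean of the paired differences \code{b - a} (the
#' constant offset between the two series), their standard deviation (the
#' jitter), and the differences centered to their mean.
#'
#' @param a,b Marker time vectors (seconds, recorder timebase).
#' @param max_pair_distance Seconds; pairs farther apart are discarded.
#' @return An \code{offset_report}: list with \code{mean_offset},
#'   \code{jitter_std}, \code{n_pairs}, \code{n_unpaired},
#'   \code{centered_diffs}.
#' @export
pairwise_offset_stats <- function(a, b, max_pair_distance = NULL) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (is.null(max_pair_distance)) {
    max_pair_distance <- if (length(a) >= 2) stats::median(diff(a)) / 2 else Inf
  }
  idx <- findInterval(a, b)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(b))
  d_lo <- abs(b[lo] - a); d_hi <- abs(b[hi] - a)
  nearest <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  paired <- dist <= max_pair_distance
  if (!any(paired)) stop("no marker pairs within max_pair_distance")
  diffs <- b[nearest[paired]] - a[paired]
  mean_offset <- mean(diffs)
  structure(list(mean_offset = mean_offset,
                 jitter_std = stats::sd(diffs),
                 n_pairs = sum(paired),
                 n_unpaired = sum(!paired),
                 centered_diffs = diffs - mean_offset),
            class = "offset_report")
}

#' @export
print.offset_report <- function(x, ...) {
  cat(sprintf("<offset_report> mean offset %.6g ms, jitter sd %.6g ms, %d pair(s), %d unpaired\n",
              x$mean_offset * 1e3,
              if (is.na(x$jitter_std)) NA else x$jitter_std * 1e3,
              x$n_pairs, x$n_unpaired))
  invisible(x)
}

#' Measure a device's setup offset from a synchronized recording
#'
#' The in-silico version of the pulse-comparison recipe: a shared pulse is
#' fed both to the instrument under test and, as software markers, to the
#' recorder. After synchronization, instrument markers are extracted by
#' half-maximum threshold crossing and paired against the reference marker
#' stream; the mean paired difference is the setup offset tau. The sign is
#' fixed so that a positive offset means the instrument marker occurs after
#' the reference (DataIn) marker; output transducers can come out negative.
#'
#' @param bundle A synchronized \code{recording_bundle}
#'   ([synchronize_recording()] already applied).
#' @param instrument_stream Name of the instrument's signal stream.
#' @param datain_marker_stream Name of the reference marker stream.
#' @param channel Signal channel used for threshold extraction.
#' @param max_pair_distance Passed to [pairwise_offset_stats()].
#' @return An \code{offset_report}; \code{mean_offset} is the setup offset
#'   in seconds.
#' @export
measure_setup_offset <- function(bundle, instrument_stream,
                                 datain_marker_stream, channel = 1,
                                 max_pair_distance = NULL) {
  inst <- bundle$streams[[instrument_stream]]
  ref <- bundle$streams[[datain_marker_stream]]
  if (is.null(inst) || is.null(ref)) stop("stream not found in bundle")
  if (is.null(inst$timestamps_sync) || is.null(ref$timestamps_sync)) {
    stop("bundle is not synchronized; run synchronize_recording() first")
  }
  inst_markers <- extract_threshold_markers(inst$timestamps_sync,
                                            as.numeric(inst$values[, channel]))
  ref_markers <- ref$timestamps_sync
  pairwise_offset_stats(ref_markers, inst_markers, max_pair_distance)
}
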