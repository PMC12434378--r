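# NTP-style clock synchronization: per-exchange RTT/OFS, min-RTT clock
# filtering over probe bursts, and the piecewise-linear smoothed offset model.

#' Round-trip time and clock offset of one probe exchange
#'
#' A probe exchange carries four timestamps: \code{t0} (send, initiator
#' clock), \code{t1} (receive, responder clock), \code{t2} (resend, responder
#' clock) and \code{t3} (final receipt, initiator clock). The round-trip time
#' is the duration of the whole round trip minus the dwell on the responder,
#' \deqn{RTT = (t3 - t0) - (t2 - t1),}
#' and the clock offset is the average of the two one-way offset estimates,
#' \deqn{OFS = ((t1 - t0) + (t2 - t3)) / 2,}
#' in which a symmetric transmission delay cancels exactly. With the inlet
#' (recorder) as initiator, OFS equals (outlet clock - inlet clock); mapping
#' outlet timestamps into the inlet timebase therefore subtracts the offset.
#'
#' @param t0,t1,t2,t3 Exchange timestamps in seconds (vectors are accepted
#'   and processed elementwise).
#' @return A data.frame with columns \code{rtt} and \code{ofs} (seconds).
#' @examples
#' compute_rtt_ofs(0, 2.503, 2.504, 0.007)  # rtt 6 ms, responder 2.5 s ahead
#' @export
compute_rtt_ofs <- function(t0, t1, t2, t3) {
  stopifnot(length(t0) == length(t1), length(t1) == length(t2),
            length(t2) == length(t3))
  rtt <- (t3 - t0) - (t2 - t1)
  if (any(rtt < 0)) {
    stop("malformed probe exchange: negative round-trip time", call. = FALSE)
  }
  ofs <- ((t1 - t0) + (t2 - t3)) / 2
  data.frame(rtt = rtt, ofs = ofs)
}

#' Construct a clock-offset measurement table
#'
#' @param at Seconds on the initiator clock at which each measurement was
#'   retained (the exchange's \code{t3}).
#' @param ofs Clock offsets in seconds.
#' @param rtt Round-trip times in seconds (non-negative).
#' @return A data.frame of class \code{offset_series}, sorted by \code{at}.
#' @export
offset_series <- function(at = numeric(), ofs = numeric(), rtt = rep(NA_real_, length(at))) {
  stopifnot(length(at) == length(ofs), length(ofs) == length(rtt))
  if (any(!is.na(rtt) & rtt < 0)) stop("rtt must be non-negative")
  o <- order(at)
  structure(data.frame(at = at[o], ofs = ofs[o], rtt = rtt[o]),
            class = c("offset_series", "data.frame"))
}

#' Minimum-RTT clock filter
#'
#' From a burst of offset measurements, discards those whose round-trip time
#' exceeds \code{max_rtt} and retains the one with the lowest remaining RTT
#' — the minimum-noise realization of the clock offset, since delay spikes
#' inflate RTT. Ties on RTT are broken by the earliest measurement, so
#' replay is deterministic.
#'
#' @param burst A data.frame with columns \code{at}, \code{ofs}, \code{rtt}
#'   (e.g. an [offset_series()]).
#' @param max_rtt Seconds; measurements above this are dropped first.
#' @return The retained single-row measurement.
#' @section Errors: signals a condition of class \code{streamsync_empty_burst}
#'   when no measurement survives the RTT filter; the caller is expected to
#'   keep its previous estimate.
#' @export
clock_filter <- function(burst, max_rtt = 0.100) {
  stopifnot(is.data.frame(burst), nrow(burst) >= 1)
  keep <- burst[burst$rtt <= max_rtt, , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop(structure(class = c("streamsync_empty_burst", "error", "condition"),
                   list(message = "no probe exchange passed the RTT filter",
                        call = sys.call())))
  }
  keep[order(keep$rtt, keep$at)[1L], , drop = FALSE]
}

#' Run one probe burst between two simulated clocks
#'
#' Performs \code{cfg$time_probe_count} probe exchanges spaced
#' \code{cfg$time_probe_interval} apart through a simulated network, computes
#' RTT/OFS for each and returns the minimum-RTT measurement (see
#' [clock_filter()]). The initiator is conventionally the recorder-side
#' (inlet) clock, so the retained offset estimates (responder clock -
#' initiator clock).
#'
#' @param initiator_clock,responder_clock [virtual_clock()] objects.
#' @param net A [network_spec()] describing per-direction delays.
#' @param cfg A [sync_config()].
#' @param t_start True time at which the burst starts, in seconds.
#' @return A one-row data.frame (\code{at}, \code{ofs}, \code{rtt}) with
#'   attribute \code{truth_time}: the true (simulation) time at the midpoint
#'   of the retained exchange, for ground-truth comparison.
#' @export
run_probe_burst <- function(initiator_clock, responder_clock, net, cfg = sync_config(),
                            t_start = 0) {
  n <- cfg$time_probe_count
  t_send <- t_start + (seq_len(n) - 1) * cfg$time_probe_interval
  fwd <- sample_delay(net, "forward", n)
  bwd <- sample_delay(net, "backward", n)
  t0 <- local_time(initiator_clock, t_send)
  t_arrive <- t_send + fwd
  t1 <- local_time(responder_clock, t_arrive)
  t2 <- t1  # zero responder dwell
  t_back <- t_arrive + bwd
  t3 <- local_time(initiator_clock, t_back)
  ex <- compute_rtt_ofs(t0, t1, t2, t3)
  burst <- data.frame(at = t3, ofs = ex$ofs, rtt = ex$rtt,
                      truth_time = (t_send + t_back) / 2)
  m <- clock_filter(burst, cfg$time_probe_max_rtt)
  structure(m[, c("at", "ofs", "rtt")], truth_time = m$truth_time)
}

#' Fit the piecewise-linear smoothed clock-offset model
#'
#' Splits an offset-measurement series wherever the step between consecutive
#' offsets exceeds \code{jump_threshold} — a discontinuity produced by a
#' reconnect, possibly to a different host whose clock differs by far more
#' than drift ever could — and fits one ordinary-least-squares line per
#' piece. Robustness to delay spikes is delegated to the upstream minimum-RTT
#' filter, so plain least squares suffices here. A single-measurement piece
#' becomes a constant.
#'
#' @param series An [offset_series()] (or data.frame with \code{at},
#'   \code{ofs}), at least one row, \code{at} strictly increasing.
#' @param jump_threshold Seconds; offset step that starts a new piece.
#' @return An object of class \code{offset_model}: a data.frame of pieces
#'   with columns \code{start}, \code{end} (half-open evaluation interval),
#'   \code{t_first}, \code{t_last} (measurement span), \code{intercept} and
#'   \code{slope}, where the modeled offset on a piece is
#'   \code{intercept + slope * (t - start)}.
#' @seealso [predict.offset_model()], [apply_clock_offsets()]
#' @export
fit_offset_model <- function(series, jump_threshold = 1) {
  stopifnot(is.data.frame(series), nrow(series) >= 1)
  at <- series$at; ofs <- series$ofs
  if (is.unsorted(at, strictly = FALSE)) {
    o <- order(at); at <- at[o]; ofs <- ofs[o]
  }
  cut <- which(abs(diff(ofs)) > jump_threshold)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, length(at))
  pieces <- do.call(rbind, lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    a <- at[idx[1L]]
    if (length(idx) == 1L) {
      data.frame(t_first = a, t_last = a, intercept = ofs[idx], slope = 0)
    } else {
      x <- at[idx] - a
      y <- ofs[idx]
      sl <- stats::cov(x, y) / stats::var(x)
      ic <- mean(y) - sl * mean(x)
      data.frame(t_first = a, t_last = at[idx[length(idx)]],
                 intercept = ic, slope = sl)
    }
  }))
  # evaluation intervals: piece i owns [start_i, start_{i+1}); ends at Inf
  pieces$start <- pieces$t_first
  pieces$end <- c(pieces$t_first[-1L], Inf)
  pieces$start[1L] <- -Inf
  structure(pieces[, c("start", "end", "t_first", "t_last", "intercept", "slope")],
            class = c("offset_model", "data.frame"))
}

#' Evaluate the smoothed clock offset at given times
#'
#' Evaluation clamps \code{t} to the measurement span of the owning piece, so
#' the model never extrapolates beyond the first or last measurement of a
#' piece: before the first measurement the first fitted value holds, after
#' the last the last fitted value holds.
#'
#' @param object An [fit_offset_model()] result.
#' @param t Times (seconds) at which to evaluate.
#' @param ... Unused.
#' @return Numeric vector of offsets, same length as \code{t}.
#' @export
predict.offset_model <- function(object, t, ...) {
  idx <- findInterval(t, object$start, left.open = FALSE)
  idx[idx < 1L] <- 1L
  tc <- pmin(pmax(t, object$t_first[idx]), object$t_last[idx])
  object$intercept[idx] + object$slope[idx] * (tc - object$t_first[idx])
}

#' @export
print.offset_model <- function(x, ...) {
  cat(sprintf("<offset_model> %d piece(s)\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  piece %d: t in [%.6g, %.6g], offset = %.9g %+.3g*(t - t0), drift %.3g ppm\n",
                i, x$t_first[i], x$t_last[i], x$intercept[i], x$slope[i],
                x$slope[i] * 1e6))
  }
  invisible(x)
}
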