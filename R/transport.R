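# In-process publish/subscribe transport: outlets, inlets, discovery by
# metadata query, bounded buffering with drop accounting, and silent
# reconnection. Semantics only — no wire sockets; determinism is the point.

#' Create a stream registry
#'
#' The process-local stream directory that [resolve_streams()] queries and
#' outlets register with.
#'
#' @return A \code{stream_registry} environment.
#' @export
stream_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$outlets <- list()
  e$next_uid <- 1L
  e$query_cache <- list()
  class(e) <- "stream_registry"
  e
}

#' Open an outlet (publisher endpoint)
#'
#' @param info A [stream_info()].
#' @param registry A [stream_registry()].
#' @param capacity_samples Buffer capacity in samples; defaults to
#'   \code{cfg$buffer_capacity_seconds} of data at the nominal rate (at
#'   least 1000 samples for irregular streams). On overflow the oldest
#'   samples are dropped first and the drops are counted.
#' @param clock Optional [virtual_clock()] used to stamp samples pushed
#'   without a timestamp, and as the responder clock of probe bursts run by
#'   [record()].
#' @param cfg A [sync_config()].
#' @return An \code{outlet} environment.
#' @export
create_outlet <- function(info, registry, capacity_samples = NULL,
                          clock = NULL, cfg = sync_config()) {
  if (is.null(capacity_samples)) {
    capacity_samples <- max(1000, ceiling(cfg$buffer_capacity_seconds *
                                            max(info$nominal_srate, 1)))
  }
  e <- new.env(parent = emptyenv())
  e$info <- info
  e$state <- "active"
  e$clock <- if (is.null(clock)) virtual_clock() else clock
  e$capacity <- capacity_samples
  e$ts <- numeric(0)
  e$vals <- list()
  e$n_pushed <- 0L        # total ever pushed
  e$n_dropped <- 0L       # overflow drops
  e$base <- 0L            # samples evicted from the front (dropped)
  e$uid <- registry$next_uid
  registry$next_uid <- registry$next_uid + 1L
  registry$outlets[[as.character(e$uid)]] <- e
  registry$query_cache <- list()
  class(e) <- "outlet"
  e
}

#' Close an outlet
#'
#' Marks the outlet closed and removes it from the registry. Connected
#' inlets switch to the recovering state and deliver no further samples
#' until an outlet with the same \code{source_id} (or matching their query)
#' reappears — they never error out.
#'
#' @param outlet An outlet.
#' @param registry The registry it was created in.
#' @export
close_outlet <- function(outlet, registry) {
  outlet$state <- "closed"
  registry$outlets[[as.character(outlet$uid)]] <- NULL
  registry$query_cache <- list()
  invisible(NULL)
}

.match_query <- function(info, query) {
  if (is.null(query) || length(query) == 0L) return(TRUE)
  for (field in names(query)) {
    v <- info[[field]]
    if (is.null(v) || as.character(v) != as.character(query[[field]])) return(FALSE)
  }
  TRUE
}

#' Resolve streams by metadata query
#'
#' Returns the stream descriptions of all active outlets whose metadata
#' satisfies every predicate of the query — a conjunction of field
#' equalities such as \code{list(type = "EEG")}. An empty query matches all
#' streams. Responses to identical queries are served from a per-registry
#' cache until the outlet set changes. An unmatched query simply yields an
#' empty list (resolution timing out is not an error).
#'
#' @param registry A [stream_registry()].
#' @param query Named list of field = value equalities over [stream_info()]
#'   fields; NULL or empty matches everything.
#' @param timeout Unused placeholder for interface parity; resolution is
#'   immediate in-process.
#' @return List of \code{stream_info}.
#' @export
resolve_streams <- function(registry, query = NULL, timeout = 0) {
  key <- paste(names(query), vapply(query, as.character, character(1)),
               sep = "=", collapse = "&")
  if (!is.null(registry$query_cache[[key]])) return(registry$query_cache[[key]])
  hits <- Filter(function(o) o$state == "active" && .match_query(o$info, query),
                 registry$outlets)
  res <- lapply(unname(hits), function(o) o$info)
  registry$query_cache[[key]] <- res
  res
}

#' Push a sample into an outlet
#'
#' A sample pushed without a timestamp is stamped with the outlet's local
#' clock at push time. \code{flush} marks the sample for immediate delivery;
#' without it delivery may batch (in this in-process transport both behave
#' identically, but the flag is honored for interface parity).
#'
#' @param outlet An outlet.
#' @param values Numeric (or character, for string streams) vector of length
#'   \code{channel_count}.
#' @param timestamp Optional capture timestamp, seconds on the outlet clock.
#' @param flush Request immediate transmission.
#' @param push_time True time of the push (drives the local clock stamp when
#'   \code{timestamp} is missing).
#' @return The stamped timestamp, invisibly.
#' @export
push_sample <- function(outlet, values, timestamp = NULL, flush = FALSE,
                        push_time = NULL) {
  if (outlet$state != "active") stop("outlet is closed")
  if (length(values) != outlet$info$channel_count) {
    stop(sprintf("sample has %d values; stream declares %d channels",
                 length(values), outlet$info$channel_count))
  }
  if (is.null(timestamp)) {
    tt <- if (is.null(push_time)) max(outlet$clock$last_det, 0) else push_time
    timestamp <- local_time(outlet$clock, tt)
  }
  outlet$ts <- c(outlet$ts, timestamp)
  outlet$vals[[length(outlet$vals) + 1L]] <- values
  outlet$n_pushed <- outlet$n_pushed + 1L
  if (length(outlet$ts) > outlet$capacity) {
    k <- length(outlet$ts) - outlet$capacity
    outlet$ts <- outlet$ts[-seq_len(k)]
    outlet$vals <- outlet$vals[-seq_len(k)]
    outlet$n_dropped <- outlet$n_dropped + k
    outlet$base <- outlet$base + k
  }
  invisible(timestamp)
}

#' Open an inlet (subscriber endpoint)
#'
#' Binds to an outlet by query and/or \code{source_id}. When both are given,
#' \code{source_id} takes precedence for (re)binding. The inlet keeps its
#' own read cursor into the outlet buffer, so a temporarily unreachable but
#' alive outlet retains samples for later delivery.
#'
#' @param registry A [stream_registry()].
#' @param query Conjunctive equality query (see [resolve_streams()]).
#' @param source_id Stable source identifier for rebinding.
#' @return An \code{inlet} environment, in state \code{"connected"} if a
#'   matching outlet exists, else \code{"recovering"}.
#' @export
create_inlet <- function(registry, query = NULL, source_id = NULL) {
  e <- new.env(parent = emptyenv())
  e$registry <- registry
  e$query <- query
  e$source_id <- source_id
  e$outlet <- NULL
  e$cursor <- 0L          # count of samples consumed (in outlet$base units)
  e$state <- "recovering"
  e$n_pulled <- 0L
  class(e) <- "inlet"
  .inlet_bind(e)
  e
}

.inlet_find <- function(inlet) {
  reg <- inlet$registry
  for (o in reg$outlets) {
    if (o$state != "active") next
    if (!is.null(inlet$source_id)) {
      if (identical(o$info$source_id, inlet$source_id)) return(o)
    } else if (.match_query(o$info, inlet$query)) {
      return(o)
    }
  }
  NULL
}

.inlet_bind <- function(inlet) {
  o <- .inlet_find(inlet)
  if (is.null(o)) {
    inlet$state <- "recovering"
    return(invisible(FALSE))
  }
  if (!identical(inlet$outlet, o)) {
    inlet$outlet <- o
    inlet$cursor <- 0L   # new outlet: start at its buffer head
  }
  inlet$state <- "connected"
  invisible(TRUE)
}

#' Pull buffered samples from an inlet
#'
#' Delivers up to \code{max_samples} samples in push (FIFO) order. A
#' recovering inlet first attempts to rebind; while no outlet is available
#' it returns an empty result — never an error. Samples evicted by buffer
#' overflow are skipped (they were counted as drops at the outlet).
#'
#' @param inlet An inlet.
#' @param max_samples Maximum number of samples to deliver (Inf = all
#'   available).
#' @return A list with \code{timestamps} and \code{values} (list of
#'   per-sample value vectors); both empty when nothing is available.
#' @export
pull_samples <- function(inlet, max_samples = Inf) {
  if (inlet$state != "connected" || is.null(inlet$outlet) ||
      inlet$outlet$state != "active" ||
      is.null(inlet$registry$outlets[[as.character(inlet$outlet$uid)]])) {
    .inlet_bind(inlet)  # the link coming back is automatic and silent
  }
  if (inlet$state != "connected") {
    return(list(timestamps = numeric(0), values = list()))
  }
  o <- inlet$outlet
  if (inlet$cursor < o$base) inlet$cursor <- o$base  # overflow skipped
  first <- inlet$cursor - o$base + 1L
  nbuf <- length(o$ts)
  if (first > nbuf) return(list(timestamps = numeric(0), values = list()))
  k <- min(nbuf - first + 1L, max_samples)
  idx <- first:(first + k - 1L)
  inlet$cursor <- inlet$cursor + k
  inlet$n_pulled <- inlet$n_pulled + k
  list(timestamps = o$ts[idx], values = o$vals[idx])
}

#' Simulate an outlet outage and recovery
#'
#' Two failure modes, matching real deployments: if \code{recreate} is
#' FALSE, the outlet stays alive but unreachable (e.g. a dropped wireless
#' link) — samples pushed meanwhile stay in its buffer and are all delivered
#' after recovery, capacity permitting. If \code{recreate} is TRUE, the
#' outlet is destroyed and a new one with the same \code{source_id} is
#' created (possibly "on another host"): the inlet rebinds automatically and
#' the lost interval appears only as a timestamp gap.
#'
#' @param inlet The subscribed inlet.
#' @param registry The registry.
#' @param outlet The outlet to disturb.
#' @param recreate Destroy-and-recreate instead of temporary unreachability.
#' @return A character vector event log.
#' @export
drop_and_recover <- function(inlet, registry, outlet, recreate = FALSE) {
  log <- character()
  if (recreate) {
    close_outlet(outlet, registry)
    inlet$state <- "recovering"
    log <- c(log, "outlet destroyed")
  } else {
    inlet$state <- "recovering"
    log <- c(log, "link down (outlet alive)")
  }
  log
}

#' Record from a set of inlets into a bundle
#'
#' The recorder: pulls every inlet dry, runs probe bursts against each
#' outlet's clock on the configured schedule, and assembles a
#' \code{recording_bundle} ready for [write_xdf()] or
#' [synchronize_recording()]. With \code{cfg$force_default_timestamps} the
#' device-supplied stamps are discarded and samples are restamped with the
#' recorder clock at receipt.
#'
#' @param inlets List of inlets (each bound to an outlet carrying a clock).
#' @param duration Recording span in seconds (drives the probe schedule).
#' @param cfg A [sync_config()].
#' @param net A [network_spec()] for the probe exchanges.
#' @param seed Integer seed for the probe-burst randomness.
#' @return A \code{recording_bundle}.
#' @export
record <- function(inlets, duration, cfg = sync_config(),
                   net = network_spec(), seed = 1) {
  stopifnot(length(inlets) >= 1)
  recorder <- virtual_clock()
  streams <- vector("list", length(inlets))
  for (i in seq_along(inlets)) {
    inl <- inlets[[i]]
    got <- pull_samples(inl, Inf)
    o <- inl$outlet
    info <- if (!is.null(o)) o$info else stream_info(name = paste0("stream", i))
    ts <- got$timestamps
    vals <- if (length(got$values) > 0) do.call(rbind, got$values) else
      matrix(numeric(), 0, info$channel_count)
    if (cfg$force_default_timestamps && length(ts) > 0) {
      # receipt order is push order; restamp on the recorder clock at pull
      ts <- local_time(recorder, pmax(cummax(ts - ts[1]), 0))
    }
    ser <- with_child_seed(seed, paste0("record/probe/", i), {
      at <- ofs <- rtt <- numeric(0)
      if (!is.null(o)) {
        for (bt in seq(0, duration, by = cfg$time_update_interval)) {
          m <- tryCatch(run_probe_burst(recorder, o$clock, net, cfg, t_start = bt),
                        streamsync_empty_burst = function(e) NULL)
          if (!is.null(m)) {
            at <- c(at, m$at); ofs <- c(ofs, m$ofs); rtt <- c(rtt, m$rtt)
          }
        }
      }
      offset_series(at, ofs, rtt)
    })
    streams[[i]] <- structure(list(info = info, timestamps_raw = ts,
                                   values = vals, offsets = ser,
                                   timestamps_sync = NULL, segments = NULL,
                                   truth = NULL),
                              class = "recorded_stream")
  }
  names(streams) <- vapply(streams, function(s) s$info$name, character(1))
  structure(list(streams = streams, duration = duration, seed = seed),
            class = "recording_bundle")
}
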