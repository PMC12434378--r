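# Scenario files: a plaintext (YAML) description of devices, clocks and
# network from which a full session can be simulated — the batch interface
# to the simulator.

#' Simulate a session from a scenario file
#'
#' Reads a YAML scenario whose keys mirror the [device_spec()],
#' [virtual_clock()] and [network_spec()] fields and runs
#' [simulate_session()]. Layout:
#' \preformatted{
#' duration: 60
#' network: {base_delay: 2.0e-4, jitter_scale: 5.0e-4,
#'           spike_prob: 0.1, spike_magnitude: 0.05}
#' devices:
#'   - name: eeg
#'     type: EEG
#'     srate: 500
#'     channel_count: 1
#'     channel_format: float32
#'     source_id: eeg-1
#'     stamp_mode: capture        # or delivery
#'     chunk_period: 0
#'     setup_offset: 0
#'     timestamp_noise_std: 2.0e-4
#'     clock: {epoch_offset: 0.5, drift: 1.0e-5, noise_std: 0}
#'     pulse: {period: 0.5, high_fraction: 0.5, amplitude: 1}
#' }
#' \code{pulse} is optional (zeros otherwise); tuning keys may be supplied
#' under \code{tuning:} with the [sync_config()] field names.
#'
#' @param path Scenario file path.
#' @param seed Root seed.
#' @return A \code{recording_bundle}.
#' @export
simulate_from_scenario <- function(path, seed = 1) {
  sc <- yaml::read_yaml(path)
  stopifnot(!is.null(sc$devices), length(sc$devices) >= 1)
  net <- do.call(network_spec, sc$network %||% list())
  cfg <- do.call(sync_config, sc$tuning %||% list())
  devices <- list(); clocks <- list()
  for (d in sc$devices) {
    info <- stream_info(name = d$name %||% "stream",
                        type = d$type %||% "",
                        channel_count = d$channel_count %||% 1,
                        nominal_srate = d$srate %||% 0,
                        channel_format = d$channel_format %||% "float32",
                        source_id = d$source_id %||% (d$name %||% "stream"))
    sig <- if (!is.null(d$pulse)) {
      square_wave(d$pulse$period, d$pulse$high_fraction %||% 0.5,
                  d$pulse$amplitude %||% 1)
    } else NULL
    devices[[length(devices) + 1L]] <-
      device_spec(info, srate = info$nominal_srate,
                  chunk_period = d$chunk_period %||% 0,
                  setup_offset = d$setup_offset %||% 0,
                  timestamp_noise_std = d$timestamp_noise_std %||% 0,
                  stamp_mode = d$stamp_mode %||% "capture",
                  dropout_windows = lapply(d$dropout_windows %||% list(), unlist),
                  signal = sig,
                  event_times = unlist(d$event_times %||% numeric()))
    ck <- d$clock %||% list()
    clocks[[length(clocks) + 1L]] <-
      virtual_clock(ck$epoch_offset %||% 0, ck$drift %||% 0,
                    ck$noise_std %||% 0)
  }
  simulate_session(devices, clocks, net, cfg,
                   duration = sc$duration %||% 60, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ground-truth sidecar for a simulated bundle
#'
#' An XML file (same metadata dialect as the stream headers) recording each
#' stream's hidden simulation truth: clock offset and drift, setup offset,
#' stamping mode and noise. Useful next to an XDF file written from the same
#' bundle, so recovered quantities can be compared to what was injected.
#'
#' @param bundle A \code{recording_bundle} with \code{truth} entries.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_sidecar <- function(bundle, path) {
  root <- xml2::xml_new_root("truth")
  for (nm in names(bundle$streams)) {
    st <- bundle$streams[[nm]]
    if (is.null(st$truth)) next
    nd <- xml2::xml_add_child(root, "stream")
    xml2::xml_add_child(nd, "name", nm)
    for (f in c("epoch_offset", "drift", "clock_noise_std", "setup_offset",
                "timestamp_noise_std", "stamp_mode")) {
      xml2::xml_add_child(nd, f, as.character(st$truth[[f]]))
    }
    xml2::xml_add_child(nd, "n_samples", as.character(length(st$timestamps_raw)))
  }
  xml2::write_xml(root, path)
  invisible(path)
}
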