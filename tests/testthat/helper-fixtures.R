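# Shared fixtures: tiny streams and bundles built in code.

make_stream <- function(name = "s", ts, vals = NULL, srate = 100,
                        fmt = "float32", type = "EEG", ch = 1,
                        offsets = offset_series(), source_id = paste0("src-", name)) {
  if (is.null(vals)) vals <- matrix(seq_along(ts), ncol = ch)
  structure(list(info = stream_info(name, type, ch, srate, fmt, source_id),
                 timestamps_raw = ts, values = vals, offsets = offsets,
                 timestamps_sync = NULL, segments = NULL, truth = NULL),
            class = "recorded_stream")
}

make_bundle <- function(...) {
  streams <- list(...)
  names(streams) <- vapply(streams, function(s) s$info$name, character(1))
  structure(list(streams = streams, duration = NA_real_, seed = NA_integer_),
            class = "recording_bundle")
}

# closed-form OLS of y on x, the independent oracle for regression paths
ols_line <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - sl * mean(x), slope = sl)
}
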