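test_that("break detection splits on gaps and leaves irregular streams whole", {
  cfg <- sync_config(break_threshold_seconds = 1, break_threshold_samples = 500)
  # 1000 clean samples at 100 Hz: one segment
  ts <- (0:999) / 100
  expect_equal(detect_breaks(ts, 100, cfg), data.frame(start = 1L, end = 1001L))
  # 2 s gap after the 501st sample at 1000 Hz (500 samples = 0.5 s, so the
  # 1 s threshold governs) -> split there
  tk <- (0:999) / 1000
  ts2 <- c(tk[1:501], tk[502:1000] + 2)
  segs <- detect_breaks(ts2, 1000, cfg)
  expect_equal(segs$start, c(1L, 502L))
  expect_equal(segs$end, c(502L, 1001L))
  # at 100 Hz the sample threshold dominates: 500 samples = 5 s, so the
  # same 2 s gap does not split
  ts3 <- c(ts[1:501], ts[502:1000] + 2)
  expect_equal(nrow(detect_breaks(ts3, 100, cfg)), 1L)
  # irregular (marker) stream: always a single segment
  expect_equal(detect_breaks(c(0, 5, 50), 0, cfg),
               data.frame(start = 1L, end = 4L))
})

test_that("segment regression reproduces exact lines and denoises jittered ones", {
  # already-linear input is returned identically
  ts <- 10 + (0:499) / 256
  r <- regress_timestamps(ts, 1L, 501L)
  expect_equal(r$fitted, ts, tolerance = 1e-12)
  expect_equal(r$segment$slope, 1 / 256, tolerance = 1e-12)
  expect_equal(r$segment$effective_srate, 256, tolerance = 1e-9)
  # uniform +-1 ms stamp jitter on 1e4 samples: fitted line is within 50 us
  # RMS of the true line (OLS error oracle by direct simulation)
  set.seed(21)
  n <- 1e4
  true_line <- 10 + (0:(n - 1)) / 256
  noisy <- true_line + runif(n, -1e-3, 1e-3)
  r <- regress_timestamps(noisy, 1L, n + 1L)
  expect_lt(sqrt(mean((r$fitted - true_line)^2)), 50e-6)
  # two samples: the line through both points
  r2 <- regress_timestamps(c(1, 1.5), 1L, 3L)
  expect_equal(r2$fitted, c(1, 1.5))
  expect_equal(r2$segment$slope, 0.5)
  # one sample: passthrough without a fit
  r1 <- regress_timestamps(c(7), 1L, 2L)
  expect_equal(r1$fitted, 7)
  expect_true(is.na(r1$segment$slope))
})

test_that("RLS with forgetting 1 equals batch OLS", {
  set.seed(4)
  idx <- 0:149
  ts <- 2 + idx / 512 + rnorm(150, 0, 1e-4)
  batch <- ols_line(idx, ts)
  r <- rls_dejitter(idx, ts, forgetting = 1)
  expect_equal(r$intercept, unname(batch["intercept"]), tolerance = 1e-9)
  expect_equal(r$slope, unname(batch["slope"]), tolerance = 1e-9)
  # and along the whole trajectory, each prefix matches its own batch fit
  for (k in c(10, 50, 100)) {
    pre <- ols_line(idx[1:k], ts[1:k])
    expect_equal(unname(r$trace[k, "slope"]), unname(pre["slope"]),
                 tolerance = 1e-9)
  }
  # noiseless line: exact after two samples
  ts0 <- 5 + idx / 100
  r0 <- rls_dejitter(idx, ts0, forgetting = 1)
  expect_equal(r0$intercept, 5, tolerance = 1e-9)
  expect_equal(r0$slope, 1 / 100, tolerance = 1e-12)
})

test_that("RLS with forgetting < 1 re-converges after a rate change", {
  set.seed(9)
  n <- 3000
  idx <- 0:(n - 1)
  # sampling interval steps from 1/100 to 1/90 halfway through
  ts <- c(idx[1:1500] / 100, idx[1500] / 100 + (1:1500) / 90)
  r <- rls_dejitter(idx, ts + rnorm(n, 0, 1e-5), forgetting = 0.99)
  expect_equal(r$slope, 1 / 90, tolerance = 1e-3)
  # within 1000 samples of the step the slope has already re-converged
  expect_equal(unname(r$trace[2500, "slope"]), 1 / 90, tolerance = 1e-3)
})

test_that("clock-offset application subtracts the modeled offset", {
  cfg <- sync_config()
  ts <- seq(0, 100, by = 0.5)
  m0 <- fit_offset_model(offset_series(c(0, 50, 100), rep(0, 3)))
  expect_equal(apply_clock_offsets(ts, m0, cfg), ts)
  mc <- fit_offset_model(offset_series(c(0, 50, 100), rep(0.5, 3)))
  expect_equal(apply_clock_offsets(ts, mc, cfg), ts - 0.5)
  # linear offset in t rescales inter-sample intervals by (1 - slope)
  sl <- 2e-3
  at <- seq(0, 100, by = 5)
  ml <- fit_offset_model(offset_series(at, 0.1 + sl * at))
  out <- apply_clock_offsets(ts, ml, cfg)
  expect_equal(diff(out), rep(0.5 * (1 - sl), length(ts) - 1), tolerance = 1e-9)
  # disabled: untouched
  off <- sync_config(handle_clock_sync = FALSE)
  expect_identical(apply_clock_offsets(ts, mc, off), ts)
})

test_that("synchronization recovers capture times exactly in the noiseless limit", {
  cfg <- sync_config(time_update_interval = 2)
  info <- stream_info("a", "EEG", 1, 200, "float32", "s1")
  b <- simulate_session(list(device_spec(info)),
                        list(virtual_clock(0.75, 0)),  # offset, no drift/noise
                        network_spec(0, 0, 0, 0), cfg, 20, seed = 3)
  bs <- synchronize_recording(b, cfg)
  expect_lt(max(abs(bs$streams$a$timestamps_sync - bs$streams$a$truth$t_actual)),
            1e-9)
})

test_that("synchronization is idempotent and order-preserving", {
  cfg <- sync_config(time_update_interval = 2)
  info <- stream_info("a", "EEG", 1, 200, "float32", "s1")
  b <- simulate_session(list(device_spec(info, timestamp_noise_std = 2e-4)),
                        list(virtual_clock(0.5, 1e-5)),
                        network_spec(), cfg, 20, seed = 5)
  b1 <- synchronize_recording(b, cfg)
  b2 <- synchronize_recording(b1, cfg)
  expect_identical(b1$streams$a$timestamps_sync, b2$streams$a$timestamps_sync)
  expect_identical(b1$streams$a$segments, b2$streams$a$segments)
  expect_true(all(diff(b1$streams$a$timestamps_sync) > 0))
})

test_that("jitter handling off returns offset-corrected raw stamps exactly", {
  cfg_off <- sync_config(handle_jitter = FALSE, time_update_interval = 2)
  info <- stream_info("a", "EEG", 1, 200, "float32", "s1")
  b <- simulate_session(list(device_spec(info, timestamp_noise_std = 2e-4)),
                        list(virtual_clock(0.5, 1e-5)),
                        network_spec(), cfg_off, 20, seed = 5)
  bs <- synchronize_recording(b, cfg_off)
  st <- bs$streams$a
  model <- fit_offset_model(st$offsets, cfg_off$offset_jump_threshold)
  expect_identical(st$timestamps_sync,
                   st$timestamps_raw - predict(model, st$timestamps_raw))
})

test_that("chunked streams keep their sawtooth when jitter handling is off", {
  cfg_off <- sync_config(handle_jitter = FALSE, time_update_interval = 2)
  info <- stream_info("a", "EMG", 1, 500, "float32", "s1")
  dev <- device_spec(info, chunk_period = 0.02, stamp_mode = "delivery")
  b <- simulate_session(list(dev), list(virtual_clock()), network_spec(0, 0, 0, 0),
                        cfg_off, 10, seed = 6)
  bs <- synchronize_recording(b, cfg_off)
  d <- diff(bs$streams$a$timestamps_sync)
  expect_equal(mean(d < 1e-9), 0.9, tolerance = 0.01)  # 10 samples per chunk
  # with jitter handling on, the sawtooth is regressed away
  cfg_on <- sync_config(time_update_interval = 2)
  bs_on <- synchronize_recording(b, cfg_on)
  d_on <- diff(bs_on$streams$a$timestamps_sync)
  expect_lt(max(abs(d_on - 0.002)), 1e-5)
})

test_that("irregular streams are never regressed", {
  cfg <- sync_config()
  mk <- make_stream("m", ts = c(0.5, 1.2, 9.7), vals = matrix(c("a", "b", "c")),
                    srate = 0, fmt = "string", type = "Markers")
  b <- make_bundle(mk)
  bs <- synchronize_recording(b, cfg)
  expect_identical(bs$streams$m$timestamps_sync, c(0.5, 1.2, 9.7))
  expect_equal(nrow(bs$streams$m$segments), 1L)
  expect_true(is.na(bs$streams$m$segments$slope))
})

test_that("injected drift is recovered by the offset-model slope", {
  cfg <- sync_config()  # default 5 s probe cadence
  info <- stream_info("a", "EEG", 1, 100, "float32", "s1")
  # 10-minute stream, 10 ppm drift, no network noise: within 1 ppm
  b <- simulate_session(list(device_spec(info)),
                        list(virtual_clock(0.5, 1e-5)),
                        network_spec(0, 0, 0, 0), cfg, 600, seed = 12)
  m <- fit_offset_model(b$streams$a$offsets)
  expect_lt(abs(m$slope - 1e-5), 1e-6)
  # default spiky network: within 3 ppm
  b2 <- simulate_session(list(device_spec(info)),
                         list(virtual_clock(0.5, 1e-5)),
                         network_spec(), cfg, 600, seed = 12)
  m2 <- fit_offset_model(b2$streams$a$offsets)
  expect_lt(abs(m2$slope - 1e-5), 3e-6)
})

test_that("effective sampling rate flags misbehaving devices", {
  # 1001 samples spanning exactly 10 s -> 100.1 Hz
  st <- make_stream("a", ts = seq(0, 10, length.out = 1001), srate = 100)
  e <- effective_srate(st, sync_config())
  expect_equal(e$effective_srate, 100.1)
  expect_false(e$flag)  # within the 1% default tolerance
  # webcam-like stream alternating 30/60 fps intervals vs nominal 30
  iv <- rep(c(1 / 30, 1 / 60), 300)
  st2 <- make_stream("cam", ts = cumsum(c(0, iv)), srate = 30)
  e2 <- effective_srate(st2, sync_config())
  expect_true(e2$flag)
  expect_equal(e2$effective_srate, 40, tolerance = 0.1)
  expect_error(effective_srate(make_stream("x", ts = 1)), "fewer than 2")
})
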