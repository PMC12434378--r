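test_that("virtual clocks apply offset, drift and monotone noise clamping", {
  expect_equal(local_time(virtual_clock(), 5), 5.0)
  # 2.5 s ahead at 10 ppm drift: 2.5 + 100 * 1.00001 (hand arithmetic)
  expect_equal(local_time(virtual_clock(2.5, 1e-5), 100), 102.501)
  # noisy clock read sequentially stays non-decreasing
  ck <- virtual_clock(0, 0, noise_std = 1e-4)
  set.seed(3)
  reads <- vapply(seq(0, 1, length.out = 1e4), function(t) local_time(ck, t),
                  numeric(1))
  expect_true(all(diff(reads) >= 0))
  # and the same holds for one vectorized read
  ck2 <- virtual_clock(0, 0, noise_std = 1e-4)
  reads2 <- local_time(ck2, seq(0, 1, length.out = 1e4))
  expect_true(all(diff(reads2) >= 0))
})

test_that("network delays follow base + asymmetry + exponential jitter + spikes", {
  expect_equal(sample_delay(network_spec(0.003, 0, 0, 0), "forward", 5),
               rep(0.003, 5))
  net <- network_spec(0.001, 0, 0, 0, asymmetry = 0.0004)
  expect_equal(sample_delay(net, "forward"), 0.0012)
  expect_equal(sample_delay(net, "backward"), 0.0008)
  # law of large numbers: mean ~= base + jitter_scale within 2%
  set.seed(5)
  d <- sample_delay(network_spec(0.002, 0.001, 0, 0), "forward", 1e5)
  expect_equal(mean(d), 0.003, tolerance = 0.02)
  # certain spikes
  d <- sample_delay(network_spec(0.001, 0, 1, 0.05), "forward", 100)
  expect_true(all(d >= 0.051 - 1e-12))
  expect_true(all(sample_delay(network_spec(0, 0.01, 0.5, 0.05), "backward", 1e4) >= 0))
})

test_that("regular devices sample on the k/srate grid and honor dropouts", {
  info <- stream_info("a", "EEG", 1, 100, "float32", "s1")
  st <- simulate_device(device_spec(info), virtual_clock(), 10)
  expect_length(st$timestamps_raw, 1000)
  expect_equal(st$truth$t_actual, (0:999) / 100)
  expect_equal(st$timestamps_raw, st$truth$t_actual)  # identity clock, tau 0
  # dropout [4, 6) removes exactly 200 samples, leaving one 2 s gap
  st <- simulate_device(device_spec(info, dropout_windows = list(c(4, 6))),
                        virtual_clock(), 10)
  expect_length(st$timestamps_raw, 800)
  gaps <- diff(st$timestamps_raw)
  expect_equal(sum(gaps > 0.011), 1L)
  expect_equal(max(gaps), 2.01, tolerance = 1e-9)
})

test_that("gap conservation: omitted samples match window lengths", {
  info <- stream_info("a", "EEG", 1, 128, "float32", "s1")
  set.seed(8)
  for (i in 1:10) {
    w1 <- sort(runif(2, 0, 5)); w2 <- sort(runif(2, 5, 10))
    st <- simulate_device(device_spec(info, dropout_windows = list(w1, w2)),
                          virtual_clock(), 10)
    expected_omitted <- floor(diff(w1) * 128) + floor(diff(w2) * 128)
    omitted <- 1280 - length(st$timestamps_raw)
    expect_lte(abs(omitted - expected_omitted), 2)
  }
})

test_that("observed stamps reconstruct the timestamp model exactly at zero noise", {
  # t_obs - t_actual - tau - OFS_true(t_actual) == 0 for capture stamping
  info <- stream_info("a", "EEG", 1, 250, "float32", "s1")
  ck <- virtual_clock(1.25, 2e-5)
  st <- simulate_device(device_spec(info, setup_offset = 0.030), ck, 20)
  resid <- st$timestamps_raw - st$truth$t_actual - 0.030 -
    true_offset(ck, st$truth$t_actual)
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("delivery-stamped chunked devices cluster their stamps", {
  info <- stream_info("a", "EMG", 1, 500, "float32", "s1")
  st <- simulate_device(device_spec(info, chunk_period = 0.02,
                                    stamp_mode = "delivery"),
                        virtual_clock(), 10)
  d <- diff(st$timestamps_raw)
  # within-chunk spacing ~ 0; chunk steps ~ chunk_period; 500 Hz / 20 ms
  # chunks -> 10 samples per chunk, so 9/10 of spacings collapse
  expect_equal(mean(d < 1e-9), 0.9, tolerance = 0.01)
  expect_equal(max(d), 0.02, tolerance = 1e-9)
  expect_equal(length(unique(st$timestamps_raw)), 500)  # one stamp per chunk
  # stamps trail capture by at most one chunk period (a boundary sample can
  # land on its own chunk edge through float rounding of k/srate / period)
  lag <- st$timestamps_raw - st$truth$t_actual
  expect_true(all(lag > -1e-9 & lag <= 0.02 + 1e-9))
})

test_that("irregular devices emit per event and reject chunked ambiguity", {
  info <- stream_info("m", "Markers", 1, 0, "string", "mk")
  ev <- c(0.5, 1.7, 3.14)
  st <- simulate_device(device_spec(info, event_times = ev,
                                    signal = function(t) rep("x", length(t))),
                        virtual_clock(), 2)
  expect_equal(st$truth$t_actual, c(0.5, 1.7))  # third event is past duration
  expect_error(device_spec(info, chunk_period = 0.1), "ambiguous")
})

test_that("sessions recover injected clock offsets and are seed-deterministic", {
  cfg <- sync_config(time_update_interval = 2)
  info1 <- stream_info("a", "EEG", 1, 100, "float32", "s1")
  info2 <- stream_info("b", "EMG", 1, 100, "float32", "s2")
  devs <- list(device_spec(info1), device_spec(info2))
  # identity clocks, zero-delay network: offset series ~ 0 everywhere
  b0 <- simulate_session(devs, list(virtual_clock(), virtual_clock()),
                         network_spec(0, 0, 0, 0), cfg, 20, seed = 2)
  expect_lt(max(abs(b0$streams$a$offsets$ofs)), 1e-12)
  # offsets {+0.5, -0.3} recovered by the measured series means
  b1 <- simulate_session(devs,
                         list(virtual_clock(0.5), virtual_clock(-0.3)),
                         network_spec(), cfg, 20, seed = 2)
  expect_equal(mean(b1$streams$a$offsets$ofs), 0.5, tolerance = 0.005)
  expect_equal(mean(b1$streams$b$offsets$ofs), -0.3, tolerance = 0.005)
  # same seed twice: identical bundles, byte-identical after XDF round trip
  b2 <- simulate_session(devs,
                         list(virtual_clock(0.5), virtual_clock(-0.3)),
                         network_spec(), cfg, 20, seed = 2)
  expect_identical(b1$streams, b2$streams)
  f1 <- tempfile(fileext = ".xdf"); f2 <- tempfile(fileext = ".xdf")
  write_xdf(b1, f1); write_xdf(b2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("pulse signals place rising edges at exact period multiples", {
  p <- pulse_signal(period = 1, high_fraction = 0.5, srate = 1000, duration = 10)
  edges <- which(diff(p$values) > 0) + 1L
  # signal starts high at t = 0; 9 more upward transitions at 1..9 s
  expect_equal(p$timestamps[edges], 1:9, tolerance = 1e-9)
  expect_equal(p$values[1], 1)
  p2 <- pulse_signal(1, 0.5, 1000, 10, amplitude = 2)
  expect_equal(max(p2$values), 2)
  expect_equal(min(p2$values), 0)
  # half-max crossing times recovered within one sample interval
  mk <- extract_threshold_markers(p$timestamps, p$values)
  expect_length(mk, 9)
  expect_lt(max(abs(mk - 1:9)), 1 / 1000)
})

test_that("child seeds separate sub-streams and stay in integer range", {
  s <- vapply(sprintf("lbl%d", 1:200), function(l) child_seed(1, l), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_gt(length(unique(s)), 195)  # essentially collision-free
  expect_identical(child_seed(7, "x"), child_seed(7, "x"))
  expect_false(child_seed(7, "x") == child_seed(8, "x"))
})
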