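test_that("numeric streams round-trip bit-exact", {
  set.seed(31)
  ts <- 100 + cumsum(rexp(10, 100))
  vals <- matrix(rnorm(30), ncol = 3)
  st <- make_stream("eeg", ts, vals, srate = 100, fmt = "double64", ch = 3,
                    offsets = offset_series(c(100, 105), c(0.5, 0.5001),
                                            c(0.001, 0.002)))
  f <- tempfile(fileext = ".xdf")
  write_xdf(make_bundle(st), f)
  b <- read_xdf(f)
  expect_identical(b$streams$eeg$timestamps_raw, ts)
  expect_identical(b$streams$eeg$values, vals)
  expect_equal(b$streams$eeg$offsets$at, c(100, 105))
  expect_equal(b$streams$eeg$offsets$ofs, c(0.5, 0.5001))
  expect_equal(b$streams$eeg$info$name, "eeg")
  expect_equal(b$streams$eeg$info$nominal_srate, 100)
  expect_equal(b$streams$eeg$info$channel_format, "double64")
  unlink(f)
})

test_that("float32 values survive at single precision", {
  ts <- (0:9) / 100
  vals <- matrix(as.numeric(1:30) / 7, ncol = 3)
  f <- tempfile(fileext = ".xdf")
  write_xdf(make_bundle(make_stream("a", ts, vals, fmt = "float32", ch = 3)), f)
  b <- read_xdf(f)
  expect_identical(b$streams$a$timestamps_raw, ts)  # stamps are 8-byte floats
  expect_equal(b$streams$a$values, vals, tolerance = 1e-7)
  unlink(f)
})

test_that("string marker streams round-trip, including empty strings", {
  ts <- c(0.5, 1.7, 2.2, 9.9)
  vals <- matrix(c("go", "", "stop", "<&>"), ncol = 1)
  st <- make_stream("mk", ts, vals, srate = 0, fmt = "string", type = "Markers")
  f <- tempfile(fileext = ".xdf")
  write_xdf(make_bundle(st), f)
  b <- read_xdf(f)
  expect_identical(b$streams$mk$values, vals)
  expect_identical(b$streams$mk$timestamps_raw, ts)
  unlink(f)
})

test_that("randomized bundles round-trip across formats, counts and gaps", {
  fmts <- c("float32", "double64", "int8", "int16", "int32", "int64", "string")
  set.seed(77)
  for (rep in 1:8) {
    streams <- lapply(seq_len(sample(1:3, 1)), function(i) {
      fmt <- sample(fmts, 1)
      ch <- sample(1:4, 1)
      n <- sample(c(0:3, 50:300), 1)
      ts <- sort(runif(n, 0, 100))
      if (n > 1 && runif(1) < 0.5) ts[seq(n %/% 2, n)] <- ts[seq(n %/% 2, n)] + 30
      vals <- if (fmt == "string") {
        matrix(replicate(n * ch, paste(sample(letters, sample(0:5, 1)),
                                       collapse = "")), ncol = ch)
      } else if (fmt %in% c("float32", "double64")) {
        matrix(round(rnorm(n * ch), 3), ncol = ch)
      } else {
        rng <- switch(fmt, int8 = 127, int16 = 32000, 1e9)
        matrix(as.numeric(sample(-rng:rng, n * ch, replace = TRUE)), ncol = ch)
      }
      noff <- sample(0:5, 1)
      make_stream(paste0("s", i), ts, vals, srate = sample(c(0, 100, 512), 1),
                  fmt = fmt, ch = ch,
                  offsets = offset_series(sort(runif(noff, 0, 100)),
                                          rnorm(noff)))
    })
    f <- tempfile(fileext = ".xdf")
    write_xdf(do.call(make_bundle, streams), f, chunk_size = 37)
    b <- read_xdf(f)
    for (st in streams) {
      got <- b$streams[[st$info$name]]
      expect_identical(got$timestamps_raw, st$timestamps_raw)
      if (st$info$channel_format == "float32") {
        expect_equal(got$values, st$values, tolerance = 1e-6)
      } else {
        expect_identical(unname(got$values), unname(st$values))
      }
      expect_equal(got$offsets$at, st$offsets$at)
      expect_equal(got$offsets$ofs, st$offsets$ofs)
      expect_identical(got$info$channel_format, st$info$channel_format)
    }
    unlink(f)
  }
})

test_that("sample order within streams is preserved under interleaving", {
  ts1 <- (0:499) / 100
  ts2 <- (0:499) / 250
  f <- tempfile(fileext = ".xdf")
  write_xdf(make_bundle(make_stream("a", ts1, srate = 100),
                        make_stream("b", ts2, srate = 250)),
            f, chunk_size = 13)
  b <- read_xdf(f)
  expect_identical(b$streams$a$timestamps_raw, ts1)
  expect_identical(b$streams$b$timestamps_raw, ts2)
  expect_equal(b$streams$a$values[, 1], as.numeric(1:500))
  unlink(f)
})

test_that("omitted timestamps are deduced from the nominal interval", {
  ts <- 10 + (0:99) / 256  # exactly on the nominal grid
  f <- tempfile(fileext = ".xdf")
  write_xdf(make_bundle(make_stream("a", ts, srate = 256)), f,
            omit_deducible = TRUE)
  b <- read_xdf(f)
  expect_equal(b$streams$a$timestamps_raw, ts, tolerance = 1e-9)
  expect_equal(diff(b$streams$a$timestamps_raw), rep(1 / 256, 99),
               tolerance = 1e-12)
  unlink(f)
})

test_that("bad magic is a hard error; truncation is salvaged with a warning", {
  f <- tempfile()
  writeBin(charToRaw("NOTXDF##"), f)
  expect_error(read_xdf(f), "magic")
  ts <- (0:199) / 100
  f2 <- tempfile(fileext = ".xdf")
  write_xdf(make_bundle(make_stream("a", ts, srate = 100)), f2, chunk_size = 50)
  sz <- file.size(f2)
  raw_all <- readBin(f2, "raw", sz)
  f3 <- tempfile(fileext = ".xdf")
  writeBin(raw_all[1:floor(sz * 0.6)], f3)  # cut mid-chunk
  expect_warning(b <- read_xdf(f3), "truncated")
  n <- length(b$streams$a$timestamps_raw)
  expect_gt(n, 0)
  expect_lt(n, 200)
  expect_identical(b$streams$a$timestamps_raw, ts[1:n])
  unlink(c(f, f2, f3))
})

test_that("unknown chunk tags are skipped", {
  ts <- (0:49) / 100
  f <- tempfile(fileext = ".xdf")
  write_xdf(make_bundle(make_stream("a", ts, srate = 100)), f)
  con <- file(f, "ab")
  writeBin(streamsync:::.chunk_raw(99L, as.raw(1:10)), con)
  close(con)
  b <- read_xdf(f)
  expect_identical(b$streams$a$timestamps_raw, ts)
  expect_equal(unname(attr(b, "chunk_counts")["Unknown"]), 1L)
  unlink(f)
})

test_that("the validator reports footer inconsistencies and boundary notes", {
  ts <- (0:299) / 100
  f <- tempfile(fileext = ".xdf")
  write_xdf(make_bundle(make_stream("a", ts, srate = 100)), f)
  rep0 <- validate_xdf(f)
  expect_length(rep0$violations, 0)
  expect_equal(rep0$streams$observed, 300)
  expect_equal(rep0$streams$footer, 300)
  # corrupt: append one extra samples chunk after the footer so the observed
  # count no longer matches the footer count
  con <- file(f, "ab")
  writeBin(streamsync:::.chunk_raw(
    3L, streamsync:::.samples_chunk_raw(1L, 3.01, matrix(0), "float32", 100)),
    con)
  close(con)
  rep1 <- validate_xdf(f)
  expect_length(rep1$violations, 1)
  expect_match(rep1$violations, "footer sample_count")
  # a boundary-free file yields a note, not a violation
  f2 <- tempfile(fileext = ".xdf")
  write_xdf(make_bundle(make_stream("b", (0:9) / 100, srate = 100)), f2)
  rep2 <- validate_xdf(f2)
  expect_length(rep2$violations, 0)
  expect_match(rep2$notes, "Boundary")
  unlink(c(f, f2))
})
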