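# Chunk-oriented binary container codec (XDF dialect): magic "XDF:", then
# chunks [NumLengthBytes][length][tag uint16][content]. Tags: 1 FileHeader,
# 2 StreamHeader, 3 Samples, 4 ClockOffset, 5 Boundary, 6 StreamFooter.
# Little-endian throughout; the length prefix uses the smallest of {1,4,8}
# bytes that fits. Raw (uncorrected) timestamps and the clock-offset
# measurement series are what get written: the file is a record of the
# session "as it happened", and synchronization is re-derived on import.

.XDF_MAGIC <- charToRaw("XDF:")
.XDF_BOUNDARY_UUID <- as.raw(c(0x43, 0xA5, 0x46, 0xDC, 0xCB, 0xF5, 0x41, 0x0F,
                               0xB3, 0x0E, 0xD5, 0x46, 0x73, 0x83, 0xCB, 0xE4))

.fmt_size <- c(float32 = 4L, double64 = 8L, int8 = 1L, int16 = 2L,
               int32 = 4L, int64 = 8L, string = NA_integer_)

#' Stream metadata
#'
#' The declared description of a stream: what a subscriber needs to decide
#' whether to use it and how to decode it.
#'
#' @param name Human-readable stream name.
#' @param type Content type (e.g. \code{"EEG"}, \code{"Markers"}).
#' @param channel_count Number of channels (>= 1).
#' @param nominal_srate Declared sampling rate in Hz; 0 for irregular
#'   (event) streams.
#' @param channel_format One of \code{"float32"}, \code{"double64"},
#'   \code{"int8"}, \code{"int16"}, \code{"int32"}, \code{"int64"},
#'   \code{"string"}; fixed per stream.
#' @param source_id Stable unique identifier of the data source, used to
#'   re-bind subscribers after the publisher restarts (possibly on another
#'   host).
#' @param desc Optional XML description subtree (a string of attribute-free
#'   XML, or NULL).
#' @return A \code{stream_info} (named list).
#' @export
stream_info <- function(name, type = "", channel_count = 1L,
                        nominal_srate = 0, channel_format = "float32",
                        source_id = "", desc = NULL) {
  channel_format <- match.arg(channel_format, names(.fmt_size))
  stopifnot(channel_count >= 1, nominal_srate >= 0)
  structure(list(name = as.character(name), type = as.character(type),
                 channel_count = as.integer(channel_count),
                 nominal_srate = as.numeric(nominal_srate),
                 channel_format = channel_format,
                 source_id = as.character(source_id),
                 desc = desc),
            class = "stream_info")
}

#' @export
print.stream_info <- function(x, ...) {
  cat(sprintf("<stream_info> %s [%s] %d ch @ %.6g Hz, %s, source_id='%s'\n",
              x$name, x$type, x$channel_count, x$nominal_srate,
              x$channel_format, x$source_id))
  invisible(x)
}

## ---- low-level byte helpers -------------------------------------------

# unsigned little-endian integer (as double) -> nbytes raw
.int_to_raw_le <- function(x, nbytes) {
  out <- raw(nbytes)
  for (k in seq_len(nbytes)) {
    out[k] <- as.raw(x %% 256)
    x <- floor(x / 256)
  }
  out
}

.raw_to_int_le <- function(r) {
  sum(as.numeric(r) * 256^(seq_along(r) - 1))
}

# variable-length length field: 1 byte for the byte count in {1,4,8},
# then the value itself
.varlen_raw <- function(x) {
  nb <- if (x <= 255) 1L else if (x <= 4294967295) 4L else 8L
  c(as.raw(nb), .int_to_raw_le(x, nb))
}

.num_raw <- function(x, size) writeBin(as.numeric(x), raw(), size = size, endian = "little")
.int_raw <- function(x, size) writeBin(as.integer(x), raw(), size = size, endian = "little")

# two's complement via 32-bit words: exact for |x| < 2^53 (the double-exact
# integer range; adding 2^64 directly would round)
.int64_raw <- function(x) {
  out <- raw(8L * length(x))
  for (i in seq_along(x)) {
    lo <- x[i] %% 4294967296
    hi <- floor(x[i] / 4294967296) %% 4294967296
    out[(8L * (i - 1L) + 1L):(8L * i)] <-
      c(.int_to_raw_le(lo, 4L), .int_to_raw_le(hi, 4L))
  }
  out
}

.raw_int64 <- function(r) {
  n <- length(r) / 8L
  out <- numeric(n)
  for (i in seq_len(n)) {
    b <- r[(8L * (i - 1L) + 1L):(8L * i)]
    lo <- .raw_to_int_le(b[1:4])
    hi <- .raw_to_int_le(b[5:8])
    if (hi >= 2147483648) hi <- hi - 4294967296
    out[i] <- hi * 4294967296 + lo
  }
  out
}

.values_raw <- function(vals, fmt) {
  # vals: n x ch numeric matrix, row-major per sample on disk
  flat <- as.vector(t(vals))
  switch(fmt,
         float32 = .num_raw(flat, 4L),
         double64 = .num_raw(flat, 8L),
         int8 = .int_raw(flat, 1L),
         int16 = .int_raw(flat, 2L),
         int32 = .int_raw(flat, 4L),
         int64 = .int64_raw(flat),
         stop("unsupported format: ", fmt))
}

.chunk_raw <- function(tag, content) {
  body <- c(.int_raw(tag, 2L), content)
  c(.varlen_raw(length(body)), body)
}

## ---- XML helpers -------------------------------------------------------

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.header_xml <- function(info) {
  desc <- if (is.null(info$desc)) "<desc />" else as.character(info$desc)
  paste0("<?xml version=\"1.0\"?><info>",
         "<name>", .xml_escape(info$name), "</name>",
         "<type>", .xml_escape(info$type), "</type>",
         "<channel_count>", info$channel_count, "</channel_count>",
         "<nominal_srate>", sprintf("%.17g", info$nominal_srate), "</nominal_srate>",
         "<channel_format>", info$channel_format, "</channel_format>",
         "<source_id>", .xml_escape(info$source_id), "</source_id>",
         desc, "</info>")
}

.footer_xml <- function(ts, n) {
  paste0("<?xml version=\"1.0\"?><info>",
         "<first_timestamp>", if (n > 0) sprintf("%.17g", ts[1]) else "", "</first_timestamp>",
         "<last_timestamp>", if (n > 0) sprintf("%.17g", ts[length(ts)]) else "", "</last_timestamp>",
         "<sample_count>", n, "</sample_count></info>")
}

.parse_info_xml <- function(txt) {
  doc <- xml2::read_xml(txt)
  gettext1 <- function(tag) {
    nd <- xml2::xml_find_first(doc, paste0("./", tag))
    if (inherits(nd, "xml_missing")) "" else xml2::xml_text(nd)
  }
  desc_nd <- xml2::xml_find_first(doc, "./desc")
  desc <- if (inherits(desc_nd, "xml_missing") ||
              length(xml2::xml_children(desc_nd)) == 0L) NULL else as.character(desc_nd)
  srate <- suppressWarnings(as.numeric(gettext1("nominal_srate")))
  stream_info(name = gettext1("name"), type = gettext1("type"),
              channel_count = max(1L, suppressWarnings(as.integer(gettext1("channel_count")))),
              nominal_srate = if (is.na(srate)) 0 else srate,
              channel_format = gettext1("channel_format"),
              source_id = gettext1("source_id"), desc = desc)
}

## ---- writer ------------------------------------------------------------

.samples_chunk_raw <- function(stream_id, ts, vals, fmt, nominal_srate,
                               omit_deducible = FALSE) {
  n <- length(ts)
  head <- c(.int_raw(stream_id, 4L), .varlen_raw(n))
  if (fmt != "string" && !omit_deducible) {
    # fast path: every timestamp explicit
    per <- 1L + 8L + .fmt_size[[fmt]] * ncol(vals)
    body <- matrix(raw(), nrow = per, ncol = n)
    body[1L, ] <- as.raw(8L)
    body[2:9, ] <- matrix(.num_raw(ts, 8L), nrow = 8L)
    body[10:per, ] <- matrix(.values_raw(vals, fmt), ncol = n)
    return(c(head, as.raw(body)))
  }
  parts <- vector("list", n)
  expected <- -Inf
  dt <- if (nominal_srate > 0) 1 / nominal_srate else 0
  for (i in seq_len(n)) {
    explicit <- !omit_deducible || nominal_srate <= 0 ||
      abs(ts[i] - expected) > 1e-9
    tsr <- if (explicit) c(as.raw(8L), .num_raw(ts[i], 8L)) else as.raw(0L)
    vr <- if (fmt == "string") {
      unlist(lapply(vals[i, ], function(s) {
        b <- charToRaw(enc2utf8(as.character(s)))
        c(.varlen_raw(length(b)), b)
      }))
    } else {
      .values_raw(vals[i, , drop = FALSE], fmt)
    }
    parts[[i]] <- c(tsr, vr)
    expected <- ts[i] + dt
  }
  c(head, unlist(parts))
}

#' Write a recording bundle to an XDF file
#'
#' Writes the file header, one stream header per stream, interleaved sample
#' chunks in timestamp order, the clock-offset measurement series, boundary
#' chunks roughly every \code{boundary_interval} seconds, and per-stream
#' footers (first/last timestamp, sample count). Raw timestamps — not
#' synchronized ones — are stored, together with the offset series, so any
#' reader can redo (or improve on) the synchronization later.
#'
#' @param bundle A \code{recording_bundle}.
#' @param path Output file path.
#' @param chunk_size Samples per on-disk sample chunk.
#' @param boundary_interval Seconds of data between Boundary chunks.
#' @param omit_deducible Store a zero presence byte (timestamp deduced from
#'   the nominal interval at read time) for samples whose stamp equals the
#'   previous stamp plus the nominal interval.
#' @return \code{path}, invisibly.
#' @export
write_xdf <- function(bundle, path, chunk_size = 500,
                      boundary_interval = 10, omit_deducible = FALSE) {
  stopifnot(inherits(bundle, "recording_bundle"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.XDF_MAGIC, con)
  writeBin(.chunk_raw(1L, charToRaw("<?xml version=\"1.0\"?><info><version>1.0</version></info>")), con)

  streams <- bundle$streams
  pieces <- list()  # (time, raw) records to interleave
  for (i in seq_along(streams)) {
    st <- streams[[i]]
    fmt <- st$info$channel_format
    writeBin(.chunk_raw(2L, c(.int_raw(i, 4L), charToRaw(.header_xml(st$info)))), con)
    ts <- st$timestamps_raw
    vals <- st$values
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = st$info$channel_count)
    n <- length(ts)
    if (n > 0) {
      starts <- seq(1L, n, by = chunk_size)
      for (s0 in starts) {
        s1 <- min(s0 + chunk_size - 1L, n)
        raw_chunk <- .chunk_raw(3L, .samples_chunk_raw(
          i, ts[s0:s1], vals[s0:s1, , drop = FALSE], fmt,
          st$info$nominal_srate, omit_deducible))
        pieces[[length(pieces) + 1L]] <- list(t = ts[s0], bytes = raw_chunk)
      }
    }
    if (!is.null(st$offsets) && nrow(st$offsets) > 0) {
      for (j in seq_len(nrow(st$offsets))) {
        raw_chunk <- .chunk_raw(4L, c(.int_raw(i, 4L),
                                      .num_raw(st$offsets$at[j], 8L),
                                      .num_raw(st$offsets$ofs[j], 8L)))
        pieces[[length(pieces) + 1L]] <- list(t = st$offsets$at[j], bytes = raw_chunk)
      }
    }
  }
  if (length(pieces) > 0) {
    times <- vapply(pieces, `[[`, numeric(1), "t")
    ord <- order(times)
    last_boundary <- times[ord[1L]]
    for (k in ord) {
      if (pieces[[k]]$t - last_boundary >= boundary_interval) {
        writeBin(.chunk_raw(5L, .XDF_BOUNDARY_UUID), con)
        last_boundary <- pieces[[k]]$t
      }
      writeBin(pieces[[k]]$bytes, con)
    }
  }
  for (i in seq_along(streams)) {
    st <- streams[[i]]
    writeBin(.chunk_raw(6L, c(.int_raw(i, 4L),
                              charToRaw(.footer_xml(st$timestamps_raw,
                                                    length(st$timestamps_raw))))),
             con)
  }
  invisible(path)
}

## ---- reader ------------------------------------------------------------

.read_varlen <- function(con) {
  nb <- readBin(con, "raw", 1L)
  if (length(nb) == 0L) return(NULL)
  nb <- as.integer(nb)
  if (!nb %in% c(1L, 4L, 8L)) stop("invalid length-field size: ", nb)
  r <- readBin(con, "raw", nb)
  if (length(r) < nb) return(NULL)
  .raw_to_int_le(r)
}

.parse_samples_content <- function(content, fmt, channel_count, nominal_srate) {
  pos <- 1L
  take <- function(k) {
    r <- content[pos:(pos + k - 1L)]
    pos <<- pos + k
    r
  }
  stream_id <- .raw_to_int_le(take(4L))
  nb <- as.integer(take(1L))
  nsamp <- .raw_to_int_le(take(nb))
  size <- .fmt_size[[fmt]]
  if (fmt != "string") {
    per <- 1L + 8L + size * channel_count
    rest <- length(content) - pos + 1L
    if (rest == per * nsamp && all(content[pos + per * (seq_len(nsamp) - 1L)] == as.raw(8L))) {
      # fast path: all timestamps explicit
      body <- matrix(content[pos:length(content)], nrow = per)
      ts <- readBin(as.raw(body[2:9, ]), "double", nsamp, size = 8L, endian = "little")
      vraw <- as.raw(body[10:per, ])
      flat <- switch(fmt,
        float32 = readBin(vraw, "double", nsamp * channel_count, size = 4L, endian = "little"),
        double64 = readBin(vraw, "double", nsamp * channel_count, size = 8L, endian = "little"),
        int8 = readBin(vraw, "integer", nsamp * channel_count, size = 1L, endian = "little"),
        int16 = readBin(vraw, "integer", nsamp * channel_count, size = 2L, endian = "little"),
        int32 = readBin(vraw, "integer", nsamp * channel_count, size = 4L, endian = "little"),
        int64 = .raw_int64(vraw))
      vals <- matrix(as.numeric(flat), nrow = nsamp, byrow = TRUE)
      return(list(stream_id = stream_id, ts = ts, explicit = rep(TRUE, nsamp),
                  vals = vals))
    }
  }
  ts <- numeric(nsamp); explicit <- logical(nsamp)
  vals <- if (fmt == "string") matrix(NA_character_, nsamp, channel_count)
          else matrix(NA_real_, nsamp, channel_count)
  for (i in seq_len(nsamp)) {
    flag <- as.integer(take(1L))
    if (flag == 8L) {
      ts[i] <- readBin(take(8L), "double", 1L, size = 8L, endian = "little")
      explicit[i] <- TRUE
    } else {
      ts[i] <- NA_real_
    }
    if (fmt == "string") {
      for (ch in seq_len(channel_count)) {
        snb <- as.integer(take(1L))
        slen <- .raw_to_int_le(take(snb))
        vals[i, ch] <- if (slen > 0) rawToChar(take(slen)) else ""
      }
    } else {
      vr <- take(size * channel_count)
      vals[i, ] <- switch(fmt,
        float32 = readBin(vr, "double", channel_count, size = 4L, endian = "little"),
        double64 = readBin(vr, "double", channel_count, size = 8L, endian = "little"),
        int8 = readBin(vr, "integer", channel_count, size = 1L, endian = "little"),
        int16 = readBin(vr, "integer", channel_count, size = 2L, endian = "little"),
        int32 = readBin(vr, "integer", channel_count, size = 4L, endian = "little"),
        int64 = .raw_int64(vr))
    }
  }
  list(stream_id = stream_id, ts = ts, explicit = explicit, vals = vals)
}

#' Read an XDF file into an (unsynchronized) recording bundle
#'
#' A tolerant reader: unknown chunk tags are skipped, and a truncated file is
#' salvaged up to the last complete chunk (with a warning). Samples whose
#' presence byte is 0 get their timestamp deduced as the previous timestamp
#' plus the nominal sampling interval. The returned bundle carries raw
#' timestamps and offset series; run [synchronize_recording()] to obtain
#' synchronized timestamps.
#'
#' @param path Path to an XDF file.
#' @return A \code{recording_bundle} with attribute \code{"chunk_counts"}
#'   (named count per chunk tag) and per-stream \code{footer} entries.
#' @export
read_xdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || !identical(magic, .XDF_MAGIC)) {
    stop("not an XDF file (bad magic): ", path)
  }
  infos <- list(); samples <- list(); offs <- list(); footers <- list()
  counts <- c(FileHeader = 0L, StreamHeader = 0L, Samples = 0L,
              ClockOffset = 0L, Boundary = 0L, StreamFooter = 0L, Unknown = 0L)
  repeat {
    len <- .read_varlen(con)
    if (is.null(len)) break
    body <- readBin(con, "raw", len)
    if (length(body) < len) {
      warning("truncated chunk at end of file; salvaged earlier content")
      break
    }
    tag <- .raw_to_int_le(body[1:2])
    content <- body[-(1:2)]
    key <- c("FileHeader", "StreamHeader", "Samples", "ClockOffset",
             "Boundary", "StreamFooter")[tag]
    if (is.na(tag) || tag < 1 || tag > 6) {
      counts["Unknown"] <- counts["Unknown"] + 1L
      next
    }
    counts[key] <- counts[key] + 1L
    if (tag == 2L) {
      sid <- as.character(.raw_to_int_le(content[1:4]))
      infos[[sid]] <- .parse_info_xml(rawToChar(content[-(1:4)]))
      samples[[sid]] <- list()
      offs[[sid]] <- list()
    } else if (tag == 3L) {
      sid <- as.character(.raw_to_int_le(content[1:4]))
      if (is.null(infos[[sid]])) next  # samples for an undeclared stream
      info <- infos[[sid]]
      parsed <- .parse_samples_content(content, info$channel_format,
                                       info$channel_count, info$nominal_srate)
      samples[[sid]][[length(samples[[sid]]) + 1L]] <- parsed
    } else if (tag == 4L) {
      sid <- as.character(.raw_to_int_le(content[1:4]))
      at <- readBin(content[5:12], "double", 1L, size = 8L, endian = "little")
      o <- readBin(content[13:20], "double", 1L, size = 8L, endian = "little")
      offs[[sid]][[length(offs[[sid]]) + 1L]] <- c(at, o)
    } else if (tag == 6L) {
      sid <- as.character(.raw_to_int_le(content[1:4]))
      doc <- xml2::read_xml(rawToChar(content[-(1:4)]))
      footers[[sid]] <- list(
        first_timestamp = suppressWarnings(as.numeric(xml2::xml_text(
          xml2::xml_find_first(doc, "./first_timestamp")))),
        last_timestamp = suppressWarnings(as.numeric(xml2::xml_text(
          xml2::xml_find_first(doc, "./last_timestamp")))),
        sample_count = suppressWarnings(as.numeric(xml2::xml_text(
          xml2::xml_find_first(doc, "./sample_count")))))
    }
  }
  streams <- lapply(names(infos), function(sid) {
    info <- infos[[sid]]
    chunks <- samples[[sid]]
    ts <- unlist(lapply(chunks, `[[`, "ts"))
    expl <- unlist(lapply(chunks, `[[`, "explicit"))
    vals <- do.call(rbind, lapply(chunks, `[[`, "vals"))
    if (is.null(ts)) { ts <- numeric(); expl <- logical() }
    if (any(!expl)) {  # deduce omitted stamps
      dt <- if (info$nominal_srate > 0) 1 / info$nominal_srate else 0
      for (i in which(!expl)) ts[i] <- if (i == 1L) 0 else ts[i - 1L] + dt
    }
    om <- offs[[sid]]
    oser <- if (length(om) > 0) {
      m <- do.call(rbind, om)
      offset_series(m[, 1], m[, 2])
    } else offset_series()
    structure(list(info = info, timestamps_raw = as.numeric(ts),
                   values = if (is.null(vals)) matrix(numeric(), 0, info$channel_count) else vals,
                   offsets = oser, timestamps_sync = NULL, segments = NULL,
                   truth = NULL, footer = footers[[sid]]),
              class = "recorded_stream")
  })
  names(streams) <- vapply(streams, function(s) s$info$name, character(1))
  dur <- suppressWarnings(max(0, vapply(streams, function(s) {
    n <- length(s$timestamps_raw)
    if (n >= 2) s$timestamps_raw[n] - s$timestamps_raw[1] else 0
  }, numeric(1))))
  structure(list(streams = streams, duration = dur, seed = NA_integer_),
            class = "recording_bundle", chunk_counts = counts)
}

#' Structural validation of an XDF file
#'
#' Walks the file and reports chunk counts per tag, per-stream sample
#' counts, and footer consistency (footer sample count versus observed).
#' Violations are listed, not raised; a file without Boundary chunks gets an
#' informational note only.
#'
#' @param path Path to an XDF file.
#' @return A list of class \code{xdf_report}: \code{chunk_counts},
#'   \code{streams} (data.frame of name, observed and footer counts),
#'   \code{violations} (character), \code{notes} (character).
#' @export
validate_xdf <- function(path) {
  bundle <- withCallingHandlers(
    read_xdf(path),
    warning = function(w) invokeRestart("muffleWarning"))
  counts <- attr(bundle, "chunk_counts")
  violations <- character(); notes <- character()
  rows <- lapply(names(bundle$streams), function(nm) {
    st <- bundle$streams[[nm]]
    obs <- length(st$timestamps_raw)
    foot <- if (is.null(st$footer)) NA_real_ else st$footer$sample_count
    if (!is.na(foot) && foot != obs) {
      violations <<- c(violations, sprintf(
        "stream '%s': footer sample_count %.0f != observed %d", nm, foot, obs))
    }
    if (is.null(st$footer)) {
      violations <<- c(violations, sprintf("stream '%s': missing footer", nm))
    }
    data.frame(stream = nm, observed = obs, footer = foot)
  })
  if (counts[["Boundary"]] == 0L) {
    notes <- c(notes, "no Boundary chunks present (seekability reduced)")
  }
  structure(list(chunk_counts = counts,
                 streams = do.call(rbind, rows),
                 violations = violations, notes = notes),
            class = "xdf_report")
}

#' @export
print.xdf_report <- function(x, ...) {
  cat("<xdf_report>\n chunk counts:\n")
  for (k in names(x$chunk_counts)) {
    if (x$chunk_counts[[k]] > 0) cat(sprintf("   %-12s %d\n", k, x$chunk_counts[[k]]))
  }
  if (!is.null(x$streams)) {
    cat(" streams:\n")
    print(x$streams, row.names = FALSE)
  }
  if (length(x$violations)) {
    cat(" violations:\n"); for (v in x$violations) cat("   -", v, "\n")
  } else cat(" no violations\n")
  for (v in x$notes) cat(" note:", v, "\n")
  invisible(x)
}
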