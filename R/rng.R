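# Reproducible sub-streams: one root seed, per-component child seeds derived
# from fixed labels so simulator components can be replayed independently.

#' Derive a child seed from a root seed and a label
#'
#' Mixes a root seed with a character label into a deterministic 31-bit
#' integer, so that every component of a simulation (each device, each probe
#' scheduler, the network) draws from its own replayable stream.
#'
#' @param seed Root integer seed.
#' @param label Character label naming the sub-stream.
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @examples
#' child_seed(1, "device/eeg") != child_seed(1, "device/emg")
#' @export
child_seed <- function(seed, label) {
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  s <- as.numeric(seed) %% m
  for (ch in utf8ToInt(paste0("streamsync:", label))) {
    s <- (s * 131 + ch) %% m
  }
  as.integer(s)
}

# Run `expr` under a temporary RNG state seeded from (seed, label),
# restoring the caller's RNG state afterwards.
with_child_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, label))
  expr
}
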