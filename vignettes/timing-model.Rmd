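---
title: "The streamsync timing model: clock offsets, dejittering, and what the simulator can show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The streamsync timing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamsync)
```

## The synchronization problem

A multimodal recording pulls time series from several devices, each
attached to a host with its own clock. Host clocks differ by a roughly
constant offset (often seconds to years, depending on the epoch), diverge
slowly (drift on the order of parts per million), and the stamps a device
produces additionally carry a constant device-path latency (the *setup
offset* $\tau$) and sample-to-sample noise. `streamsync` models an observed
stamp as

$$ t_{obs} = t_{actual} + \tau + \overline{OFS} + \varepsilon $$

and provides the machinery to measure $\overline{OFS}$ online, invert the
model post hoc, and quantify what remains.

## Clock measurement and the minimum-RTT filter

One probe exchange produces four timestamps $t_0 \ldots t_3$ and the pair

$$ RTT = (t_3 - t_0) - (t_2 - t_1), \qquad
   OFS = \tfrac{1}{2}\big((t_1 - t_0) + (t_2 - t_3)\big). $$

$OFS$ is exact when the forward and backward transmission delays are equal;
an asymmetry of $\Delta$ biases it by $\Delta/2$. Since delay spikes
(scheduler hiccups, WLAN retransmits) inflate $RTT$, selecting the
minimum-RTT exchange of a burst bounds the offset error by half the
retained round trip — an invariant the test suite asserts against an
exhaustive scan of each simulated burst. Ties on $RTT$ are broken toward
the earliest exchange so replays are deterministic. A burst whose exchanges
all exceed `time_probe_max_rtt` raises a typed empty-burst condition and the
caller keeps its previous estimate; the retained measurement is dated at
$t_3$ (the burst midpoint would be equally defensible; $t_3$ is what a
live inlet actually possesses).

The offset series is smoothed into a **piecewise-linear model**: the series
is split wherever consecutive offsets step by more than
`offset_jump_threshold` (default 1 s — a reconnect, possibly to a different
host, produces steps orders of magnitude above anything drift can do
between two bursts), and one ordinary-least-squares line is fitted per
piece. Robustness to outliers is deliberately left to the upstream RTT
filter rather than duplicated with a robust regressor; the estimator is
then linear, exactly reproducible, and recovers a noiseless drift to
machine precision. Evaluation clamps the query time into the measurement
span of the owning piece, so the model never extrapolates a drift line
beyond what was measured; at the default 5 s burst cadence the freeze
costs at most drift × 5 s ≈ 50 µs at 10 ppm.

## Dejittering

Within a regularly sampled segment the capture times are a perfect line in
the sample index, so all timestamp roughness — stamping noise, and for
delivery-stamped devices the chunking sawtooth — is removed by replacing
the stamps with their least-squares line. Two estimators are provided:
batch OLS per segment (`regress_timestamps()`, the post-hoc path) and a
recursive least-squares filter with forgetting factor
$\lambda \in (0, 1]$ (`rls_dejitter()`, the real-time path). The RLS
recursion is initialized exactly from the first two samples, which makes
the $\lambda = 1$ case algebraically identical to batch OLS — the suite
checks equality at every prefix, not just in the limit. $\lambda < 1$
(default capability, not default behavior) tracks genuine rate changes at
the cost of variance.

Segments are delimited by **break detection**: a gap between consecutive
stamps larger than `max(break_threshold_seconds, break_threshold_samples /
nominal_srate)` (defaults 1 s / 500 samples, both config-exposed) starts a
new segment, so a dropout or reconnect never lets one regression span two
regimes. Irregular streams (`nominal_srate = 0`, e.g. marker streams) are
structurally exempt from regression — smoothing event times would destroy
them, and the guard makes that failure mode impossible rather than merely
discouraged. The same reasoning motivates the `effective_srate()`
diagnostic (sample count divided by the recorded span): a device whose
effective rate deviates from its declared rate by more than
`srate_tolerance` (default 1%) — a webcam hopping between 30 and 60 fps —
is flagged, and the recommended response is `handle_jitter = FALSE`, which
leaves the offset-corrected raw stamps untouched. `HandleJitter` and
`HandleJitterRemoval` are accepted as aliases in configuration files, as
both spellings circulate.

**Sign convention.** With the recorder-side inlet as probe initiator, the
measured offset equals (outlet clock − recorder clock); mapping stamps into
the recorder timebase therefore *subtracts* the modeled offset. The
convention is fixed package-wide and pinned by an end-to-end test: a
noiseless simulated session must synchronize to the true capture times
exactly, which fails loudly under either sign error.

## What the simulator emulates — and what it does not

The simulator generates the conditions the synchronization layer is built
for, with every hidden variable retained as ground truth:

* **Clocks** — constant epoch offset, linear drift, Gaussian read noise
  with a monotonicity clamp (reads never run backwards as long as the
  queried true times do not).
* **Networks** — per-direction delay = base ± asymmetry/2 + exponential
  jitter + Bernoulli spikes. The spike family (10% × 50 ms by default) is a
  modeling choice: published descriptions say only "random spikes", so the
  distribution is documented and every parameter surfaced in
  `network_spec()`.
* **Devices** — regular capture on the $k/f_s$ grid or irregular events;
  per-sample stamping noise; dropout windows; chunked transmission with an
  explicit stamping mode. *Capture-stamped* devices (professional
  amplifiers) stamp each sample when measured; *delivery-stamped* devices
  (consumer webcams, chunked links) stamp whole chunks on arrival, which
  makes their raw stamps a 20 ms sawtooth. Both modes exist in the wild and
  neither is asserted as "the" truth; the flag is per device.
* **Reproducibility** — one root seed; every device, probe scheduler and
  experiment derives its own labeled sub-stream (`child_seed()`), so a
  session is bit-reproducible and components can be replayed in isolation.

Deliberately not emulated: physiological signal content (only timing
structure matters here), operating-system scheduling artifacts beyond the
delay model, and temperature-dependent (nonlinear) drift. Consequently,
passing tests show that the *estimators invert the stated model*; they do
not certify any particular device's $\tau$ stability or a real network's
asymmetry, which must be measured in situ — that is precisely what
`measure_setup_offset()` is for.

## The reference studies and their sizes

Two canned experiments reproduce the package's headline checks; sizes were
chosen so each runs in seconds while leaving estimator error far from the
thresholds being asserted:

* `two_stream_pulse_experiment()` — 10 simulated minutes of two 2000 Hz
  streams sharing a 2 Hz square wave (≈1200 usable edge pairs), one
  capture-stamped and one delivery-stamped in 20 ms chunks, host clocks
  0.5 s off with 10 ppm drift, 0.2 ms stamping noise, default probe
  schedule. With jitter handling on, the sd of mean-centered paired edge
  differences is a few hundredths of a millisecond; turning it off
  re-exposes the raw stamp noise and sawtooth and inflates that sd by an
  order of magnitude.
* `clock_filter_experiment()` — 100 bursts × 10 probes through a 0.2 ms
  base-delay network with 0.5 ms exponential jitter and 10% × 50 ms spikes
  against a 0.5 s / 10 ppm clock; the maximum offset error at the retained
  exchanges stays well under a millisecond because a burst almost surely
  contains at least one spike-free round trip.

In this sampling-grid geometry both streams sample the shared wave at the
same true instants and every edge sits at a fixed phase within the 20 ms
chunk, so the chunk-induced error is constant and the centered statistics
isolate genuine jitter; the setup-offset study instead uses a 997 Hz grid
against a 0.2 s pulse so edge phases equidistribute and the interpolation
error averages out of the mean.

## Container format choices

The XDF writer fixes what the container description leaves open:
little-endian throughout; length prefixes use the smallest of {1, 4, 8}
bytes that fits; timestamps are 8-byte floats in outlet-local time;
clock-offset chunks store (collection time, offset) pairs; boundary chunks
are emitted every 10 s of data (config-exposed; cadence is a seekability
aid, not a correctness feature). The reader is tolerant by policy: unknown
tags are skipped, a truncated file is salvaged to the last complete chunk
with a warning, and `validate_xdf()` reports structural violations instead
of raising. A sample whose presence byte is 0 has its stamp deduced as the
previous stamp plus the nominal interval — the writer only omits stamps
that are exactly deducible, so deduction is lossless.

## Degenerate inputs and numerical corners

Single-measurement offset series become constant pieces; length-1 segments
pass through unfitted; a constant signal yields no threshold markers (the
threshold is `(max+min)/2`, referenced to the recorded minimum so a DC
offset does not bias it, and markers are refractory until the signal falls
below threshold again); `force_default_timestamps` is realized at the
recorder boundary (device stamps discarded, samples restamped at receipt),
which rescues third-party applications stamping from an unsynchronizable
clock source. Probe exchanges difference timestamps of similar magnitude,
so absolute float error near 100 s magnitudes is ~1e-14 s — tests assert
absolute, not relative, tolerances there.

## Known limitations

* Constant path asymmetry is indistinguishable from a clock offset for any
  two-way protocol; the residual bias is asymmetry/2 and must be bounded by
  hardware knowledge, not software.
* The offset model is linear per piece; strongly temperature-cycled clocks
  would need a spline or windowed fit (out of scope).
* The transport is in-process by design — it reproduces buffering,
  discovery and recovery *semantics*, not wire formats or multicast
  behavior.
* Dejittering assumes the declared rate is honest within a segment; the
  effective-rate flag is the intended escape hatch when it is not.
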