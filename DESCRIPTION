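Package: streamsync
Title: Clock Synchronization, Dejittering and XDF Storage for Multimodal Biosignal Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable implementation of the timing core used by
    lab-streaming acquisition systems: NTP-style clock-offset estimation with
    minimum round-trip-time filtering, the observed-timestamp model
    (capture time + device setup offset + smoothed clock offset + noise) and
    its post-hoc inversion by segmented linear regression (dejittering), a
    chunk-oriented XDF-compatible binary container codec, an in-process
    publish/subscribe transport with buffering and reconnection semantics,
    and a virtual clock/network/device simulator that reproduces
    synchronization-validation experiments entirely in software, with known
    ground truth and seeded determinism.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
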