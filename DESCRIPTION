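Package: tinnipipe
Title: Startle, Brainstem Response and Cochlear Nucleus Unit Analysis for
    Tinnitus Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies gap prepulse inhibition of the acoustic startle
    reflex (GPIAS) from piezoelectric or accelerometer recordings via
    Hilbert-envelope response amplitudes, estimates hearing thresholds from
    auditory brainstem response (ABR) epoch stacks with a peak-tracking
    algorithm, and extracts firing rate, tuning width and best frequency
    from dorsal cochlear nucleus spike trains.  Includes a seeded synthetic
    recording generator emulating the full experimental timeline
    (screening, noise exposure, chemogenetic treatment), group statistics
    and power computations, and a binary-array plus JSON-sidecar container
    format for recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
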