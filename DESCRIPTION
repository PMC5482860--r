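Package: rrnastage
Title: Ribosomal RNA Profiling for Sex Identification and Ovary Staging in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies 5S and 18S ribosomal RNA from capillary-electrophoresis
    electropherograms and turns the resulting rRNA indexes into reproductive
    staging tools for fish. Provides ladder-based time-to-size calibration,
    baseline correction, valley-to-valley peak detection and integration with
    time-corrected areas, assignment of peaks to RNA species by apparent-size
    windows, and the three ovary indexes (percent 5S rRNA of total RNA, the
    natural log of the 5S/18S ratio, and percent 18S rRNA). Builds
    species-specific standard curves between an index and the gonadosomatic
    index or the volume percent of primary-growth oocytes by comparing a fixed
    menu of regression families, inverts them to predict maturity on a
    normalized 10-point score, and classifies sex by margin-based index
    thresholds with explicit applicability regimes. A synthetic-data module
    generates electropherograms, oocyte morphometry tables and fish cohorts
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
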