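Package: repcycle
Title: Cell-Cycle Transcription and DNA Replication Timing Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links cell-cycle-phase-specific transcription to DNA replication
    timing (T_rep). Maps replication-timing profiles onto genes by linear
    interpolation to gene midpoints, computes per-timepoint correlation
    "oscillation profiles" between synchronized expression time courses and
    T_rep, and stratifies genes by replication time (early/late S) and by
    proximity to origins of replication. Includes early-replicating peak
    calling for low-resolution human-style profiles, asynchronous-expression
    comparisons with copy-number correction, and a fully truth-tracked
    synthetic-data generator (ORI firing program, fork-progression T_rep
    rendering, sinusoidal expression with tunable expression-to-firing-time
    coupling) so that every stage of the analysis is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
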