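Package: prmforge
Title: Design, Scheduling and Figures of Merit for Parallel Reaction
    Monitoring Assays on Ion-Trap Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds scheduled parallel reaction monitoring (PRM) assays from
    transition-level quantitative reports: transition-quality filtering and
    precursor qualification, retention-time window assignment with edge
    widening, concurrency and cycle-time feasibility analysis, scan-range
    optimization, balanced-load peptide selection and multi-assay splitting.
    Includes an instrument timing model (ion-trap scan rates, SRM dwell
    arithmetic, automatic gain control injection times, dynamic
    maximum-injection-time allocation, Poisson counting-statistics bounds),
    real-time retention-time alignment against a compressed reference run for
    scheduled acquisition windows, dilution-curve figures of merit (bilinear
    limit-of-detection fitting, limit-of-quantification estimation with
    transition-subset optimization, integration-boundary alignment), and a
    synthetic LC-MS simulator so every component is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
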