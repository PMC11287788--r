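Package: pscpipe
Title: Postsynaptic Current Detection and Neuroendocrine Scoring for
    Stress-Physiology Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested pipeline for the bespoke computations of early-life by
    adult stress neuroendocrine experiments in mice: detection of GABAergic
    postsynaptic currents (PSCs) in voltage-clamp recordings and per-cell
    event metrics (frequency, backward interevent intervals, eligibility
    filtered amplitudes, isolated-event averages, 80-20% decay time);
    k-sample Anderson-Darling comparison of event distributions with Holm
    adjusted post hoc pairs and a design-aware percentile bootstrap of group
    means and differences; luteinizing hormone surge thresholding and
    classification; estrous-cycle scoring; and summary-statistic effect
    sizes. A synthetic-data module generates traces with ground-truth
    events, hormone time courses and stage sequences so every stage is
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
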