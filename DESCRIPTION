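Package: connectodist
Title: Jensen-Shannon Connectivity Distance for Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Edgewise Jensen-Shannon distance between cohorts of functional
    connectomes (task versus resting-state), with centralized and distributed
    processing statistics over functional-network partitions, amplitude-adjusted
    Fourier-transform (AAFT) surrogate and label-permutation null models,
    search information on weighted structural connectomes, and percentile-bin
    association analyses between connectivity distance and structural weights.
    Includes a synthetic-data generator with planted edge effects so every
    pipeline stage can be validated without access to neuroimaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
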