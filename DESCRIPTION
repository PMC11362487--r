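Package: entropySI
Title: Latent Speech Intelligibility from Listener-Transcription Entropy Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures speech intelligibility from aligned listener
    transcriptions of spontaneous speech. Aggregates transcription grids
    into word-level normalized Shannon entropy scores, fits Bayesian
    normal linear mixed models and beta-proportion generalized linear
    latent and mixed models (GLLAMMs) to the scores by MCMC, assesses
    chain quality with rank-normalized split R-hat and effective sample
    size, compares models by DIC, WAIC and PSIS-LOO with
    Pareto-k influential-observation diagnostics, and estimates, ranks
    and contrasts speakers' latent potential intelligibility. Includes a
    synthetic-data generator emulating a two-group (normal hearing vs.
    cochlear implant) transcription study design so the full pipeline is
    testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
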