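Package: covleak
Title: Auditing Covariance-Based Data Reconstruction in Federated Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mock federated-analysis testbed and attack toolkit for auditing
    whether summary-statistic endpoints leak individual-level data. Servers
    expose only sample means, sample covariances and a client-to-server
    broadcast under configurable disclosure-control thresholds, additive output
    noise and an epsilon-differential-privacy accountant (Laplace mechanism,
    sequential composition). The package implements the covariance-based
    reconstruction attack, which recovers a private server-side vector from
    its covariances with client-known linearly independent probe vectors, the
    noise-averaging extension of the attack, privacy-budget trade-off
    experiments, a CNSIM-like synthetic federation generator, and command-line
    entry points for reproducible audits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
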