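Package: seabedrisk
Title: Probabilistic Environmental Risk Assessment for Seabed Mining
Version: 0.1.0
Authors@R: person("Baltic", "Benthos Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for causal, probabilistic environmental risk assessment
    of seabed mineral extraction. Merges expert-elicited causal maps into a
    combined causal network, builds a discrete Bayesian network of mining
    pressures and benthic-fauna mortality with decision and random nodes,
    initializes conditional probability tables from ranked parent influences,
    combines direct and indirect mortality on a 1 percent grid, and queries
    posterior mortality distributions under alternative mining scenarios.
    Includes a synthetic-data generator emulating the elicited structure and
    a command-line pipeline with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
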