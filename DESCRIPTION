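Package: nicodyn
Title: Nicotine Microdose Craving Dynamics and Brain-Connectivity-State
    Driver-Node Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing cyclical nicotine craving under intranasal
    microdosing and for nominating neuromodulatory targets from dynamic
    functional connectivity. Implements the exponential craving model
    cravings = A + B*exp(-t/tau) with its pharmacokinetic reparameterisation
    against blood nicotine concentration, fixed-interval and ad-libitum puff
    schedule simulation, windowed Pearson connectivity with nodal-strength
    profiles clustered into brain-connectivity states, exact enumeration of
    minimum dominating sets of the binarized state graphs, and ranking of
    common driver nodes by the fraction of regions they control. A synthetic
    data generator plants multi-state correlation structure with designated
    hub regions so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    cluster,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
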