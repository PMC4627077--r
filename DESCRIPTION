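Package: tufret
Title: Kinetics of EF-Tu Dynamics During Pretranslocation Complex Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the delivery of aminoacyl-tRNA to the bacterial ribosome by
    the elongation factor EF-Tu as a branched mass-action reaction scheme, and
    provides the analysis machinery used to characterize it: deterministic
    integration of the scheme with projection onto four stopped-flow
    fluorescence observables (EF-Tu:L11 Cy3 quench/recovery, EF-Tu:tRNA Cy3
    quench/recovery, proflavin accommodation, phosphate-binding-protein Pi
    release), mono- and biexponential apparent-rate fitting, linear and
    Michaelis-Menten concentration-dependence fits, global multi-channel
    rate-constant estimation, a per-molecule stochastic (Gillespie) simulator
    of camera-frame Cy3/Cy5 single-molecule FRET traces, and trace analysis
    (event detection, dwell-time fitting, postsynchronized FRET probability
    density plots and synchronized averages). A synthetic-data module generates
    every input the fitters consume so the full pipeline is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
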