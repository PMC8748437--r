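Package: muldekit
Title: Body-Size Time Series, Fossil-Record Completeness and
    Sampled-Ancestor Post-Processing for the Silurian Ophiuroid Record
Version: 0.9.0
Authors@R: person("Gotland", "Palaeo Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing miniaturization (Lilliput) signals in
    fossil assemblage series and for post-processing fossilized
    birth-death (FBD) inferences. Builds lateral-arm-plate body-size time
    series by locality and tests per-event size changes with a Monte
    Carlo permutation null; computes fossil-record completeness
    (psi/(mu+psi)) and ancestor-descendant sampling probabilities from
    per-stage FBD posterior draws; counts sampled-ancestor support and
    summarizes per-branch rate multipliers over posterior tree samples;
    estimates per-interval sampling probabilities with the three-timer
    method and moment-matches a Beta prior for the FBD sampling rate.
    Includes generators for every input format with machine-readable
    ground truth, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
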