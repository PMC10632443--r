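Package: ecoreact
Title: Reactivity and Stability of Complex Ecological Communities
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random-matrix theory of reactivity (transient amplification of
    perturbations) in large ecological communities. Provides generators for
    random, mixed-interaction, cascade and niche community matrices with
    homogeneous or heterogeneous self-regulation; exact reactivity and
    stability computation from the community matrix; analytic reactivity
    criteria for the main interaction types and for mixed communities;
    critical curves, phase diagrams, and the normalised distance between the
    reactivity and instability transitions; and a generalized Lotka-Volterra
    simulator with pulse-perturbation schedules, extinction detection, and a
    frequent-perturbation species-loss experiment. Includes a small pipeline
    for reactivity analysis of empirically inferred Lotka-Volterra parameter
    sets and a fixture generator for few-species test communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
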