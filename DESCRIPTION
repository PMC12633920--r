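Package: prosoceq
Title: Agent-Based Simulation of Religiosity, Security and Prosocial Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A demographic microsimulation of the prosocial-equilibrium account
    of religiosity: agents accumulate insecurity from external threats, anxiety
    (insecurity times sensitivity) interacts with religiosity to trigger costly
    prosocial behaviour that relieves insecurity and reinforces religiosity in
    the young, while marriage, reproduction, wellbeing and mortality drive the
    population. Includes a secular central-institution extension, a reference
    model calibration routine, a Latin-hypercube experiment driver with
    trajectory classification (dying/surviving/thriving, religiosity trends),
    and an observed-minus-expected range-based sensitivity assessor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    parallel,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
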