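Package: plastevol
Title: Individual-Based Simulation of Coevolving Reversible Plasticity
    and Life History
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-based eco-evolutionary simulator in which a
    reversible-plasticity gene (the schedule by which individuals update
    their phenotype towards a fluctuating environmental optimum) coevolves
    with a reproductive-effort gene in a fixed-size population with
    overlapping generations. The environment follows an AR(1) process, or
    an ARMA(2,1) process constructed to decouple autocorrelation from total
    variance. Phenotype-environment mismatch reduces fecundity and raises
    mortality, updating carries a fecundity cost, and reproductive effort
    trades off against survival, so lifespan, plasticity and effort emerge
    jointly. Includes summary statistics (lifespan proxy, evolved gene
    values, mismatch~age senescence slope), cross-run pattern tests,
    robustness-variant switches, a scenario-sweep driver and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
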