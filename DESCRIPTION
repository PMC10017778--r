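Package: senopbk
Title: Physiologically Based Kinetic Modelling of Senecionine N-Oxide and
    Senecionine in Rat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based kinetic (PBK) modelling of oral dosing of
    the pyrrolizidine alkaloid senecionine (SEN) and its N-oxide (SENO) in
    rat.  Simulates gastrointestinal uptake, microbial N-oxide reduction,
    hepatic reduction and clearance, and glutathione scavenging of the
    reactive pyrrole intermediate (7-GS-DHP formation, tracked as an
    observer flux that does not disturb the mass balance).  Fits the
    first-order in vitro catalytic efficiency of 7-GS-DHP formation from
    liver S9 incubation data and scales it to an in vivo clearance.
    Computes relative potency (REP) values of the N-oxide by two endpoints
    (AUC of the parent alkaloid; amount of pyrrole-protein adducts), with a
    dose-dependent residual conjugation capacity mimicking glutathione
    depletion, fraction-bioactivated and dose scans, and local normalized
    sensitivity coefficients.  Includes a synthetic-data generator for
    incubation tables and in vivo-like profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
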