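Package: crypticfold
Title: Reconciling Unfolding and Hydrogen-Exchange Free Energies and
    Predicting Cryptic Unfolding Intermediates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A four-stage pipeline for proteins studied by both equilibrium
    denaturation and native-state hydrogen/deuterium (H/D) exchange.  Stage
    one computes intrinsic (random-coil) amide exchange rates from sequence
    context and solution conditions, and converts measured EX2 exchange
    rates into residue-specific free energies of exchange and protection
    factors.  Stage two corrects the global free energy of exchange for
    cis-trans proline isomerization in the unfolded state.  Stage three
    fits equilibrium melting curves to a two-state model with linear,
    exponential or polynomial pre- and post-transition baselines.  Stage
    four clusters hydrogen-bonded amides in regular secondary structure
    with a 7 Angstrom backbone-nitrogen contact-order matrix to predict
    cryptic unfolding intermediates, or, when a single cluster results,
    searches for higher-energy metastable states above a free-energy
    threshold.  Includes generators for fully synthetic test inputs
    (ideal helices and sheets, melting curves, exchange tables).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
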