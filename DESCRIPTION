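Package: trpgating
Title: Semi-Markov Gating Models for Thermosensitive TRP Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and fitting of two- and three-state alternating-renewal
    (semi-Markov) gating models for temperature-sensitive TRP ion channels such
    as TRPV1 (heat-activated) and TRPM8 (cold-activated). Provides residence
    (dwell) time distribution families with densities, survival functions,
    hazards and Laplace transforms; Eyring-form temperature- and
    voltage-dependent rate constants; the gating free-energy asymmetry
    epsilon(T) = dH - T*dS + R*T*log(1 + k_c1*tau_r) with its memory
    correction; stochastic trajectory simulation with seeded reproducibility;
    occupancy curves by Monte Carlo, by closed-form master equation and by
    numerical inversion of the Laplace-domain generalized master equation;
    Tauberian long-time tail classification for heavy-tailed dwell laws;
    conductance-voltage (Boltzmann) and conductance-temperature (van't Hoff)
    analysis including Q10; maximum-likelihood dwell-law fitting, equilibrium
    model fitting with identifiability accounting, and AIC-based model
    comparison; plus a synthetic-data generator emulating TRPV1-like and
    TRPM8-like conductance-temperature-voltage datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
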