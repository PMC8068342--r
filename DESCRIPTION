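Package: mcdamage
Title: Monte Carlo Simulation of Clustered DNA Damage, Radical Scavenging,
    Oxygen Effect and Excision-Repair Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates track-induced clustered DNA lesions on short genomic
    segments, classifies each cluster into the standard damage taxonomy
    (base damage, single-strand break classes, double-strand break classes
    using the 10 base-pair opposition rule), and tallies absolute yields per
    Gy per Gbp with Monte Carlo standard errors.  Per-lesion survival models
    for dimethylsulfoxide (DMSO) radical scavenging (non-scavengeable
    fraction and half-effect concentration) and for oxygen tension (a
    hyperbolic dose-modification factor normalised at 21% O2) act on lesion
    populations by Bernoulli thinning before classification, so the
    quasi-quadratic response of complex damage emerges from clustering.  A
    central fitting function calibrates the cluster-generation parameters to
    reference baseline yield tables; fitted models support simulation and
    prediction of yields under any DMSO/oxygen condition, relative
    biological effectiveness (RBE) and oxygen enhancement ratio (OER)
    endpoints, dose-weighted spectral averaging over secondary-electron
    fluence spectra, and a Monte Carlo excision-repair simulator (short- and
    long-patch base excision repair and nucleotide excision repair hybrids)
    reporting mutation frequency per Gy per cell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
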