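Package: cardiopd
Title: Pharmacodynamic Analysis of Perfused Insect-Heart Recordings
Version: 0.1.0
Authors@R:
    person("cardiopd", "maintainers", email = "cardiopd@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing chronotropic drug effects in semi-isolated
    insect-heart perfusion bioassays. Converts densitometric traces to beat
    times and per-minute contraction frequencies, normalises recordings to
    percent change from the first-minute baseline, and computes the standard
    per-recording pharmacodynamic summaries (slope coefficient, maximal
    effect, time to half-maximal effect t50, half-recovery time RT50).
    Fits Hill/four-parameter logistic dose-response curves (IC50, EC75)
    and quantifies two-compound interactions with the toxic index (TI) and
    toxic units (TU), classifying mixtures as additive, antagonistic or
    synergistic. A seeded simulator generates perfusion protocols, effect
    kinetics, frequency series and raw beat traces so every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
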