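Package: apcsim
Title: Simulation and Signal Processing for a Gravity-Fed Optical Larva Counter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and signal-processing toolkit for an automated
    particle counter of the kind used to count and dispense first-instar mosquito
    larvae: gravity-fed capillary hydraulics, Poisson larva arrivals, synthetic
    light-intensity sensor traces with noise, drift and contaminants, three
    streaming counting algorithms (smoothed z-score thresholding, threshold-reset
    and refractory-period detection), a closed-loop dispensing controller with
    dead-segment carryover between runs, and the evaluation statistics used to
    characterise dispensing accuracy and precision (percent-error summaries,
    one-way ANOVA with Tukey HSD letters from group summaries, rate-accuracy
    correlation, and related worked-example calculators).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
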