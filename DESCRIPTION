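Package: lodsim
Title: Aging-Population Simulation of Polygenic Late-Onset Disease Risk and
    GWAS Discovery Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time simulation of an aging population carrying fixed
    polygenic risk scores for late-onset diseases. Individuals are diagnosed
    year by year with probability proportional to their hazard-converted
    polygenic odds, so risk-allele frequencies diverge between accumulating
    cases and the shrinking unaffected pool. The package builds discretized
    genetic architectures on a liability-scale heritability target, models
    yearly disease incidence and mortality (with eight calibrated late-onset
    disease presets), runs individual-values and age-matched cohort analyses,
    and converts the resulting case/control allele-frequency differences into
    non-centrality-based GWAS discovery power and cases-needed-for-80%-power
    estimates. Brute-force reference implementations and closed-form oracles
    are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
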