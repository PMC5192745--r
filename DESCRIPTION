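Package: hetfit
Title: Heterozygosity-Fitness Correlations and Identity Disequilibrium in Wild Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-based heterozygosity-fitness correlation (HFC)
    analyses of interannual local recruitment in wild populations genotyped at
    microsatellite loci. Implements per-locus diversity statistics with Monte
    Carlo Hardy-Weinberg and linkage-disequilibrium tests, homozygosity by
    locus (HL) and single-locus heterozygosity indices, the g2 estimator of
    identity disequilibrium with a permutation test, AICc-based multimodel
    inference for binomial mixed models (model averaging with unconditional
    standard errors), single-locus scans with sequential Bonferroni
    correction, selection differentials on heterozygosity and their
    regression on environmental-harshness metrics, and a synthetic-data
    generator with known inbreeding structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
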