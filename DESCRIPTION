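Package: famhet
Title: Family- and Population-Based GWAS Under Heterogeneous Allelic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, estimation and closed-form prediction tools for
    studying what family-based and population-based genome-wide association
    study (GWAS) designs estimate when allelic effects are heterogeneous
    across families, for example through gene-by-environment interaction or
    population differences in linkage disequilibrium. Provides generators for
    trio and sibling cohorts with Mendelian segregation, structured allele
    frequencies and environment-linked effect sizes; OLS estimators for
    population, trio, sibling-difference and polygenic-score designs with
    heteroskedasticity-robust standard errors; exact-enumeration and
    closed-form predictions (allele-flip effects, complier average effects in
    children of heterozygous parents, polygenic-score slope theory and the
    within/between-family variance decomposition); and scripted experiments
    verifying each prediction against simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
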