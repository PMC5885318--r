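Package: phewaspower
Title: Power and Type I Error Simulation for Phenome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo power and Type I error estimation for phenome-wide
    association studies (PheWAS). Simulates biallelic SNP genotypes under
    Hardy-Weinberg equilibrium, maps them to binary case/control status or
    quantitative traits through additive penetrance functions, runs additive
    single-SNP logistic and linear regression batteries over parameter grids
    (case counts, case:control ratios, minor allele frequency, penetrance,
    sample size), and tabulates power and Type I error at Bonferroni-style
    significance thresholds. Includes a closed-form oracle for quantitative
    power, PLINK ped/map export, and an electronic-health-record phenotyping
    toolkit implementing the "three or more independent visits" ICD-9 case
    definition with a synthetic longitudinal record generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
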