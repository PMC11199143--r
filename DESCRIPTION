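Package: driftherit
Title: Heritability of Polygenic Traits Under Bottlenecks, Migration and
    Growth
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation pipeline for studying how population bottlenecks,
    migration and post-founding growth reshape the heritability and genetic
    architecture of a polygenic trait. Genotypes for a two-population split
    demography are generated with the msprime coalescent simulator under the
    infinite-sites model; a frequency-coupled trait architecture is overlaid
    in the reference population, environmental variance is calibrated to a
    target heritability, and heritability is re-evaluated in the bottlenecked
    population. Includes a GWAS-detectability thresholding analysis (variance
    explained or association p-values with pooled quantile thresholds),
    empirical bootstrap confidence intervals, Fisher-z correlation standard
    errors, sweep orchestration over demographic parameters, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the msprime (>= 1.0) and numpy
    modules available on the PATH as 'python'.
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
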