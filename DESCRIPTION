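Package: SNPclassify
Title: Two-Population Classification from Biallelic SNP Genotype Frequencies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Likelihood-ratio assignment of individuals to one of two
    populations from a small panel of biallelic SNP markers. Each marker's
    genotype is modelled as a single draw from a trinomial distribution over
    the two homozygotes and the heterozygote, markers are assumed free of
    linkage disequilibrium, and a sample is assigned to the population whose
    genotype-frequency model gives its profile the higher likelihood (with an
    optional population-size-weighted expected-count rule). Includes
    per-marker summary statistics (allele frequencies, MAF, observed
    heterozygosity, exact and chi-square Hardy-Weinberg tests), exact
    classification power by exhaustive enumeration of genotype vectors,
    Monte-Carlo power estimation, synthetic genotype simulation and frequency
    estimation, TSV/VCF input, a packaged eight-marker example panel, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), vcfR, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'SNPclassify-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'markers.R'
    'hwe.R'
    'classify.R'
    'evaluate.R'
    'simdata.R'
    'io.R'
    'vcf.R'
    'examplePanel.R'
    'cli.R'
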