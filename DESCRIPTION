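Package: tadrive
Title: Genotype-to-Phenotype Models for CRISPR Toxin-Antidote Gene Drives
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic models of CRISPR toxin-antidote
    gene drives (TADE modification, TADE suppression and TARE systems) as
    studied in Drosophila melanogaster split-drive crosses.  Provides a
    dosage-based viability model for haplolethal and haplosufficient target
    genes, exact enumeration of gamete and offspring genotype distributions
    for single crosses (germline cutting, maternal Cas9/gRNA deposition,
    homology-directed repair to functional resistance alleles, leaky somatic
    expression), closed-form and maximum-likelihood inference of germline
    and embryo cut rates from vial-structured egg-to-adult viability counts
    (binomial and beta-binomial likelihoods, profile-likelihood intervals,
    exact binomial and Fisher tests), discrete-generation forward simulation
    of drive allele dynamics with introduction-threshold search, a synthetic
    vial-count data generator with batch effects, and a command-line
    interface tying the pieces into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
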