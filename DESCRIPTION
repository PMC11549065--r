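Package: ckmrseal
Title: Close-Kin Mark-Recapture for Age-Structured, Lethally Sampled Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Close-kin mark-recapture (CKMR) estimation of abundance and
    demographic parameters from harvested (lethally sampled) animals, built
    around the bearded seal monitoring problem. Provides an age-structured
    demographic model with reduced additive Weibull ("bathtub") survival,
    pairwise kinship probability kernels for parent-offspring, maternal and
    paternal half-sibling, and grandparent-grandchild pairs (with
    mitochondrial-haplotype conditioning and persistent heterogeneity in male
    breeding success), a penalised joint pseudo-likelihood fitted by
    quasi-Newton optimisation, pseudo-log-odds (PLOD) kin identification from
    SNP panels with heritable null alleles, quality control for such panels,
    an individual-based pedigree and genotype simulator for power analysis
    and validation, and reproductions of the associated tabular statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
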