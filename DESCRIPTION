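Package: antagmap
Title: Brain-Structural Characterization of Antagonistic Cross-Disorder SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize single-nucleotide polymorphisms with
    antagonistic effects across neuropsychiatric disorders (the same allele
    raising risk for one disorder while protecting against another) at the
    level of brain structure. Implements a SNP-to-image-derived-phenotype
    association scan over GWAS summary statistics with allele harmonization,
    LD-proxy substitution and grid-wide Benjamini-Hochberg FDR control; a
    bootstrap enrichment test against randomly sampled SNP sets; a
    three-source effect-direction concordance analysis combining SNP-to-IDP,
    SNP-to-disorder and patient-versus-control effects; eQTL and
    trait-association annotation filters; and a voxel-wise general linear
    model for gray-matter volume with cluster-extent thresholds and
    permutation-based peak-level family-wise-error correction. A synthetic
    data module generates all required inputs with known ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
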