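Package: breedscan
Title: Cross-Breed Stereotype GWAS, Selection Scans and Haplotype Fine-Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping breed-average (stereotype) behavioral traits in
    structured dog populations. Implements single-SNP association with a
    univariate linear mixed model using a centered genetic relatedness matrix
    and likelihood-ratio tests; Hudson pairwise FST with the windowed
    di (differentiation) and si (reduced-heterozygosity) selection statistics;
    direct haplotype phasing of homozygous carriers around association peaks
    with cross-breed maximum/minimum map-interval fine-mapping; and a
    no-intercept stepwise regression of breed allele frequencies for
    predicting stereotypes of unseen breeds, evaluated by a success/failure
    matrix against a permutation null. A breed-structured genotype simulator
    (Balding-Nichols divergence with planted selective sweeps) supports
    end-to-end testing, and PLINK PED/MAP and TPED/TFAM text formats are read
    and written natively.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
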