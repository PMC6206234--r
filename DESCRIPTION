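Package: ccsnp
Title: Case-Control SNP Association Analysis with Haplotype EM and FPRP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multi-SNP case-control genetic
    association studies: Hardy-Weinberg equilibrium quality control in
    controls, odds-ratio contrasts under the standard genetic models
    (heterozygote, homozygote, dominant, recessive, additive),
    covariate-adjusted logistic regression, combined protective-genotype
    scoring, stratified analysis, false-positive report probability (FPRP)
    with detection power, and EM estimation of multi-locus haplotype
    frequencies from unphased genotypes with haplotype-level association
    against a reference haplotype. Includes a seeded synthetic-cohort
    generator with haplotype-level linkage disequilibrium and logistic
    disease effects that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
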