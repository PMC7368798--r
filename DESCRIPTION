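Package: pedseg
Title: Pedigree-Aware Segregation Filtering of Sequencing Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Family-structure-aware prioritization of candidate variants from
    multi-sample VCF files: trio, sibship and incremental extended-family
    segregation filtering under recessive-homozygous and de novo models, with
    the site-level filters used in clinical rare-disease analysis (depth >= 20,
    population allele frequency < 1.5 percent, PASS-only) and hemizygous
    handling of the male X chromosome. Includes a consanguineous-pedigree
    genome simulator (first-cousin mating loop with founder-allele tracking,
    family-enriched alleles, genotyping error, depth simulation and a planted
    recessive causal variant) so the whole analysis is exercisable end-to-end
    on synthetic cohorts, plus Table-style reduction-curve reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
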