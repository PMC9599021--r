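Package: phenodiv
Title: Phenolic Assay Quantification and SSR Diversity Analysis for Berry Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint biochemical and genetic characterisation of
    berry germplasm collections. Converts raw spectrophotometric absorbance
    readings into concentration units for five colorimetric assays (total
    phenolics by Folin-Ciocalteau, total flavonoids, monomeric anthocyanins by
    the pH-differential method, and FRAP/ABTS antioxidant capacity), computes
    genotype-level statistics with one-way ANOVA, Duncan's multiple range test
    and compact-letter displays, and Pearson correlation matrices. For diploid
    microsatellite (SSR) genotypes it computes per-locus diversity statistics
    (allele counts, expected and observed heterozygosity, polymorphic
    information content), genetic and biochemical distance matrices, UPGMA
    dendrograms with Newick export, and the Mantel permutation test linking
    the two domains. A synthetic-data generator reproduces the statistical
    structure of a replicated germplasm trial so the whole pipeline can be
    exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, ape, jsonlite
Suggests: testthat (>= 3.0.0), vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
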