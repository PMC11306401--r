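Package: rvburden
Title: Rare-Variant Burden Testing and Single-Cell Polygenic Burden Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Case-control rare-variant analysis for exome studies of complex
    eye disease: qualifying-variant classification (protein-truncating,
    damaging and benign missense, synonymous), variant- and sample-level
    quality control including an exact Hardy-Weinberg test and sex inference
    from X-chromosome heterozygosity, ancestry principal components with
    nearest-neighbour control matching, Fisher's exact and Firth
    penalized-logistic burden tests at the gene, gene-set and exome level
    with permutation and length-matched resampling nulls, and a single-cell
    polygenic burden score (scPBS) that maps case-control rare-variant burden
    onto individual cells of an scRNA-seq dataset, producing a per-cell
    rare-variant trait-relevance score (rvTRS). Includes a synthetic-data
    generator producing coupled genotype/phenotype and single-cell expression
    fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
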