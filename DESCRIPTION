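Package: finescale
Title: Fine-Scale Beta Diversity of Replicate Amplicon Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fine-scale (millimeter) beta diversity in
    replicate 16S rRNA amplicon surveys. Provides read quality filtering,
    OTU count-table input/output (plain TSV and mothur shared dialects),
    nine qualitative and quantitative pairwise similarity indices (Anderberg,
    Jaccard, Sorensen, Ochiai, Bray-Curtis, Chao abundance-based Jaccard and
    Sorensen, Smith theta, Yue-Clayton theta), multi-sample shared-OTU (Venn)
    accounting, rare/abundant partitioning at count and proportion cutoffs,
    sequence-identity sub-classification of the rare biosphere into
    non-unique non-novel, unique non-novel and unique novel members, a
    mixture-of-two-exponentials mixed-Poisson richness model with a
    shared-singleton null prediction, subsampling tests of spatial
    separation, likelihood-ratio chi-squared tests of phylum composition,
    rarefaction, and a synthetic community generator with planted structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
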