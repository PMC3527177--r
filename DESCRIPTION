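Package: snpstacks
Title: Genome-Wide SNP Discovery from Read Stacks in Heterozygous Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers single-nucleotide polymorphisms in a single
    heterozygous (outcrossing) individual by mapping deep short-read
    coverage onto shallow long-read reference sequences such as BAC end
    sequences. Implements variant-frequency and folded-variant-frequency
    statistics on per-site read stacks, a t-test for deviation of the
    folded variant frequency from the heterozygous expectation of 0.5,
    extreme-value (Gumbel) modelling of read mapping depth to derive a
    repeat-exclusion depth cutoff, a multi-criterion SNP filter cascade,
    Infinium I/II assay typing and panel selection, genotyping-based
    validation with segregation classification and a logistic
    true-positive classifier, and pedigree analytics (coefficient of
    parentage, heterozygosity, pairwise dissimilarity). A synthetic-data
    generator provides known-truth references, pileups, crosses and
    pedigrees so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
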