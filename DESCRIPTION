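Package: xhsd
Title: Maximum-Parsimony Haplotype Phasing from Xor-Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers haplotype pairs for a population of unrelated individuals
    from xor-genotypes (per-site heterozygosity indicators, as produced by
    assays such as DHPLC) under the maximum parsimony principle.  The core is
    a greedy sparse dictionary selection over the set of compatible
    haplotypes, with optional augmentation by a small number of regular
    genotypes selected by a minimal empty-intersection (MTI-style) search to
    resolve the bit-flip degree of freedom.  Long sequences are handled by
    entropy-minimizing block partitioning and ligation; missing sites and
    typing errors are supported.  Includes a synthetic-population simulator,
    phasing accuracy metrics (switch error rate, homozygous prediction error,
    pair error, haplotype diversity ratio), plain-text data formats and a
    phased VCF export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
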