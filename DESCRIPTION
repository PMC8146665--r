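Package: haplosignal
Title: Haplotype-Level Selection Signals at Candidate Insecticide-Resistance Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise haplotype structure and selection signals
    around a candidate gene from phased diploid genotypes: a minimal
    protein-effect annotator with per-population allele frequencies,
    Hamming-distance hierarchical clustering of haplotypes, signed Lewontin's
    D' linkage disequilibrium, median-joining haplotype networks with an
    edge-distance component filter, and extended haplotype homozygosity (EHH)
    decay around a core region. A forward-time Wright-Fisher simulator with
    recombination, mutation, optional positive selection and bottlenecks
    provides fully reproducible synthetic cohorts, so the whole pipeline runs
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    vcfR,
    igraph,
    Biostrings,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
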