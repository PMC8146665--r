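#!/usr/bin/env Rscript
# Hamming-distance hierarchical clustering of the gene-region haplotypes,
# cut at seven SNPs; per-population cluster frequencies and the signature
# variants of each cluster.

suppressMessages(library(haplosignal))
gene <- region("3R", 6928858, 6930547)

panel <- read_panel("results/panel.tsv")
hapset <- read_phased_vcf("results/cohort.vcf.gz",
                          region("3R", 1, gene$end + 300000), panel)

d <- hamming_matrix(hapset, gene)
clusters <- hierarchical_clusters(d, cut_height = 7, min_cluster_freq = 0.01)
print(clusters)

write_tsv_table(tibble::tibble(haplotype_id = hapset$meta$haplotype_id,
                               population = hapset$meta$population,
                               cluster = clusters$labels),
                "results/clusters.tsv")
write_tsv_table(cluster_population_summary(clusters, hapset),
                "results/cluster_population_summary.tsv")

hifreq <- utils::read.table("results/high_frequency_missense.tsv",
                            header = TRUE, sep = "\t")
if (nrow(hifreq)) {
  sig <- cluster_signature_variants(clusters, hapset,
                                    hapset$sites[hapset$sites$pos %in% hifreq$pos, ])
  write_tsv_table(sig, "results/cluster_signatures.tsv")
  message(sprintf("%d cluster x variant signature flags written",
                  sum(sig$signature)))
}
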