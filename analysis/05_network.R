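#!/usr/bin/env Rscript
# Median-joining network of the gene-region haplotypes, connected
# components at a maximum edge distance of two SNPs, and concordance with
# the hierarchical clusters.

suppressMessages(library(haplosignal))
gene <- region("3R", 6928858, 6930547)

panel <- read_panel("results/panel.tsv")
hapset <- read_phased_vcf("results/cohort.vcf.gz",
                          region("3R", 1, gene$end + 300000), panel)
gene_set <- subset_region(hapset, gene)

net <- median_join(gene_set)
print(net)
write_network(net, "results/network.graphml", "graphml")
write_network(net, "results/network.dot", "dot")

comp <- components_by_edge_filter(net, max_edge = 2)
clusters <- hierarchical_clusters(hamming_matrix(hapset, gene),
                                  cut_height = 7, min_cluster_freq = 0.01)
conc <- concordance(comp, clusters)
write_tsv_table(tibble::tibble(haplotype_id = hapset$meta$haplotype_id,
                               component = comp$hap_component,
                               cluster = clusters$labels),
                "results/network_components.tsv")
message(sprintf("%d components at max edge 2; concordance with clusters %.1f%%",
                length(unique(comp$node_component)), 100 * conc))
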