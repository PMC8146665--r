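#!/usr/bin/env Rscript
# Annotate coding variants in the focal gene, tabulate per-cohort allele
# frequencies and keep those above 5% in at least one cohort.

suppressMessages(library(haplosignal))
gene <- region("3R", 6928858, 6930547)
seed <- 20260930L

panel <- read_panel("results/panel.tsv")
hapset <- read_phased_vcf("results/cohort.vcf.gz",
                          region("3R", 1, gene$end + 300000), panel)
gene_set <- subset_region(hapset, gene)

model <- plant_gene_model(gene, "+", seed = seed, sites = hapset$sites)
eff <- annotate_variants(model, gene_set$sites)
freqs <- population_allele_frequencies(gene_set, panel)
freqs$effect_class <- eff$effect_class
freqs$label <- eff$label
hifreq <- filter_high_frequency(freqs, 0.05)
hifreq_mis <- hifreq[hifreq$effect_class == "missense", ]

write_tsv_table(eff, "results/effects.tsv")
write_tsv_table(format_frequency_table(freqs), "results/frequencies.tsv")
write_tsv_table(format_frequency_table(hifreq_mis),
                "results/high_frequency_missense.tsv")

message(sprintf("%d gene sites: %d missense, %d synonymous, %d other",
                nrow(eff), sum(eff$effect_class == "missense"),
                sum(eff$effect_class == "synonymous"),
                sum(!eff$effect_class %in% c("missense", "synonymous"))))
message(sprintf("%d variants exceed 5%% in at least one cohort (%d missense)",
                nrow(hifreq), nrow(hifreq_mis)))
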