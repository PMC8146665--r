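#!/usr/bin/env Rscript
# EHH decay around the core region, per population cohort, with decay
# areas per core-haplotype group.

suppressMessages(library(haplosignal))
core <- region("3R", 6928858, 6930547)

panel <- read_panel("results/panel.tsv")
hapset <- read_phased_vcf("results/cohort.vcf.gz",
                          region("3R", 1, core$end + 300000), panel)

ehh <- ehh_by_population(hapset, core, min_core_freq = 0.01,
                         max_distance = 200000)
write_tsv_table(ehh$curves, "results/ehh_curves.tsv")
write_tsv_table(ehh$groups, "results/ehh_group_areas.tsv")

for (pop in unique(ehh$groups$population)) {
  g <- ehh$groups[ehh$groups$population == pop, ]
  top <- g[which.max(g$area), ]
  message(sprintf("%s: %d core groups; slowest decay %s (n = %d, area %.0f bp)",
                  pop, nrow(g), top$group, top$n, top$area))
}
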