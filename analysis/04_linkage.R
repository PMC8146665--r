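#!/usr/bin/env Rscript
# Signed Lewontin's D' between the retained missense variants, pooled and
# stratified by population: associations that vanish within every stratum
# are artefacts of population structure, not physical linkage.

suppressMessages(library(haplosignal))
gene <- region("3R", 6928858, 6930547)

panel <- read_panel("results/panel.tsv")
hapset <- read_phased_vcf("results/cohort.vcf.gz",
                          region("3R", 1, gene$end + 300000), panel)
hifreq <- utils::read.table("results/high_frequency_missense.tsv",
                            header = TRUE, sep = "\t")
vars <- hapset$sites[hapset$sites$pos %in% hifreq$pos, ]
stopifnot(nrow(vars) >= 2)

pooled <- dprime_matrix(hapset, vars)
write_ld_matrix(pooled, "results/dprime_pooled.tsv")
for (pop in unique(panel$population)) {
  strat <- stratified_dprime(hapset, vars, pop)
  write_ld_matrix(strat, sprintf("results/dprime_%s.tsv", pop))
  message(sprintf("%s: %d of %d pairs undefined within the stratum", pop,
                  sum(is.na(strat$dprime[upper.tri(strat$dprime)])),
                  sum(upper.tri(strat$dprime))))
}
off <- pooled$dprime[upper.tri(pooled$dprime)]
message(sprintf("pooled |D'|: median %.2f, %d pairs at |D'| = 1",
                stats::median(abs(off), na.rm = TRUE),
                sum(abs(off) == 1, na.rm = TRUE)))
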