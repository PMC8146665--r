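#!/usr/bin/env Rscript
# Simulate the study cohort: two demes with contrasting demography — a
# diverse deme carrying a selected focal allele and a bottlenecked neutral
# deme — and write the phased VCF, sample panel and truth records.

suppressMessages(library(haplosignal))
dir.create("results", showWarnings = FALSE)

lat <- default_site_lattice()
fs <- which.min(abs(lat$pos - 6929700))
seed <- 20260930L

sims <- list(
  sim_config(n_pop = 100, n_founders = 20, sites = lat, generations = 20,
             s = 0.3, focal_site = fs, seed = seed,
             pop_label = "AO", species_label = "coluzzii"),
  sim_config(n_pop = 100, n_founders = 20, sites = lat, generations = 20,
             seed = seed + 1, pop_label = "KE", species_label = "gambiae",
             bottleneck = list(generation = 5, size = 10, duration = 10)))

runs <- lapply(sims, simulate_population)
hapset <- bind_hapsets(lapply(runs, `[[`, "hapset"))
panel <- do.call(rbind, lapply(runs, `[[`, "panel"))

write_phased_vcf(hapset, "results/cohort.vcf.gz")
write_panel(panel, "results/panel.tsv")
write_sim_truth(runs[[1]]$truth, "results/truth_AO")

traj <- runs[[1]]$truth$trajectory
message(sprintf("simulated %d haplotypes over %d sites", ncol(hapset$matrix),
                nrow(hapset$sites)))
message(sprintf("focal allele in AO: %.3f -> %.3f over %d generations",
                traj[1], traj[length(traj)], length(traj) - 1L))
message("wrote results/cohort.vcf.gz, results/panel.tsv, results/truth_AO/")
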