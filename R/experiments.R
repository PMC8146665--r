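#' Standard study conditions for the sweep-recovery experiment
#'
#' The reference parameterisation used by the packaged simulation
#' experiments: 200 diploids, 20 founder haplotypes, a 144-site lattice
#' (60 sites per 200 kb flank, 24 inside the gene), scaled per-generation
#' rates mu = 1e-5 and r = 1e-6 per base, a 200-generation neutral burn-in,
#' then 12 generations with the focal allele planted on the standing
#' core-haplotype class nearest 6% frequency. The planting frequency and
#' epoch length were calibrated together so that the survival conditioning
#' is almost always satisfied — a strongly selective conditioning would
#' bias the carrier class young and decalibrate the neutral comparison.
#' The selection coefficient is the only knob the two arms of the contrast
#' differ in.
#'
#' @param s selection coefficient for the second phase.
#' @param seed replicate seed.
#' @return A list with the [sim_config()] and the experiment constants
#'   (`burn_in`, `core`, `gene`, `target_freq`).
#' @export
recovery_conditions <- function(s = 0, seed = 1L) {
  gene <- region("3R", 6928858, 6930547)
  sites <- default_site_lattice(gene, flank_bp = 200000,
                                n_flank = 60, n_gene = 24)
  focal <- which.min(abs(sites$pos - (gene$start + gene$end) %/% 2))
  list(config = sim_config(n_pop = 200L, n_founders = 20L, sites = sites,
                           mu = 1e-5, r = 1e-6, generations = 12L, s = s,
                           focal_site = focal, seed = seed),
       burn_in = 200L, core = gene, gene = gene, target_freq = 0.06)
}

#' Sweep-recovery experiment: carrier EHH dominance across replicates
#'
#' Runs replicate two-phase simulations under the standard study
#' conditions ([recovery_conditions()]) and, per replicate, compares the
#' focal-carrier core group's EHH decay area with the wild-type core
#' groups' ([carrier_area_contrast()]). The reported win is against the
#' size-matched wild-type group: because the carrier class is planted as a
#' standing core-haplotype class, under neutrality it is exchangeable with
#' any wild-type class of its size and the expected win rate is one half,
#' while a selective sweep lifts it far above that. The win against every
#' wild-type group regardless of size is also reported; that comparison is
#' dominated by the youngest (hence smallest) neutral clades and is not
#' frequency-fair.
#'
#' @param s selection coefficient (0.2 for the sweep arm, 0 for the null).
#' @param n_reps number of surviving replicates.
#' @param seed base seed; replicate `i` uses `seed + (i - 1) * 1000`.
#' @return A tibble with one row per replicate: the areas, win indicators
#'   (`win_matched`, `win_all`, ties scored 0.5), starting and final focal
#'   frequencies.
#' @export
sweep_recovery_experiment <- function(s, n_reps = 20L, seed = 1L) {
  rows <- lapply(seq_len(n_reps), function(i) {
    cond <- recovery_conditions(s = s, seed = seed + (i - 1L) * 1000L)
    sim <- suppressMessages(
      simulate_two_phase(cond$config, burn_in = cond$burn_in,
                         plant = "standing", core = cond$core,
                         target_freq = cond$target_freq))
    areas <- ehh_group_areas(sim$hapset, cond$core,
                             carrier = sim$truth$carrier)
    cbind(tibble::tibble(rep = i),
          carrier_area_contrast(areas),
          tibble::tibble(
            start_freq = attr(sim, "start_freq"),
            final_freq = sim$truth$trajectory[length(sim$truth$trajectory)]))
  })
  do.call(rbind, rows)
}

#' Bottleneck-confound experiment: wild-type EHH under demography alone
#'
#' Pairs of neutral cohorts at matched parameters, one passed through a
#' bottleneck epoch, one of constant size. For each replicate the mean EHH
#' decay area over the cohort's core-haplotype groups is recorded; the
#' bottlenecked cohorts' longer shared haplotypes mimic a sweep signal
#' without any selection — the confound that makes demographic context
#' essential when reading EHH curves.
#'
#' The default is a severe recent bottleneck: the cohort drops to 5% of
#' its size for fifteen generations. Two cohort summaries are reported:
#' the unweighted mean over core groups, and the haplotype-weighted mean
#' (the expected EHH area of the group a randomly drawn haplotype belongs
#' to). The weighted summary is the discriminating one — a bottleneck
#' concentrates haplotypes into few large recently-coalesced groups, which
#' raises the area experienced per haplotype, while the per-group mean is
#' diluted by the small young clades every cohort contains.
#'
#' @param n_reps number of replicate pairs.
#' @param seed base seed.
#' @param n_pop diploid cohort size.
#' @param generations generations simulated.
#' @param bottleneck bottleneck epoch for the demographic arm.
#' @return A tibble with columns `rep`, `scenario`
#'   (`bottleneck`/`constant`), `area_per_group` and `area_per_haplotype`.
#' @export
bottleneck_experiment <- function(n_reps = 20L, seed = 1L, n_pop = 100L,
                                  generations = 30L,
                                  bottleneck = list(generation = 10,
                                                    size = 5,
                                                    duration = 15)) {
  gene <- region("3R", 6928858, 6930547)
  sites <- default_site_lattice(gene, n_flank = 60, n_gene = 24)
  rows <- list()
  for (i in seq_len(n_reps)) {
    for (scen in c("bottleneck", "constant")) {
      cfg <- sim_config(n_pop = n_pop, n_founders = 20L, sites = sites,
                        generations = generations,
                        bottleneck = if (scen == "bottleneck") bottleneck,
                        seed = seed + (i - 1L) * 1000L +
                          (scen == "bottleneck") * 500L)
      sim <- simulate_population(cfg)
      areas <- ehh_group_areas(sim$hapset, gene)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = i, scenario = scen,
        area_per_group = mean(areas$area),
        area_per_haplotype = sum(areas$n * areas$area) / sum(areas$n))
    }
  }
  do.call(rbind, rows)
}
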