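small_lattice <- default_site_lattice(n_flank = 15, n_gene = 8)

test_that("simulation is bit-identical given the configuration", {
  cfg <- sim_config(n_pop = 25, n_founders = 8, sites = small_lattice,
                    generations = 10, s = 0.1, focal_site = 20L, seed = 4)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$hapset$matrix, b$hapset$matrix)
  expect_identical(a$truth$trajectory, b$truth$trajectory)
  expect_identical(a$truth$founder_origin, b$truth$founder_origin)
})

test_that("zero generations copies the founders verbatim", {
  cfg <- sim_config(n_pop = 10, n_founders = 5, sites = small_lattice,
                    generations = 0, seed = 2)
  sim <- simulate_population(cfg)
  founders <- sim$truth$founders
  assign <- rep_len(1:5, 20)
  expect_identical(sim$hapset$matrix,
                   matrix(founders[, assign], ncol = 20,
                          dimnames = dimnames(sim$hapset$matrix)))
})

test_that("without mutation, recombination or selection every haplotype is a founder", {
  cfg <- sim_config(n_pop = 15, n_founders = 6, sites = small_lattice,
                    mu = 0, r = 0, generations = 12, seed = 3)
  sim <- simulate_population(cfg)
  fk <- apply(sim$truth$founders, 2, paste0, collapse = "")
  hk <- apply(sim$hapset$matrix, 2, paste0, collapse = "")
  expect_true(all(hk %in% fk))
})

test_that("carrier flags and trajectory match the final matrix", {
  cfg <- sim_config(n_pop = 30, n_founders = 10, sites = small_lattice,
                    generations = 8, s = 0.3, focal_site = 19L, seed = 11)
  sim <- simulate_population(cfg)
  expect_equal(length(sim$truth$trajectory), 9L)
  expect_equal(sim$truth$trajectory[9],
               mean(sim$hapset$matrix[19, ]))
  expect_equal(sim$truth$carrier, unname(sim$hapset$matrix[19, ] == 1L))
})

test_that("neutral drift leaves the mean allele-frequency change near zero", {
  lat <- default_site_lattice(n_flank = 8, n_gene = 4)
  p0 <- 4 / 10
  deltas <- vapply(1:300, function(i) {
    cfg <- sim_config(n_pop = 20, n_founders = 10, sites = lat,
                      generations = 8, focal_site = 10L, focal_founders = 4L,
                      mu = 0, seed = 1000 + i)
    sim <- simulate_population(cfg)
    sim$truth$trajectory[9] - p0
  }, 0)
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 1e-12)
})

test_that("selection drives the focal allele upward relative to neutrality", {
  lat <- default_site_lattice(n_flank = 8, n_gene = 4)
  final_freq <- function(s, seed) {
    cfg <- sim_config(n_pop = 40, n_founders = 8, sites = lat,
                      generations = 15, s = s, focal_site = 10L,
                      focal_founders = 2L, seed = seed)
    simulate_population(cfg)$truth$trajectory[16]
  }
  neutral <- vapply(1:30, function(i) final_freq(0, 300 + i), 0)
  swept <- vapply(1:30, function(i) final_freq(0.4, 300 + i), 0)
  expect_gt(mean(swept), mean(neutral) + 0.15)
})

test_that("bottlenecks reduce mean pairwise Hamming diversity", {
  lat <- default_site_lattice(n_flank = 12, n_gene = 6)
  diversity <- function(bn, seed) {
    cfg <- sim_config(n_pop = 60, n_founders = 20, sites = lat,
                      generations = 20, bottleneck = bn, seed = seed)
    mean(hamming_matrix(simulate_population(cfg)$hapset))
  }
  bn <- list(generation = 5, size = 6, duration = 8)
  res <- vapply(1:12, function(i)
    diversity(bn, 40 + i) < diversity(NULL, 40 + i), TRUE)
  expect_gte(mean(res), 0.9)
})

test_that("the sweep contrast raises carrier identity in most replicates", {
  lat <- default_site_lattice(n_flank = 20, n_gene = 8)
  fs <- 25L
  neutral <- sim_config(n_pop = 60, n_founders = 12, sites = lat,
                        generations = 15, s = 0, focal_site = fs,
                        focal_founders = 1L, seed = 501)
  sweep <- sim_config(n_pop = 60, n_founders = 12, sites = lat,
                      generations = 15, s = 0.4, focal_site = fs,
                      focal_founders = 1L, seed = 501)
  tab <- simulate_sweep_contrast(neutral, sweep, n_reps = 10,
                                 flank_bp = 50000)
  expect_equal(nrow(tab), 20L)
  expect_true(all(tab$carrier_identity >= 0 & tab$carrier_identity <= 1))
  expect_gt(mean(tab$focal_freq[tab$scenario == "sweep"]),
            mean(tab$focal_freq[tab$scenario == "neutral"]))
  # configurations must differ only in s
  other <- sim_config(n_pop = 50, n_founders = 12, sites = lat,
                      generations = 15, s = 0.4, focal_site = fs, seed = 501)
  expect_error(simulate_sweep_contrast(neutral, other, 5), "identical except")
  expect_error(simulate_sweep_contrast(neutral, sweep, 1), "n_reps")
})

test_that("survival conditioning retries deterministically with the next seed", {
  lat <- default_site_lattice(n_flank = 8, n_gene = 4)
  cfg <- sim_config(n_pop = 20, n_founders = 10, sites = lat,
                    generations = 10, s = 0, focal_site = 10L,
                    focal_founders = 1L, seed = 7)
  a <- suppressMessages(simulate_surviving(cfg, min_freq = 0.05))
  b <- suppressMessages(simulate_surviving(cfg, min_freq = 0.05))
  expect_identical(a$hapset$matrix, b$hapset$matrix)
  fq <- a$truth$trajectory[11]
  expect_gte(fq, 0.05)
})

test_that("two-phase runs are deterministic and plant as requested", {
  lat <- default_site_lattice(n_flank = 20, n_gene = 12)
  fs <- which.min(abs(lat$pos - 6929700))
  core <- region("3R", 6928858, 6930547)
  cfg <- sim_config(n_pop = 50, n_founders = 10, sites = lat,
                    generations = 10, s = 0.2, focal_site = fs, seed = 9)
  a <- suppressMessages(simulate_two_phase(cfg, burn_in = 30, core = core,
                                           target_freq = 0.05))
  b <- suppressMessages(simulate_two_phase(cfg, burn_in = 30, core = core,
                                           target_freq = 0.05))
  expect_identical(a$hapset$matrix, b$hapset$matrix)
  expect_gte(attr(a, "start_freq"), 0.02)
  # de novo planting starts from a single copy
  d <- suppressMessages(simulate_two_phase(cfg, burn_in = 30,
                                           plant = "de_novo", core = core))
  expect_equal(attr(d, "start_freq"), 1 / 100)
  expect_gte(d$truth$trajectory[11], 0.01)
})

test_that("panel and truth files round-trip as TSV", {
  cfg <- sim_config(n_pop = 10, n_founders = 4, sites = small_lattice,
                    generations = 3, focal_site = 5L, seed = 21)
  sim <- simulate_population(cfg)
  dir <- withr::local_tempdir()
  write_sim_truth(sim$truth, dir)
  traj <- utils::read.table(file.path(dir, "trajectory.tsv"), header = TRUE)
  expect_equal(traj$focal_freq, sim$truth$trajectory)
  carriers <- utils::read.table(file.path(dir, "carriers.tsv"), header = TRUE)
  expect_equal(carriers$carrier, unname(sim$truth$carrier))
})
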