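test_that("Hamming distances match hand counts and a double-loop oracle", {
  hs <- toy_hapset(cbind(c(1L, 0L, 1L), c(0L, 1L, 1L), c(1L, 0L, 1L), c(0L, 0L, 0L)))
  d <- as.matrix(hamming_matrix(hs))
  expect_equal(d[1, 2], 2)  # 101 vs 011
  expect_equal(d[1, 3], 0)  # identical haplotypes
  expect_equal(d[1, 4], 2)

  set.seed(21)
  mat <- random_hap_matrix(50, 20)
  hs <- toy_hapset(mat)
  expect_equal(unname(as.matrix(hamming_matrix(hs))), oracle_hamming(mat))
  expect_equal(attr(hamming_matrix(hs), "n_sites"), 50L)
})

test_that("restricting the distance region and degenerate inputs error cleanly", {
  hs <- toy_hapset(random_hap_matrix(10, 6), pos = (1:10) * 50L)
  expect_error(hamming_matrix(hs, region("3R", 2000, 3000)), "no sites")
  one <- haplotype_set(hs$sites, hs$matrix[, 1:2, drop = FALSE], hs$meta[1:2, 1:4])
  expect_silent(hamming_matrix(one))
})

test_that("single-linkage cut groups by transitive <=h connectivity", {
  # d(h1,h2)=0, d(.,h3)=10: h1,h2 together, h3 apart at cut 7
  m <- cbind(rep(0L, 10), rep(0L, 10), rep(1L, 10))
  m <- cbind(m, m)[, c(1, 4, 2, 5, 3, 6)]  # 6 haplotypes = 3 pairs
  hs <- toy_hapset(m)
  cl <- hierarchical_clusters(hamming_matrix(hs), cut_height = 7,
                              min_cluster_freq = 0)
  expect_equal(length(unique(cl$labels[1:4])), 1L)
  expect_false(cl$labels[5] == cl$labels[1])

  # chain 5-5 with endpoints at 10 merges fully under single linkage
  chain <- cbind(c(rep(1L, 5), rep(0L, 5)),
                 c(rep(0L, 10)),
                 c(rep(0L, 5), rep(1L, 5)))
  chain <- chain[, c(1, 1, 2, 2, 3, 3)]
  hs2 <- toy_hapset(chain)
  d2 <- as.matrix(hamming_matrix(hs2))
  expect_equal(d2[1, 3], 5); expect_equal(d2[3, 5], 5); expect_equal(d2[1, 5], 10)
  cl2 <- hierarchical_clusters(hamming_matrix(hs2), cut_height = 7,
                               min_cluster_freq = 0)
  expect_equal(length(unique(cl2$labels)), 1L)
  # complete linkage does not chain
  cl3 <- hierarchical_clusters(hamming_matrix(hs2), linkage = "complete",
                               cut_height = 7, min_cluster_freq = 0)
  expect_gt(length(unique(cl3$labels)), 1L)
})

test_that("cut at zero recovers groups of identical haplotypes", {
  set.seed(5)
  mat <- random_hap_matrix(12, 10)[, rep(1:5, 2)]
  hs <- toy_hapset(mat)
  cl <- hierarchical_clusters(hamming_matrix(hs), cut_height = 0,
                              min_cluster_freq = 0)
  key <- apply(mat, 2, paste0, collapse = "")
  expect_equal(length(unique(cl$labels)), length(unique(key)))
  expect_true(all(tapply(cl$labels, key, function(x) length(unique(x))) == 1))
})

test_that("single-linkage components equal threshold-graph components (random)", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(6:16, 1)
    mat <- random_hap_matrix(sample(10:40, 1), 2 * ceiling(n / 2))
    hs <- toy_hapset(mat)
    h <- sample(0:8, 1)
    cl <- hierarchical_clusters(hamming_matrix(hs), cut_height = h,
                                min_cluster_freq = 0)
    oracle <- oracle_threshold_components(oracle_hamming(mat), h)
    # identical partitions up to relabelling
    expect_equal(length(unique(cl$labels)), length(unique(oracle)))
    expect_true(all(tapply(oracle, cl$labels,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("cluster naming orders by size and folds small clusters into wt", {
  # 10 haplotypes: 6 identical, 2 identical, 2 singletons far apart
  base <- matrix(0L, 20, 10)
  base[1:10, 7:8] <- 1L
  base[11:15, 9] <- 1L
  base[16:20, 10] <- 1L
  hs <- toy_hapset(base)
  cl <- hierarchical_clusters(hamming_matrix(hs), cut_height = 2,
                              min_cluster_freq = 0.15)
  expect_equal(cl$labels, c(rep("C1", 6), rep("C2", 2), "wt", "wt"))
  # labels are invariant to haplotype order (same partition after shuffling)
  ord <- c(9, 10, 7, 8, 1, 2, 3, 4, 5, 6)
  hs2 <- toy_hapset(base[, ord])
  cl2 <- hierarchical_clusters(hamming_matrix(hs2), cut_height = 2,
                               min_cluster_freq = 0.15)
  expect_equal(cl2$labels, cl$labels[ord])
})

test_that("population summaries tally cluster proportions exactly", {
  hs <- toy_hapset(random_hap_matrix(5, 8),
                   population = c("AO", "AO", "KE", "KE"))
  cl <- hierarchical_clusters(hamming_matrix(hs), cut_height = 100)
  s <- cluster_population_summary(cl, hs)
  expect_equal(sort(s$population), c("AO_spA", "KE_spA"))
  expect_true(all(abs(rowSums(as.matrix(s[-1])) - 1) < 1e-12))

  set.seed(31)
  mat <- random_hap_matrix(30, 24)
  hs2 <- toy_hapset(mat, population = rep(c("A", "B", "C"), each = 4))
  cl2 <- hierarchical_clusters(hamming_matrix(hs2), cut_height = 10,
                               min_cluster_freq = 0)
  s2 <- cluster_population_summary(cl2, hs2)
  pops <- cohort_label(hs2$meta$population, hs2$meta$species)
  for (i in seq_len(nrow(s2))) for (lab in setdiff(names(s2), "population")) {
    expect_equal(s2[[lab]][i],
                 mean(cl2$labels[pops == s2$population[i]] == lab))
  }
})

test_that("signature variants are the cluster-defining alleles", {
  mat <- matrix(0L, 4, 12)
  mat[1, 1:6] <- 1L          # variant 1 carried by cluster of 6
  mat[2, 7:8] <- 1L          # variant 2 marks a 2-haplotype class -> wt
  hs <- toy_hapset(mat)
  cl <- hierarchical_clusters(hamming_matrix(hs), cut_height = 0,
                              min_cluster_freq = 0.25)
  vars <- hs$sites[1:2, ]
  sig <- cluster_signature_variants(cl, hs, vars)
  c1 <- sig[sig$cluster == "C1" & sig$pos == vars$pos[1], ]
  expect_equal(c1$carrier_prop, 1)
  expect_true(c1$signature)
  wt1 <- sig[sig$cluster == "wt" & sig$pos == vars$pos[1], ]
  expect_equal(wt1$carrier_prop, 0)
  expect_false(wt1$signature)
  expect_error(cluster_signature_variants(cl, hs,
                                          variant_sites("3R", 999L, "A", "G")),
               "not present")
})

test_that("a planted high-frequency sweep is recovered as one cluster", {
  lat <- default_site_lattice(n_flank = 40, n_gene = 24)
  fs <- which.min(abs(lat$pos - 6929700))
  gene <- region("3R", 6928858, 6930547)
  pure_hits <- 0
  for (i in 1:5) {
    cfg <- sim_config(n_pop = 150, n_founders = 20, sites = lat, s = 0.3,
                      generations = 25, focal_site = fs, seed = 70 + i * 13)
    sim <- suppressMessages(simulate_surviving(cfg, min_freq = 0.25))
    cl <- hierarchical_clusters(hamming_matrix(sim$hapset, gene))
    carrier <- sim$truth$carrier
    # the cluster holding most carriers should be nearly all of them and
    # nearly nothing else
    main <- names(which.max(table(cl$labels[carrier])))
    completeness <- mean(cl$labels[carrier] == main)
    purity <- mean(carrier[cl$labels == main])
    pure_hits <- pure_hits + (completeness > 0.8 && purity > 0.8)
  }
  expect_gte(pure_hits, 4)
})
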