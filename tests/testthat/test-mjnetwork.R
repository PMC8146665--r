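test_that("two haplotypes yield a single edge and no medians", {
  m <- cbind(c(0L, 0L, 0L), c(1L, 1L, 1L))
  net <- median_join(m)
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(net$edges$weight, 3L)
  msn <- minimum_spanning_network(m)
  expect_equal(msn$edges, net$edges)
})

test_that("the star fixture keeps its three unit edges and adds no median", {
  star <- cbind(c(0L, 0L, 0L, 0L), c(1L, 0L, 0L, 0L),
                c(0L, 1L, 0L, 0L), c(0L, 0L, 1L, 0L))
  msn <- minimum_spanning_network(star)
  expect_equal(nrow(msn$edges), 3L)
  expect_true(all(msn$edges$weight == 1L))
  expect_true(all(msn$edges$from == 1L | msn$edges$to == 1L))
  mj <- median_join(star)
  expect_equal(sum(mj$nodes$type == "median"), 0L)
})

test_that("equidistant haplotypes retain every MST-member edge", {
  # four sequences, all pairwise distance 2: every edge is in some MST
  eq <- cbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L),
              c(1L, 0L, 1L, 0L), c(0L, 1L, 1L, 0L))
  d <- oracle_hamming(eq)
  expect_true(all(d[upper.tri(d)] == 2))
  msn <- minimum_spanning_network(eq)
  oracle <- oracle_mst_union_edges(d)
  expect_equal(nrow(msn$edges), nrow(oracle))
  expect_equal(nrow(msn$edges), 6L)
})

test_that("random small networks match the exhaustive MST-union oracle", {
  set.seed(303)
  done <- 0
  while (done < 25) {
    mat <- unique(t(random_hap_matrix(6, 5)))
    if (nrow(mat) < 3) next
    mat <- t(mat)
    done <- done + 1
    msn <- minimum_spanning_network(mat)
    oracle <- oracle_mst_union_edges(oracle_hamming(mat))
    got <- msn$edges[order(msn$edges$from, msn$edges$to), ]
    want <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
    expect_equal(unname(as.matrix(got)), unname(want))
  }
})

test_that("the worked triplet gains exactly the Steiner median 100", {
  m <- cbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(1L, 0L, 1L))
  # exhaustive Steiner-point search over {0,1}^3
  steiner <- oracle_steiner_point(m[, 1], m[, 2], m[, 3])
  expect_equal(unname(steiner), c(1, 0, 0))
  net <- median_join(m)
  med <- net$nodes[net$nodes$type == "median", ]
  expect_equal(nrow(med), 1L)
  expect_equal(med$sequence, "100")
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight == 1L))
  # all three observed nodes connect through the median
  expect_true(all(sort(unique(c(net$edges$from, net$edges$to))) == 1:4))
})

test_that("duplicates collapse with summed multiplicity and memberships", {
  m <- cbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L), c(1L, 1L))
  net <- median_join(m)
  expect_equal(sort(net$nodes$multiplicity), c(2L, 3L))
  expect_equal(length(net$membership), 5L)
  expect_equal(net$nodes$multiplicity[net$membership[1]], 2L)
})

test_that("median insertion is a fixed point when medians are present", {
  # observed set already contains all triplet medians
  m <- cbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, 0L, 1L))
  mj <- median_join(m)
  msn <- minimum_spanning_network(m)
  expect_equal(sum(mj$nodes$type == "median"), 0L)
  expect_equal(mj$edges, msn$edges)
})

test_that("non-binary input is rejected", {
  expect_error(median_join(matrix(c(0, 2, 1, 1), 2)), "binary")
})

test_that("edge filtering yields the hand-traced and oracle components", {
  # chain A -(2)- B -(3)- C: at max_edge 2 the components are {A,B}, {C}
  m <- cbind(c(0L, 0L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L, 0L),
             c(1L, 1L, 1L, 1L, 1L))
  net <- median_join(m)
  comp <- components_by_edge_filter(net, max_edge = 2)
  expect_equal(comp$hap_component[1], comp$hap_component[2])
  expect_false(comp$hap_component[1] == comp$hap_component[3])
  expect_error(components_by_edge_filter(net, 0), "max_edge")

  # all edges weight 1: one component
  star <- cbind(c(0L, 0L), c(1L, 0L), c(0L, 1L))
  cs <- components_by_edge_filter(median_join(star), 2)
  expect_equal(length(unique(cs$node_component)), 1L)

  # random instances against a union-find oracle on the filtered graph
  set.seed(44)
  for (i in 1:20) {
    mat <- random_hap_matrix(8, 10)
    net <- median_join(mat)
    maxe <- sample(1:3, 1)
    comp <- components_by_edge_filter(net, maxe)
    k <- nrow(net$nodes)
    d <- matrix(Inf, k, k); diag(d) <- 0
    keep <- net$edges[net$edges$weight <= maxe, ]
    d[cbind(keep$from, keep$to)] <- 1
    d[cbind(keep$to, keep$from)] <- 1
    oracle <- oracle_threshold_components(d, 1)
    expect_equal(length(unique(comp$node_component)), length(unique(oracle)))
    expect_true(all(tapply(oracle, comp$node_component,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("the unfiltered network is connected; infinite filter gives one component", {
  set.seed(45)
  mat <- random_hap_matrix(12, 14)
  net <- median_join(mat)
  comp <- components_by_edge_filter(net, max_edge = Inf)
  expect_equal(length(unique(comp$node_component)), 1L)
})

test_that("concordance scores identical and perturbed partitions correctly", {
  fake_components <- function(ids) structure(
    list(node_component = ids, hap_component = ids, max_edge = 2),
    class = "ComponentClustering")
  fake_clusters <- function(labels) structure(
    list(labels = labels, cut_height = 7, linkage_method = "single",
         min_cluster_freq = 0.01), class = "ClusterAssignment")
  expect_equal(concordance(fake_components(c(1, 1, 2, 2)),
                           fake_clusters(c("C1", "C1", "C2", "C2"))), 1)
  # one of four haplotypes misassigned -> 0.75 under plurality matching
  expect_equal(concordance(fake_components(c(1, 1, 1, 2)),
                           fake_clusters(c("C1", "C1", "C2", "C2"))), 0.75)
  expect_error(concordance(fake_components(c(1, 1)),
                           fake_clusters(c("C1", "C1", "C2"))),
               "different haplotype universes")
  # one-to-one matching uses each label once
  expect_equal(concordance(fake_components(c(1, 1, 2, 2)),
                           fake_clusters(c("C1", "C1", "C1", "C1")),
                           method = "one_to_one"), 0.5)
})

test_that("surviving medians are well-connected and the network stays whole", {
  set.seed(77)
  for (i in 1:10) {
    mat <- random_hap_matrix(10, 8)
    mj <- median_join(mat)
    deg <- tabulate(c(mj$edges$from, mj$edges$to), nbins = nrow(mj$nodes))
    # obsolete-median pruning: every surviving inferred node has degree >= 3
    expect_true(all(deg[mj$nodes$type == "median"] >= 3))
    # every observed haplotype is reachable in the pre-filter network
    comp <- components_by_edge_filter(mj, max_edge = Inf)
    expect_equal(length(unique(comp$node_component)), 1L)
    # every inserted median strictly improves the cost of connecting some
    # triplet of current nodes (the insertion criterion, restated)
    d <- oracle_hamming(mj$seqs)
    for (m in which(mj$nodes$type == "median")) {
      nb <- unique(c(mj$edges$to[mj$edges$from == m],
                     mj$edges$from[mj$edges$to == m]))
      improves <- FALSE
      if (length(nb) >= 3) {
        trips <- utils::combn(nb, 3)
        for (k in seq_len(ncol(trips))) {
          u <- trips[1, k]; v <- trips[2, k]; w <- trips[3, k]
          via <- d[u, m] + d[v, m] + d[w, m]
          direct <- sum(sort(c(d[u, v], d[u, w], d[v, w]))[1:2])
          if (via <= direct) { improves <- TRUE; break }
        }
      }
      expect_true(improves)
    }
  }
})

test_that("networks export to GraphML and DOT with node attributes", {
  hs <- toy_hapset(random_hap_matrix(6, 8),
                   population = c("AO", "AO", "KE", "KE"))
  net <- median_join(hs)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".dot")
  write_network(net, f1, "graphml")
  write_network(net, f2, "dot")
  g <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_true("multiplicity" %in% igraph::vertex_attr_names(g))
  expect_true(any(grepl("multiplicity", readLines(f2))))
})
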