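# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately naive (double loops, exhaustive enumeration) and
# share no code with the implementation paths they check.

# a HaplotypeSet from a plain 0/1 matrix (sites x haplotypes)
toy_hapset <- function(mat, pos = NULL, chrom = "3R",
                       population = "P1", species = "spA") {
  n_hap <- ncol(mat)
  stopifnot(n_hap %% 2 == 0)
  if (is.null(pos)) pos <- seq_len(nrow(mat)) * 100L
  nt <- c("A", "C", "G", "T")
  sites <- variant_sites(chrom, pos, nt[pos %% 4 + 1], nt[(pos + 1) %% 4 + 1])
  n_s <- n_hap / 2
  population <- rep_len(population, n_s)
  species <- rep_len(species, n_s)
  meta <- tibble::tibble(sample_id = rep(sprintf("s%03d", seq_len(n_s)), each = 2),
                         hap_index = rep(c(1L, 2L), n_s),
                         population = rep(population, each = 2),
                         species = rep(species, each = 2))
  haplotype_set(sites, mat, meta)
}

# random binary haplotype matrix
random_hap_matrix <- function(n_sites, n_hap, p = 0.4) {
  matrix(rbinom(n_sites * n_hap, 1, p), n_sites, n_hap)
}

# write a small phased VCF as plain text
write_text_vcf <- function(path, chrom, pos, ref, alt, gt_rows, samples) {
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", chrom, ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom, pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt_rows[[i]]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  path
}

# oracle: Hamming distances by double loop
oracle_hamming <- function(mat) {
  n <- ncol(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(mat[, i] != mat[, j])
  d
}

# oracle: connected components of the graph joining pairs at distance <= h
oracle_threshold_components <- function(d, h) {
  n <- nrow(d)
  comp <- rep(0L, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      nb <- which(d[i, ] <= h & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# oracle: signed D' from the four gametic counts
oracle_dprime_counts <- function(nAB, nAb, naB, nab) {
  n <- nAB + nAb + naB + nab
  pA <- (nAB + nAb) / n
  pB <- (nAB + naB) / n
  D <- nAB / n - pA * pB
  if (D == 0) return(0)
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  D / dmax
}

# expand gametic counts into two indicator vectors
counts_to_vectors <- function(nAB, nAb, naB, nab) {
  list(a = rep(c(1, 1, 0, 0), c(nAB, nAb, naB, nab)),
       b = rep(c(1, 0, 1, 0), c(nAB, nAb, naB, nab)))
}

# oracle: EHH by naive all-pairs identity scan over [core edge, x]
oracle_ehh <- function(mat, members, flank_idx) {
  c_n <- length(members)
  pairs <- utils::combn(members, 2)
  vapply(seq_along(flank_idx), function(t) {
    rows <- flank_idx[seq_len(t)]
    ident <- vapply(seq_len(ncol(pairs)), function(k)
      all(mat[rows, pairs[1, k]] == mat[rows, pairs[2, k]]), TRUE)
    mean(ident)
  }, 0)
}

# oracle: enumerate all spanning trees of a small complete graph and keep
# edges appearing in at least one minimum spanning tree
oracle_mst_union_edges <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 6)
  edges <- t(utils::combn(n, 2))
  k <- nrow(edges)
  best <- Inf; in_some <- rep(FALSE, k)
  for (mask in 0:(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(sel) != n - 1) next
    # connectivity check
    comp <- seq_len(n)
    for (e in sel) {
      a <- comp[edges[e, 1]]; b <- comp[edges[e, 2]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) != 1) next
    w <- sum(d[edges[sel, , drop = FALSE]])
    if (w < best - 1e-9) { best <- w; in_some[] <- FALSE; in_some[sel] <- TRUE }
    else if (abs(w - best) < 1e-9) in_some[sel] <- TRUE
  }
  cbind(edges[in_some, , drop = FALSE],
        weight = d[edges[in_some, , drop = FALSE]])
}

# oracle: best single Steiner point over {0,1}^L for three binary sequences
oracle_steiner_point <- function(u, v, w) {
  L <- length(u)
  grid <- as.matrix(expand.grid(rep(list(0:1), L)))
  cost <- apply(grid, 1, function(m)
    sum(abs(u - m)) + sum(abs(v - m)) + sum(abs(w - m)))
  grid[which.min(cost), ]
}
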