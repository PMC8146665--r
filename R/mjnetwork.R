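# --- internal helpers -------------------------------------------------------

# collapse haplotype columns to distinct sequences
collapse_haplotypes <- function(mat) {
  keys <- hap_key(mat)
  uq <- unique(keys)
  node_of <- match(keys, uq)
  list(seqs = mat[, match(uq, keys), drop = FALSE],
       keys = uq,
       membership = node_of,
       multiplicity = as.integer(table(factor(node_of, levels = seq_along(uq)))))
}

# full pairwise Hamming distance matrix between columns
full_hamming <- function(mat) as.matrix(hamming_dist(mat))

# minimax path weights over the MST (epsilon-relaxed MSN criterion):
# sigma[i, j] = the largest edge on the unique MST path between i and j
minimax_via_mst <- function(d) {
  k <- nrow(d)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  t <- igraph::mst(g)
  adj <- lapply(seq_len(k), function(i) {
    nb <- as.integer(igraph::neighbors(t, i))
    w <- vapply(nb, function(j)
      igraph::E(t)[igraph::`%--%`(i, j)]$weight[1L], 0)
    list(nb = nb, w = w)
  })
  sigma <- matrix(0, k, k)
  for (src in seq_len(k)) {
    seen <- rep(FALSE, k); seen[src] <- TRUE
    queue <- src; best <- rep(0, k)
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      a <- adj[[i]]
      for (t2 in seq_along(a$nb)) {
        j <- a$nb[t2]
        if (!seen[j]) {
          seen[j] <- TRUE
          best[j] <- max(best[i], a$w[t2])
          queue <- c(queue, j)
        }
      }
    }
    sigma[src, ] <- best
  }
  sigma
}

# edges of the epsilon-relaxed minimum spanning network over node columns
msn_edges <- function(seqs, epsilon = 0) {
  k <- ncol(seqs)
  if (k < 2L)
    return(tibble::tibble(from = integer(0), to = integer(0),
                          weight = integer(0)))
  d <- full_hamming(seqs)
  sigma <- minimax_via_mst(d)
  pairs <- which(upper.tri(d) & d <= sigma + epsilon, arr.ind = TRUE)
  tibble::tibble(from = pairs[, 1L], to = pairs[, 2L],
                 weight = as.integer(d[pairs]))
}

# per-site majority of three binary sequences
triplet_median <- function(u, v, w) as.integer(u + v + w >= 2L)

# --- exported operations ----------------------------------------------------

#' Minimum spanning network of distinct haplotypes
#'
#' The first phase of median-joining network construction: the union of all
#' minimum spanning trees over the distinct input sequences, relaxed by
#' `epsilon` (an edge of weight `w` is kept when `w` is within `epsilon` of
#' the largest edge on the minimum spanning tree path between its ends).
#' Duplicate input sequences are collapsed into one node with summed
#' multiplicity. The result is always connected.
#'
#' @param x a `HaplotypeSet` or a 0/1 matrix (sites in rows, haplotypes in
#'   columns) with at least two distinct columns.
#' @param epsilon non-negative integer relaxation (default 0, the sparsest
#'   network).
#' @return An `MJNetwork` (with no median nodes); see [median_join()].
#' @export
minimum_spanning_network <- function(x, epsilon = 0) {
  build_network(x, epsilon, add_medians = FALSE)
}

#' Median-joining haplotype network
#'
#' Implements the Bandelt-Forster-Roehl median-joining construction over
#' binary haplotypes: starting from the (epsilon-relaxed) minimum spanning
#' network, every connected triplet of nodes proposes its per-site majority
#' consensus as a candidate median vector; a new median is adopted when it
#' strictly reduces the cost of connecting the triplet. The network is
#' rebuilt and the search repeated until no new median arises, after which
#' obsolete median nodes (inferred nodes of degree < 3) are iteratively
#' deleted. Triplets are scanned in lexicographic node order and candidate
#' medians inserted in sorted order, so reruns are bit-identical.
#'
#' @param x a `HaplotypeSet` or a 0/1 matrix (sites x haplotypes) with at
#'   least two distinct columns.
#' @param epsilon non-negative integer relaxation passed to the spanning
#'   phase.
#' @return An object of class `MJNetwork`: list with
#'   \describe{
#'     \item{nodes}{tibble of `node_id`, `type` (`observed`/`median`),
#'       `multiplicity`, `sequence` key.}
#'     \item{seqs}{0/1 matrix of node sequences (sites x nodes).}
#'     \item{edges}{tibble `from`, `to`, `weight` (Hamming distances).}
#'     \item{membership}{for each input haplotype, its node id.}
#'     \item{pop_counts}{per-node population counts (when built from a
#'       `HaplotypeSet`).}
#'     \item{epsilon}{the relaxation used.}
#'   }
#' @export
median_join <- function(x, epsilon = 0) {
  build_network(x, epsilon, add_medians = TRUE)
}

build_network <- function(x, epsilon, add_medians) {
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  meta <- NULL
  if (inherits(x, "HaplotypeSet")) {
    meta <- x$meta
    mat <- x$matrix
  } else mat <- x
  if (!is.matrix(mat) || (nrow(mat) && !all(mat %in% c(0L, 1L))))
    stop("haplotypes must be a binary 0/1 matrix", call. = FALSE)
  storage.mode(mat) <- "integer"
  col <- collapse_haplotypes(mat)
  if (ncol(col$seqs) < 2L)
    stop("need at least two distinct haplotype sequences", call. = FALSE)

  seqs <- col$seqs
  type <- rep("observed", ncol(seqs))
  if (add_medians) {
    for (iter in seq_len(200L)) {
      e <- msn_edges(seqs, epsilon)
      k <- ncol(seqs)
      adjm <- matrix(FALSE, k, k)
      adjm[cbind(e$from, e$to)] <- TRUE
      adjm <- adjm | t(adjm)
      d <- full_hamming(seqs)
      existing <- hap_key(seqs)
      cand <- character(0)
      for (u in seq_len(k - 2L)) for (v in (u + 1L):(k - 1L)) for (w in (v + 1L):k) {
        nlinks <- adjm[u, v] + adjm[u, w] + adjm[v, w]
        if (nlinks < 2L) next
        m <- triplet_median(seqs[, u], seqs[, v], seqs[, w])
        key <- paste0(m, collapse = "")
        if (key %in% existing || key %in% cand) next
        # connecting the triplet through the median must beat doing so
        # directly via its two cheapest internal links
        direct <- sum(sort(c(d[u, v], d[u, w], d[v, w]))[1:2])
        via <- sum(abs(seqs[, u] - m)) + sum(abs(seqs[, v] - m)) +
          sum(abs(seqs[, w] - m))
        if (via < direct) cand <- c(cand, key)
      }
      if (!length(cand)) break
      cand <- sort(cand)
      newseqs <- vapply(strsplit(cand, ""), as.integer,
                        integer(nrow(seqs)))
      newseqs <- matrix(newseqs, nrow = nrow(seqs))
      seqs <- cbind(seqs, newseqs)
      type <- c(type, rep("median", length(cand)))
    }
    # prune obsolete medians: inferred nodes of degree < 3
    repeat {
      e <- msn_edges(seqs, epsilon)
      deg <- tabulate(c(e$from, e$to), nbins = ncol(seqs))
      drop <- which(type == "median" & deg < 3L)
      if (!length(drop)) break
      keep <- setdiff(seq_len(ncol(seqs)), drop)
      seqs <- seqs[, keep, drop = FALSE]
      type <- type[keep]
    }
  }
  edges <- msn_edges(seqs, epsilon)
  keys <- hap_key(seqs)
  mult <- integer(ncol(seqs))
  obs_idx <- match(col$keys, keys)
  mult[obs_idx] <- col$multiplicity
  membership <- obs_idx[col$membership]
  pop_counts <- NULL
  if (!is.null(meta)) {
    pop <- cohort_label(meta$population, meta$species)
    pop_counts <- unclass(table(factor(membership, levels = seq_len(ncol(seqs))),
                                pop))
    dimnames(pop_counts) <- list(NULL, colnames(pop_counts))
  }
  structure(list(
    nodes = tibble::tibble(node_id = seq_len(ncol(seqs)), type = type,
                           multiplicity = mult, sequence = keys),
    seqs = seqs, edges = edges, membership = membership,
    pop_counts = pop_counts, epsilon = epsilon),
    class = "MJNetwork")
}

#' @export
print.MJNetwork <- function(x, ...) {
  cat(sprintf("<MJNetwork> %d observed + %d median nodes, %d edges (epsilon %d)\n",
              sum(x$nodes$type == "observed"), sum(x$nodes$type == "median"),
              nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Connected components after an edge-distance filter
#'
#' Removes every network edge heavier than `max_edge` SNPs and returns the
#' connected components of what remains, so that each component contains
#' only closely related haplotypes. Isolated observed nodes form their own
#' singleton components.
#'
#' @param net an `MJNetwork`.
#' @param max_edge maximum edge weight (SNPs) to retain; default 2.
#' @return An object of class `ComponentClustering`: list with
#'   `node_component` (component id per network node) and `hap_component`
#'   (component id per input haplotype).
#' @export
components_by_edge_filter <- function(net, max_edge = 2) {
  stopifnot(inherits(net, "MJNetwork"))
  if (max_edge < 1) stop("max_edge must be >= 1", call. = FALSE)
  k <- nrow(net$nodes)
  e <- net$edges[net$edges$weight <= max_edge, , drop = FALSE]
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, rbind(e$from, e$to))
  comp <- igraph::components(g)$membership
  structure(list(node_component = as.integer(comp),
                 hap_component = as.integer(comp[net$membership]),
                 max_edge = max_edge),
            class = "ComponentClustering")
}

#' Concordance between network components and hierarchical clusters
#'
#' Each network component is matched to a cluster label and the concordance
#' is the fraction of haplotypes whose matched label equals their actual
#' cluster label. With `method = "plurality"` (default) a component takes
#' the label held by the plurality of its haplotypes, ties going to the
#' label whose cluster is larger overall (then alphabetical); several
#' components may map to one label. With `method = "one_to_one"` labels are
#' assigned greedily by descending overlap and each label is used at most
#' once.
#'
#' @param components a `ComponentClustering`.
#' @param clusters a `ClusterAssignment` over the same haplotypes.
#' @param method `"plurality"` or `"one_to_one"`.
#' @return Concordance proportion in `[0, 1]`.
#' @export
concordance <- function(components, clusters,
                        method = c("plurality", "one_to_one")) {
  method <- match.arg(method)
  stopifnot(inherits(components, "ComponentClustering"),
            inherits(clusters, "ClusterAssignment"))
  comp <- components$hap_component
  labs <- clusters$labels
  if (length(comp) != length(labs))
    stop("components and clusters cover different haplotype universes",
         call. = FALSE)
  tab <- table(comp, labs)
  cluster_sizes <- table(labs)
  matched <- character(nrow(tab))
  names(matched) <- rownames(tab)
  if (method == "plurality") {
    for (i in seq_len(nrow(tab))) {
      row <- as.vector(tab[i, ])
      best <- colnames(tab)[row == max(row)]
      if (length(best) > 1L) {
        sz <- cluster_sizes[best]
        best <- best[sz == max(sz)]
        best <- sort(best)[1L]
      }
      matched[i] <- best
    }
  } else {
    cells <- expand.grid(comp = rownames(tab), lab = colnames(tab),
                         stringsAsFactors = FALSE)
    cells$n <- as.vector(tab)
    cells <- cells[order(-cells$n, cells$comp, cells$lab), ]
    used_lab <- character(0)
    for (r in seq_len(nrow(cells))) {
      ci <- cells$comp[r]
      if (matched[ci] != "" || cells$lab[r] %in% used_lab) next
      matched[ci] <- cells$lab[r]
      used_lab <- c(used_lab, cells$lab[r])
    }
    matched[matched == ""] <- NA_character_
  }
  hit <- matched[as.character(comp)] == labs
  # components left without a label (one-to-one mode, labels exhausted)
  # count as discordant
  hit[is.na(hit)] <- FALSE
  mean(hit)
}

# igraph view of a network, with node and edge attributes
network_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  if (nrow(net$edges))
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to),
                           weight = net$edges$weight)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("n", net$nodes$node_id))
  g <- igraph::set_vertex_attr(g, "type", value = net$nodes$type)
  g <- igraph::set_vertex_attr(g, "multiplicity", value = net$nodes$multiplicity)
  if (!is.null(net$pop_counts)) {
    pops <- colnames(net$pop_counts)
    lab <- apply(net$pop_counts, 1L, function(row)
      paste0(pops[row > 0], ":", row[row > 0], collapse = ","))
    g <- igraph::set_vertex_attr(g, "populations", value = lab)
  }
  g
}

#' Export a haplotype network to GraphML or DOT
#'
#' Node attributes carry the observed/median flag, multiplicity and (when
#' available) per-population haplotype counts; edges carry Hamming weights.
#'
#' @param net an `MJNetwork`.
#' @param path output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(network_igraph(net), path, format = format)
  invisible(path)
}
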