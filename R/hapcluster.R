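# pairwise Hamming distances between columns of a 0/1 matrix, as a dist
hamming_dist <- function(mat) {
  storage.mode(mat) <- "double"
  d <- crossprod(mat, 1 - mat)
  stats::as.dist(d + t(d))
}

#' Pairwise Hamming distance matrix over a region
#'
#' Counts, for every unordered pair of haplotypes, the number of biallelic
#' sites inside `region` at which their alleles differ. Distances are in SNP
#' units (site counts), not per-base rates, so a clustering threshold of
#' "seven SNPs" is applied directly on these values.
#'
#' @param hapset a `HaplotypeSet` with at least two haplotypes.
#' @param region optional [region()] to restrict sites to; by default all
#'   sites in the set are used. At least one site must remain.
#' @return A `dist` object of integer SNP distances, with attribute
#'   `n_sites` (number of sites counted over).
#' @export
hamming_matrix <- function(hapset, region = NULL) {
  stopifnot(inherits(hapset, "HaplotypeSet"))
  if (!is.null(region)) hapset <- subset_region(hapset, region)
  if (ncol(hapset$matrix) < 2L)
    stop("need at least two haplotypes", call. = FALSE)
  if (nrow(hapset$matrix) == 0L)
    stop("no sites in the requested region", call. = FALSE)
  d <- hamming_dist(hapset$matrix)
  attr(d, "n_sites") <- nrow(hapset$matrix)
  d
}

#' Agglomerative clustering of haplotypes cut at a SNP threshold
#'
#' Hierarchically clusters haplotypes on their Hamming distances and cuts
#' the dendrogram at `cut_height` SNPs. Flat clusters whose frequency is at
#' least `min_cluster_freq` are named `C1..Ck` in order of decreasing size
#' (ties broken by the lowest member index); every remaining haplotype is
#' labelled `wt` (wild type). With single linkage (the default) the flat
#' clusters at cut `h` are exactly the connected components of the graph
#' joining pairs at distance `<= h`.
#'
#' @param dist a `dist` from [hamming_matrix()].
#' @param linkage `"single"`, `"complete"` or `"average"`.
#' @param cut_height dendrogram cut height in SNPs (default 7).
#' @param min_cluster_freq minimum cluster frequency to earn a `C` label
#'   (default 0.01, i.e. 1% of haplotypes).
#' @return An object of class `ClusterAssignment`: a list with `labels`
#'   (character vector, `C1..Ck` or `"wt"`, one per haplotype), plus the
#'   parameters used and the underlying `hclust` tree.
#' @export
hierarchical_clusters <- function(dist, linkage = c("single", "complete", "average"),
                                  cut_height = 7, min_cluster_freq = 0.01) {
  linkage <- match.arg(linkage)
  if (cut_height < 0) stop("cut_height must be >= 0", call. = FALSE)
  tree <- stats::hclust(dist, method = linkage)
  raw <- stats::cutree(tree, h = cut_height)
  n <- length(raw)
  sizes <- table(raw)
  keep <- names(sizes)[sizes / n >= min_cluster_freq]
  # order retained clusters by descending size, ties by lowest member index
  first_idx <- vapply(keep, function(k) min(which(raw == as.integer(k))), 0L)
  ord <- keep[order(-as.integer(sizes[keep]), first_idx)]
  labels <- rep("wt", n)
  for (i in seq_along(ord))
    labels[raw == as.integer(ord[i])] <- paste0("C", i)
  structure(list(labels = labels, cut_height = cut_height,
                 linkage_method = linkage, min_cluster_freq = min_cluster_freq,
                 tree = tree, raw = raw),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<ClusterAssignment> %d haplotypes, cut at %s SNPs (%s linkage)\n",
              length(x$labels), format(x$cut_height), x$linkage_method))
  print(tab[order(names(tab) != "wt", names(tab))])
  invisible(x)
}

#' Per-population haplotype-cluster frequencies
#'
#' Tabulates, within each population cohort, the proportion of haplotypes
#' assigned to each cluster label (rows sum to 1). Populations with zero
#' haplotypes are absent rather than zero-filled.
#'
#' @param assignment a `ClusterAssignment`.
#' @param hapset the `HaplotypeSet` that was clustered (supplies the
#'   per-haplotype population labels).
#' @return A tibble with a `population` column and one proportion column per
#'   cluster label.
#' @export
cluster_population_summary <- function(assignment, hapset) {
  stopifnot(inherits(assignment, "ClusterAssignment"),
            inherits(hapset, "HaplotypeSet"))
  if (length(assignment$labels) != ncol(hapset$matrix))
    stop("assignment and haplotype set cover different haplotypes", call. = FALSE)
  pop <- cohort_label(hapset$meta$population, hapset$meta$species)
  tab <- table(pop, assignment$labels)
  prop <- prop.table(tab, margin = 1L)
  out <- tibble::tibble(population = rownames(prop))
  for (lab in colnames(prop)) out[[lab]] <- as.vector(prop[, lab])
  out
}

#' Signature variants of each haplotype cluster
#'
#' For every cluster label and high-frequency variant, the proportion of the
#' cluster's haplotypes carrying the alternate allele. A variant is flagged
#' a signature of a cluster when the carrier proportion exceeds
#' `signature_threshold` (default 0.9).
#'
#' @param assignment a `ClusterAssignment`.
#' @param hapset the clustered `HaplotypeSet`.
#' @param variants a site table (subset of `hapset$sites`, e.g. from
#'   [filter_high_frequency()]).
#' @param signature_threshold carrier proportion above which the variant is
#'   called a signature.
#' @return A tibble with columns `cluster`, `pos`, `label` (if present in
#'   `variants`), `carrier_prop`, `signature`.
#' @export
cluster_signature_variants <- function(assignment, hapset, variants,
                                       signature_threshold = 0.9) {
  stopifnot(inherits(assignment, "ClusterAssignment"),
            inherits(hapset, "HaplotypeSet"))
  idx <- match(variants$pos, hapset$sites$pos)
  if (anyNA(idx))
    stop("variant(s) not present in the haplotype set: ",
         paste(variants$pos[is.na(idx)], collapse = ", "), call. = FALSE)
  labs <- sort(unique(assignment$labels))
  rows <- list()
  for (cl in labs) {
    cols <- which(assignment$labels == cl)
    prop <- rowMeans(hapset$matrix[idx, cols, drop = FALSE])
    rows[[cl]] <- tibble::tibble(
      cluster = cl, pos = variants$pos,
      label = if ("label" %in% names(variants)) variants$label else NA_character_,
      carrier_prop = prop,
      signature = prop > signature_threshold)
  }
  do.call(rbind, rows)
}
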