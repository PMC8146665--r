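#' Phased haplotype set
#'
#' The central container of the package: a binary allele matrix over ordered
#' biallelic SNP sites, one column per haplotype, together with per-haplotype
#' metadata. Entries are 0 (reference allele) or 1 (alternate allele). Each
#' diploid sample contributes exactly two haplotype columns, in sample order,
#' first chromosome then second, so `n_haplotypes = 2 * n_samples`.
#'
#' @param sites a tibble from [variant_sites()] (columns `chrom`, `pos`,
#'   `ref`, `alt`), rows in strictly increasing position order.
#' @param matrix integer matrix of 0/1 alleles, `nrow(sites)` rows and one
#'   column per haplotype.
#' @param meta a data frame with one row per haplotype and columns
#'   `sample_id`, `hap_index` (1 or 2), `population`, `species`.
#' @return An object of class `HaplotypeSet`.
#' @export
haplotype_set <- function(sites, matrix, meta) {
  stopifnot(is.data.frame(sites), is.matrix(matrix), is.data.frame(meta))
  if (nrow(sites) != nrow(matrix))
    stop("matrix must have one row per site", call. = FALSE)
  if (ncol(matrix) != nrow(meta))
    stop("meta must have one row per haplotype column", call. = FALSE)
  need <- c("sample_id", "hap_index", "population", "species")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("meta is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(matrix) && !all(matrix %in% c(0L, 1L)))
    stop("allele matrix entries must all be 0 or 1", call. = FALSE)
  counts <- table(meta$sample_id)
  if (length(counts) && !all(counts == 2L))
    stop("each diploid sample must contribute exactly two haplotypes", call. = FALSE)
  storage.mode(matrix) <- "integer"
  meta <- tibble::as_tibble(meta)
  meta$haplotype_id <- paste0(meta$sample_id, "_", meta$hap_index)
  colnames(matrix) <- meta$haplotype_id
  structure(list(sites = tibble::as_tibble(sites), matrix = matrix, meta = meta),
            class = "HaplotypeSet")
}

#' @export
print.HaplotypeSet <- function(x, ...) {
  cat(sprintf("<HaplotypeSet> %d sites x %d haplotypes (%d samples, %d populations)\n",
              nrow(x$sites), ncol(x$matrix),
              length(unique(x$meta$sample_id)),
              length(unique(x$meta$population))))
  invisible(x)
}

#' Number of haplotypes in a set or implied by a sample count
#'
#' Every phased diploid contributes two haplotypes, so a cohort of 1142
#' samples yields 2284 haplotypes.
#'
#' @param x a `HaplotypeSet`, or a single number of diploid samples.
#' @return Integer haplotype count.
#' @export
n_haplotypes <- function(x) {
  if (inherits(x, "HaplotypeSet")) return(ncol(x$matrix))
  if (is.numeric(x) && length(x) == 1L) return(as.integer(2 * x))
  stop("x must be a HaplotypeSet or a diploid sample count", call. = FALSE)
}

#' Restrict a haplotype set to a region
#'
#' Keeps the sites falling inside `region` under half-open semantics
#' (a site at `pos == start` is kept, at `pos == end` dropped). The haplotype
#' columns and metadata are unchanged; an empty site list is allowed.
#' The operation is idempotent.
#'
#' @param hapset a `HaplotypeSet`.
#' @param region a [region()].
#' @return A `HaplotypeSet` with the restricted site list.
#' @export
subset_region <- function(hapset, region) {
  stopifnot(inherits(hapset, "HaplotypeSet"), inherits(region, "Region"))
  keep <- region_contains(region, hapset$sites$chrom, hapset$sites$pos)
  haplotype_set(hapset$sites[keep, , drop = FALSE],
                hapset$matrix[keep, , drop = FALSE],
                hapset$meta)
}

#' Restrict a haplotype set to a subset of haplotype columns
#'
#' @param hapset a `HaplotypeSet`.
#' @param idx integer or logical index over haplotype columns. Must keep both
#'   haplotypes of every retained sample.
#' @return A `HaplotypeSet`.
#' @export
subset_haplotypes <- function(hapset, idx) {
  stopifnot(inherits(hapset, "HaplotypeSet"))
  haplotype_set(hapset$sites,
                hapset$matrix[, idx, drop = FALSE],
                hapset$meta[idx, , drop = FALSE])
}

#' Combine haplotype sets over the same site list
#'
#' Column-binds haplotypes of several sets sharing an identical site table
#' (same chromosome, positions and ref/alt alleles); used to pool demes that
#' were simulated independently.
#'
#' @param ... `HaplotypeSet` objects, or a single list of them.
#' @return A pooled `HaplotypeSet`.
#' @export
bind_hapsets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "HaplotypeSet"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "HaplotypeSet")))
  ref <- sets[[1L]]$sites
  for (s in sets[-1L])
    if (!identical(as.data.frame(ref), as.data.frame(s$sites)))
      stop("haplotype sets must share an identical site table", call. = FALSE)
  ids <- unlist(lapply(sets, function(s) unique(s$meta$sample_id)))
  if (anyDuplicated(ids))
    stop("duplicate sample ids across the sets being combined", call. = FALSE)
  haplotype_set(ref,
                do.call(cbind, lapply(sets, function(s) s$matrix)),
                do.call(rbind, lapply(sets, function(s)
                  s$meta[, c("sample_id", "hap_index", "population", "species")])))
}

#' Cohort label for a population x species stratum
#'
#' Cohorts are defined by the combination of population and species (so the
#' same country sampled for two sibling species yields two cohorts, as in
#' frequency tables that separate e.g. coluzzii and gambiae columns).
#'
#' @param population,species character vectors.
#' @return Character cohort labels.
#' @export
cohort_label <- function(population, species) {
  ifelse(is.na(species) | species == "", population,
         paste0(population, "_", species))
}
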