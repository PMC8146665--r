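#' Genomic region (1-based, half-open)
#'
#' A `Region` names a chromosome interval under the half-open convention
#' `[start, end)`: the site at `start` is inside the region, the site at
#' `end` is outside. All coordinates in the package are 1-based, as in VCF.
#' With this convention a gene printed with endpoints 6928858 and 6930547
#' spans exactly 1689 bases.
#'
#' @param chrom chromosome (contig) name, e.g. `"3R"`.
#' @param start 1-based start position (inclusive).
#' @param end 1-based end position (exclusive); must satisfy `end > start`.
#' @return An object of class `Region`.
#' @examples
#' region("3R", 6928858, 6930547)
#' @export
region <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing positions", call. = FALSE)
  if (start < 1) stop("positions are 1-based; start must be >= 1", call. = FALSE)
  if (end <= start)
    stop("invalid region: end (", end, ") must be greater than start (", start, ")",
         call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end), class = "Region")
}

#' @export
print.Region <- function(x, ...) {
  cat(sprintf("<Region> %s:%d-%d (half-open, %d bp)\n",
              x$chrom, as.integer(x$start), as.integer(x$end),
              as.integer(region_length(x))))
  invisible(x)
}

#' Length of a half-open region in bases
#'
#' @param region a [region()] object.
#' @return Integer length `end - start`.
#' @examples
#' region_length(region("3R", 6928858, 6930547)) # 1689
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "Region"))
  as.integer(region$end - region$start)
}

#' Distance from an anchor end to a downstream gene start
#'
#' Genomic offset between the (exclusive) end of an anchor interval and the
#' start of a gene lying strictly downstream of it on the same chromosome.
#' The anchor is explicit because "downstream of the gene" can reasonably be
#' measured from the gene's own end or from the end of an enclosing gene
#' cluster; the two give different offsets and both are meaningful.
#'
#' @param anchor_end 1-based exclusive end of the anchor interval.
#' @param gene_start 1-based start of the downstream gene; must exceed
#'   `anchor_end`.
#' @return Integer distance `gene_start - anchor_end`.
#' @examples
#' downstream_distance(6930547, 7059422) # 128875
#' @export
downstream_distance <- function(anchor_end, gene_start) {
  anchor_end <- as.numeric(anchor_end)
  gene_start <- as.numeric(gene_start)
  if (gene_start <= anchor_end)
    stop("gene_start (", gene_start, ") must lie strictly downstream of anchor_end (",
         anchor_end, ")", call. = FALSE)
  as.integer(gene_start - anchor_end)
}

#' Is a position inside a region?
#'
#' Vectorised membership test under the half-open convention: `pos == start`
#' is inside, `pos == end` is outside.
#'
#' @param region a [region()] object.
#' @param chrom chromosome of each position.
#' @param pos 1-based positions.
#' @return Logical vector.
#' @export
region_contains <- function(region, chrom, pos) {
  stopifnot(inherits(region, "Region"))
  chrom == region$chrom & pos >= region$start & pos < region$end
}

#' Biallelic SNP site descriptors
#'
#' Validates a table of biallelic SNP sites: single-nucleotide `ref`/`alt`
#' in `{A,C,G,T}` with `ref != alt`, positions strictly increasing within a
#' chromosome.
#'
#' @param chrom,pos,ref,alt equal-length vectors describing each site.
#' @return A `tibble` with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
variant_sites <- function(chrom, pos, ref, alt) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n), length(ref) == n, length(alt) == n)
  chrom <- rep_len(chrom, n)
  pos <- as.integer(pos)
  nt <- c("A", "C", "G", "T")
  if (!all(ref %in% nt) || !all(alt %in% nt))
    stop("ref and alt must be single nucleotides in {A,C,G,T}", call. = FALSE)
  if (any(ref == alt))
    stop("biallelic SNPs require ref != alt", call. = FALSE)
  if (n > 1L) {
    same <- chrom[-1L] == chrom[-n]
    if (any(same & diff(pos) <= 0L))
      stop("site positions must be strictly increasing within a chromosome",
           call. = FALSE)
  }
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
}
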