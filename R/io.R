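#' Read a sample panel
#'
#' The panel is a tab-separated file with header columns `sample_id`,
#' `population`, `species`, one row per diploid sample. Duplicate sample ids
#' are rejected: the panel is the authority on haplotype ordering and a
#' duplicated id would make that ordering ambiguous.
#'
#' @param path path to the TSV file.
#' @return A tibble with columns `sample_id`, `population`, `species`.
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("sample_id", "population", "species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("panel contains duplicated sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  tibble::as_tibble(df[need])
}

#' Write a sample panel
#'
#' @param panel a panel tibble (`sample_id`, `population`, `species`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel[, c("sample_id", "population", "species")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

vlog <- function(verbose, ...) if (isTRUE(verbose)) message(...)

#' Read phased haplotypes from a VCF
#'
#' Reads a VCF with phased `GT` fields and returns the in-region biallelic
#' SNP haplotypes as a [haplotype_set()]. Records are restricted to `region`
#' under the half-open convention. Multiallelic records, non-SNP records and
#' records with any unphased or missing genotype are skipped (never split or
#' imputed) and each skipped class is reported with a count when
#' `verbose = TRUE`. Haplotype columns follow panel order: sample A hap 1,
#' sample A hap 2, sample B hap 1, and so on.
#'
#' @param path VCF path (plain or gzipped).
#' @param region a [region()] to restrict to.
#' @param panel panel tibble covering every sample in the VCF.
#' @param verbose report skipped-record counts to stderr.
#' @return A `HaplotypeSet` (possibly with zero sites).
#' @export
read_phased_vcf <- function(path, region, panel, verbose = FALSE) {
  stopifnot(inherits(region, "Region"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no genotype columns", call. = FALSE)
  vcf_samples <- colnames(gt)[-1L]
  unknown <- setdiff(vcf_samples, panel$sample_id)
  if (length(unknown))
    stop("VCF sample(s) absent from panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  panel <- panel[panel$sample_id %in% vcf_samples, , drop = FALSE]

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  in_region <- region_contains(region, chrom, pos)
  nt <- c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- ref %in% nt & alt %in% nt & !multi

  gtcol <- sub(":.*", "", gt[, panel$sample_id, drop = FALSE])
  phased <- matrix(grepl("^[01]\\|[01]$", gtcol), nrow = nrow(gt))
  allphased <- rowSums(!phased) == 0L

  vlog(verbose, "records outside region: ", sum(!in_region))
  vlog(verbose, "multiallelic/non-SNP records skipped: ", sum(in_region & !snp))
  vlog(verbose, "records with unphased or missing genotypes skipped: ",
       sum(in_region & snp & !allphased))
  keep <- in_region & snp & allphased
  ord <- order(pos[keep])
  sites <- variant_sites(chrom[keep][ord], pos[keep][ord],
                         ref[keep][ord], alt[keep][ord])

  n_hap <- 2L * nrow(panel)
  mat <- matrix(0L, nrow = sum(keep), ncol = n_hap)
  if (sum(keep)) {
    g <- gtcol[keep, , drop = FALSE][ord, , drop = FALSE]
    mat[, seq(1L, n_hap, by = 2L)] <- as.integer(substr(g, 1L, 1L))
    mat[, seq(2L, n_hap, by = 2L)] <- as.integer(substr(g, 3L, 3L))
  }
  meta <- tibble::tibble(
    sample_id = rep(panel$sample_id, each = 2L),
    hap_index = rep(c(1L, 2L), nrow(panel)),
    population = rep(panel$population, each = 2L),
    species = rep(panel$species, each = 2L))
  haplotype_set(sites, mat, meta)
}

#' Write a haplotype set as a phased VCF
#'
#' Emits one biallelic SNP record per site with phased `GT` fields in the
#' set's sample order. Written files round-trip through [read_phased_vcf()]
#' bit-exactly at the genotype level.
#'
#' @param hapset a `HaplotypeSet`.
#' @param path output path; vcfR compresses the stream, so a `.vcf.gz`
#'   suffix is conventional.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hapset, path) {
  stopifnot(inherits(hapset, "HaplotypeSet"))
  s <- hapset$sites
  n <- nrow(s)
  samples <- unique(hapset$meta$sample_id)
  fix <- cbind(CHROM = s$chrom, POS = as.character(s$pos), ID = rep(".", n),
               REF = s$ref, ALT = s$alt, QUAL = rep(".", n),
               FILTER = rep("PASS", n), INFO = rep(".", n))
  h1 <- hapset$matrix[, seq(1L, ncol(hapset$matrix), by = 2L), drop = FALSE]
  h2 <- hapset$matrix[, seq(2L, ncol(hapset$matrix), by = 2L), drop = FALSE]
  gtbody <- matrix(paste0(h1, "|", h2), nrow = n)
  gt <- cbind(FORMAT = rep("GT", n), gtbody)
  colnames(gt) <- c("FORMAT", samples)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", unique(s$chrom), ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line, `#` comments allowed. Values that parse
#' as numbers are returned numeric; `true`/`false` become logical; quoted
#' strings are unquoted. Used to name regions, thresholds and seeds for a
#' pipeline run.
#'
#' @param path path to the config file.
#' @return Named list.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <-
      if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

#' Write a tibble as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
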