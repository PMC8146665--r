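#' Annotate the protein effect of a SNP against a gene model
#'
#' Maps the genomic position into transcript coordinates
#' (reverse-complementing alleles on the minus strand), substitutes the
#' alternate base into the reference codon, translates both codons under the
#' standard genetic code and classifies the change. Labels follow the usual
#' one-letter convention of reference amino acid, codon number, alternate
#' amino acid — e.g. `I359V` for an isoleucine-to-valine change at codon 359.
#'
#' @param gene a [gene_model()].
#' @param site one-row site table (`chrom`, `pos`, `ref`, `alt`) from
#'   [variant_sites()].
#' @return A one-row tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `effect_class` (one of `missense`, `synonymous`, `stop_gained`,
#'   `stop_lost`, `non_coding`), `aa_ref`, `aa_pos`, `aa_alt`, `label`.
#' @export
annotate_variant <- function(gene, site) {
  stopifnot(inherits(gene, "GeneModel"), nrow(site) == 1L)
  if (site$chrom != gene$chrom)
    stop("site is not on the gene's chromosome", call. = FALSE)
  tpos <- transcript_position(gene, site$pos)
  base <- tibble::tibble(chrom = site$chrom, pos = site$pos,
                         ref = site$ref, alt = site$alt)
  if (is.na(tpos))
    return(tibble::tibble(base, effect_class = "non_coding",
                          aa_ref = NA_character_, aa_pos = NA_integer_,
                          aa_alt = NA_character_, label = NA_character_))
  cds <- strsplit(gene$ref_coding_sequence, "")[[1L]]
  tref <- if (gene$strand == "+") site$ref else comp_base(site$ref)
  talt <- if (gene$strand == "+") site$alt else comp_base(site$alt)
  if (cds[tpos] != tref)
    stop("reference allele at ", site$chrom, ":", site$pos,
         " (", site$ref, ") is inconsistent with the gene model's coding sequence",
         call. = FALSE)
  codon_i <- (tpos - 1L) %/% 3L
  idx <- codon_i * 3L + 1:3
  ref_codon <- cds[idx]
  alt_codon <- ref_codon
  alt_codon[(tpos - 1L) %% 3L + 1L] <- talt
  aa_ref <- translate_codons(ref_codon)
  aa_alt <- translate_codons(alt_codon)
  cls <- if (aa_ref == aa_alt) "synonymous"
         else if (aa_alt == "*") "stop_gained"
         else if (aa_ref == "*") "stop_lost"
         else "missense"
  tibble::tibble(base, effect_class = cls, aa_ref = aa_ref,
                 aa_pos = codon_i + 1L, aa_alt = aa_alt,
                 label = paste0(aa_ref, codon_i + 1L, aa_alt))
}

#' Annotate every site in a table
#'
#' @param gene a [gene_model()].
#' @param sites site table from [variant_sites()] (or a `HaplotypeSet`,
#'   whose site table is used).
#' @return A tibble with one annotated row per site; see [annotate_variant()].
#' @export
annotate_variants <- function(gene, sites) {
  if (inherits(sites, "HaplotypeSet")) sites <- sites$sites
  rows <- lapply(seq_len(nrow(sites)), function(i)
    annotate_variant(gene, sites[i, , drop = FALSE]))
  do.call(rbind, rows)
}

#' Per-cohort alternate-allele frequencies
#'
#' Computes, for every site, the alternate-allele frequency within each
#' population-by-species cohort and an `All` column over the pooled
#' haplotypes. `All` is haplotype-weighted — total alternate count divided
#' by total haplotype count — not the mean of cohort frequencies (set
#' `all_mode = "cohort_mean"` for the unweighted alternative). Cohorts with
#' zero haplotypes do not appear.
#'
#' @param hapset a `HaplotypeSet`.
#' @param panel optional panel tibble; when given, every sample in the set
#'   must have a panel entry.
#' @param all_mode how to pool the `All` column: `"haplotype"` (default) or
#'   `"cohort_mean"`.
#' @return A tibble with the site columns, one frequency column per cohort
#'   and an `All` column; cohort column names are stored in
#'   `attr(, "cohorts")` and cohort haplotype counts in
#'   `attr(, "cohort_sizes")`.
#' @export
population_allele_frequencies <- function(hapset, panel = NULL,
                                          all_mode = c("haplotype", "cohort_mean")) {
  stopifnot(inherits(hapset, "HaplotypeSet"))
  all_mode <- match.arg(all_mode)
  if (ncol(hapset$matrix) == 0L || nrow(hapset$sites) == 0L)
    stop("empty haplotype set: nothing to tabulate", call. = FALSE)
  if (!is.null(panel)) {
    missing <- setdiff(unique(hapset$meta$sample_id), panel$sample_id)
    if (length(missing))
      stop("sample(s) absent from panel: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  cohorts <- cohort_label(hapset$meta$population, hapset$meta$species)
  levels <- unique(cohorts)
  out <- hapset$sites
  sizes <- integer(0)
  for (co in levels) {
    cols <- which(cohorts == co)
    out[[co]] <- rowMeans(hapset$matrix[, cols, drop = FALSE])
    sizes[co] <- length(cols)
  }
  out$All <- if (all_mode == "haplotype") rowMeans(hapset$matrix)
             else rowMeans(as.matrix(out[levels]))
  attr(out, "cohorts") <- levels
  attr(out, "cohort_sizes") <- sizes
  out
}

#' Keep variants at high frequency in at least one cohort
#'
#' A variant is retained when its frequency strictly exceeds `threshold`
#' in one or more population cohorts (the pooled `All` column is not
#' consulted). The comparison is strict, so a variant at exactly the
#' threshold everywhere is dropped.
#'
#' @param table output of [population_allele_frequencies()].
#' @param threshold proportion in `[0, 1]`; default 0.05 (5%).
#' @return The retained rows, sorted by position.
#' @export
filter_high_frequency <- function(table, threshold = 0.05) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a proportion in [0, 1]", call. = FALSE)
  cohorts <- attr(table, "cohorts")
  if (is.null(cohorts))
    stop("table must come from population_allele_frequencies()", call. = FALSE)
  m <- as.matrix(table[cohorts])
  keep <- apply(m, 1L, max) > threshold
  out <- table[keep, , drop = FALSE][order(table$pos[keep]), , drop = FALSE]
  attr(out, "cohorts") <- cohorts
  attr(out, "cohort_sizes") <- attr(table, "cohort_sizes")
  out
}

#' Format a frequency table as percentages for reporting
#'
#' @param table output of [population_allele_frequencies()] (optionally
#'   filtered).
#' @param digits decimal places for the percentages.
#' @return A tibble with frequency columns formatted as percent strings.
#' @export
format_frequency_table <- function(table, digits = 1) {
  cohorts <- c(attr(table, "cohorts"), "All")
  out <- table
  for (co in cohorts)
    out[[co]] <- formatC(100 * table[[co]], format = "f", digits = digits)
  out
}
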