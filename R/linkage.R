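#' Signed Lewontin's D' between two sites
#'
#' For alternate-allele indicator vectors `a` and `b` over the same
#' haplotypes, with marginal frequencies `pA`, `pB` and joint alt-alt
#' frequency `pAB`, the gametic disequilibrium is `D = pAB - pA * pB` and
#' `D' = D / Dmax`, where `Dmax = min(pA * (1 - pB), (1 - pA) * pB)` when
#' `D > 0` and `Dmax = min(pA * pB, (1 - pA) * (1 - pB))` when `D < 0`
#' (`D' = 0` when `D = 0`). The sign is retained: `D' = 1` means the alt
#' alleles always travel together as far as their frequencies allow, and
#' `D' = -1` means they are never found on the same haplotype.
#'
#' A monomorphic site leaves D' undefined; by default this is an error, or
#' `NA` with `on_monomorphic = "na"` — it is never silently reported as 0,
#' because in stratified analyses an undefined value and an absence of
#' association mean different things.
#'
#' @param a,b equal-length 0/1 vectors (alt-allele indicators).
#' @param on_monomorphic `"error"` or `"na"`.
#' @return Signed D' in `[-1, 1]`, or `NA` for a flagged undefined pair.
#' @export
dprime <- function(a, b, on_monomorphic = c("error", "na")) {
  on_monomorphic <- match.arg(on_monomorphic)
  stopifnot(length(a) == length(b), length(a) >= 1L)
  a <- as.numeric(a); b <- as.numeric(b)
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    if (on_monomorphic == "error")
      stop("D' is undefined for a monomorphic site", call. = FALSE)
    return(NA_real_)
  }
  D <- mean(a * b) - pA * pB
  if (D == 0) return(0)
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  D / dmax
}

#' All-pairs signed D' matrix over a variant list
#'
#' Computes [dprime()] for every unordered pair of the named variants from
#' phased haplotypes. Pairs involving a site monomorphic in the input are
#' flagged `NA` (undefined), never 0. The diagonal is 1 for polymorphic
#' sites.
#'
#' @param hapset a `HaplotypeSet`.
#' @param variants site table (rows of `hapset$sites`) to include; defaults
#'   to all sites.
#' @return An object of class `LDMatrix`: list with `dprime` (symmetric
#'   matrix), `freq` (per-variant alt frequency) and `sites`.
#' @export
dprime_matrix <- function(hapset, variants = NULL) {
  stopifnot(inherits(hapset, "HaplotypeSet"))
  if (is.null(variants)) variants <- hapset$sites
  if (nrow(variants) == 0L) stop("empty variant list", call. = FALSE)
  idx <- match(variants$pos, hapset$sites$pos)
  if (anyNA(idx))
    stop("variant(s) not present in the haplotype set: ",
         paste(variants$pos[is.na(idx)], collapse = ", "), call. = FALSE)
  m <- hapset$matrix[idx, , drop = FALSE]
  k <- nrow(m)
  freq <- rowMeans(m)
  poly <- freq > 0 & freq < 1
  out <- matrix(NA_real_, k, k)
  diag(out) <- ifelse(poly, 1, NA_real_)
  if (k >= 2L) for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    if (poly[i] && poly[j]) {
      v <- dprime(m[i, ], m[j, ])
      out[i, j] <- v; out[j, i] <- v
    }
  }
  nm <- if ("label" %in% names(variants) && !anyNA(variants$label))
    variants$label else as.character(variants$pos)
  dimnames(out) <- list(nm, nm)
  names(freq) <- nm
  structure(list(dprime = out, freq = freq, sites = variants),
            class = "LDMatrix")
}

#' @export
print.LDMatrix <- function(x, ...) {
  cat(sprintf("<LDMatrix> %d variants; %d pair(s) undefined\n",
              nrow(x$dprime),
              sum(is.na(x$dprime[upper.tri(x$dprime)]))))
  print(round(x$dprime, 3))
  invisible(x)
}

#' D' within one population cohort
#'
#' Restricts the haplotypes to a single population before computing the
#' all-pairs D' matrix. Associations seen in the pooled cohort can be driven
#' by a single stratum (a Simpson-style artefact of population structure);
#' comparing stratified and pooled matrices exposes this. Sites monomorphic
#' within the cohort yield flagged-undefined (`NA`) pairs.
#'
#' @param hapset a `HaplotypeSet`.
#' @param variants site table of variants to include.
#' @param population population label to restrict to (matched against the
#'   per-haplotype `population` metadata).
#' @return An `LDMatrix` for the cohort.
#' @export
stratified_dprime <- function(hapset, variants, population) {
  stopifnot(inherits(hapset, "HaplotypeSet"))
  keep <- hapset$meta$population == population
  if (!any(keep))
    stop("population not present in the haplotype set: ", population,
         call. = FALSE)
  dprime_matrix(subset_haplotypes(hapset, keep), variants)
}

#' Write an LD matrix as TSV
#'
#' @param ld an `LDMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(variant = rownames(ld$dprime), freq = ld$freq,
                   ld$dprime, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
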