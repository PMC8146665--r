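#' Strand-aware single-transcript gene model
#'
#' Describes one protein-coding transcript: chromosome, strand, an ordered
#' set of CDS intervals (half-open [region()] objects in genomic order) and
#' the reference coding sequence in transcript orientation. The model covers
#' the common case at candidate detoxification loci of a gene with a single
#' annotated transcript and no alternative splicing; the stored coding
#' sequence excludes the terminal stop codon.
#'
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals list of [region()] objects, strictly increasing and
#'   non-overlapping in genomic coordinates.
#' @param ref_coding_sequence reference CDS in transcript orientation
#'   (reverse-complemented relative to the genome on the minus strand);
#'   length must equal the summed CDS interval lengths, be divisible by 3,
#'   and translate without internal stop codons.
#' @param transcript_id transcript identifier used in reports.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(chrom, strand, cds_intervals, ref_coding_sequence,
                       transcript_id = "TX1") {
  stopifnot(strand %in% c("+", "-"), is.list(cds_intervals),
            all(vapply(cds_intervals, inherits, TRUE, "Region")))
  starts <- vapply(cds_intervals, function(r) r$start, 0)
  ends <- vapply(cds_intervals, function(r) r$end, 0)
  if (is.unsorted(starts, strictly = TRUE) || any(starts[-1L] < ends[-length(ends)]))
    stop("CDS intervals must be non-overlapping and in increasing genomic order",
         call. = FALSE)
  total <- sum(ends - starts)
  seq_chars <- strsplit(toupper(ref_coding_sequence), "")[[1L]]
  if (length(seq_chars) != total)
    stop("ref_coding_sequence length (", length(seq_chars),
         ") does not match total CDS length (", total, ")", call. = FALSE)
  if (total %% 3L != 0L)
    stop("total CDS length must be divisible by 3", call. = FALSE)
  aa <- translate_codons(seq_chars)
  if (any(aa == "*"))
    stop("reference coding sequence contains an internal stop codon", call. = FALSE)
  structure(list(chrom = chrom, strand = strand, cds_intervals = cds_intervals,
                 ref_coding_sequence = paste0(seq_chars, collapse = ""),
                 transcript_id = transcript_id),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  total <- sum(vapply(x$cds_intervals, region_length, 0L))
  cat(sprintf("<GeneModel> %s (%s strand, %s) %d CDS bases, %d codons\n",
              x$transcript_id, x$strand, x$chrom, total, total %/% 3L))
  invisible(x)
}

# translate a character vector of CDS bases codon-by-codon (one-letter code)
translate_codons <- function(bases) {
  stopifnot(length(bases) %% 3L == 0L)
  if (!length(bases)) return(character(0))
  codons <- apply(matrix(bases, nrow = 3L), 2L, paste0, collapse = "")
  unname(Biostrings::GENETIC_CODE[codons])
}

# genomic position -> 1-based transcript (CDS) position, or NA if non-coding
transcript_position <- function(gene, pos) {
  starts <- vapply(gene$cds_intervals, function(r) r$start, 0)
  ends <- vapply(gene$cds_intervals, function(r) r$end, 0)
  lens <- ends - starts
  out <- rep(NA_integer_, length(pos))
  if (gene$strand == "+") {
    offs <- cumsum(c(0, lens[-length(lens)]))
    for (i in seq_along(starts)) {
      hit <- pos >= starts[i] & pos < ends[i]
      out[hit] <- as.integer(offs[i] + (pos[hit] - starts[i]) + 1)
    }
  } else {
    # transcript runs right to left: last interval first, bases reversed
    rlens <- rev(lens)
    offs <- rev(cumsum(c(0, rlens[-length(rlens)])))
    for (i in seq_along(starts)) {
      hit <- pos >= starts[i] & pos < ends[i]
      out[hit] <- as.integer(offs[i] + (ends[i] - 1 - pos[hit]) + 1)
    }
  }
  out
}

#' Generate a random gene model over a region
#'
#' Draws a reference coding sequence for a single-interval CDS spanning
#' `region`, sampling codons uniformly from the 61 sense codons so the
#' translation never contains an internal stop. When `sites` are supplied
#' (the simulator's SNP lattice), the reference base at each in-CDS site is
#' forced to the site's `ref` allele so annotation of simulated variants is
#' internally consistent; any codon turned into a stop by that constraint is
#' repaired at one of its unconstrained positions.
#'
#' @param region a [region()]; its length must be divisible by 3 and at
#'   least 6.
#' @param strand `"+"` or `"-"`.
#' @param seed integer seed; the model is deterministic given the seed.
#' @param sites optional site table (`chrom`, `pos`, `ref`) to honour.
#' @param transcript_id transcript identifier.
#' @return A `GeneModel`.
#' @export
plant_gene_model <- function(region, strand = "+", seed = 1L, sites = NULL,
                             transcript_id = "TX1") {
  stopifnot(inherits(region, "Region"))
  len <- region_length(region)
  if (len < 6L) stop("CDS region too short (< 6 bases)", call. = FALSE)
  if (len %% 3L != 0L)
    stop("CDS region length (", len, ") must be divisible by 3", call. = FALSE)
  nt <- c("A", "C", "G", "T")
  codons64 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  sense <- setdiff(codons64, c("TAA", "TAG", "TGA"))
  bases <- with_seed(seed, {
    codons <- sample(sense, len %/% 3L, replace = TRUE)
    unlist(strsplit(codons, ""), use.names = FALSE)
  })
  constrained <- integer(0)
  if (!is.null(sites)) {
    inside <- sites$pos >= region$start & sites$pos < region$end &
      sites$chrom == region$chrom
    gpos <- sites$pos[inside]
    gref <- sites$ref[inside]
    if (length(gpos)) {
      gm0 <- structure(list(chrom = region$chrom, strand = strand,
                            cds_intervals = list(region)), class = "GeneModel")
      tpos <- transcript_position(gm0, gpos)
      tref <- if (strand == "+") gref else comp_base(gref)
      bases[tpos] <- tref
      constrained <- tpos
      # repair codons the constraints turned into stops
      for (cd in unique((tpos - 1L) %/% 3L)) {
        idx <- cd * 3L + 1:3
        while (translate_codons(bases[idx]) == "*") {
          free <- setdiff(idx, constrained)
          if (!length(free))
            stop("cannot avoid a stop codon: all three bases constrained",
                 call. = FALSE)
          j <- free[1L]
          bases[j] <- nt[match(bases[j], nt) %% 4L + 1L]
        }
      }
    }
  }
  gene_model(region$chrom, strand, list(region),
             paste0(bases, collapse = ""), transcript_id)
}

#' Read a gene model from a GFF3-like file plus a coding-sequence FASTA
#'
#' The GFF3 file must contain `CDS` feature rows for a single transcript
#' (columns: seqid, source, type, start, end, score, strand, phase,
#' attributes with an `ID=` or `Parent=` tag); GFF3 end coordinates are
#' inclusive and are converted to the package's half-open convention. The
#' FASTA holds one record: the reference coding sequence in transcript
#' orientation.
#'
#' @param gff_path path to the GFF3-like file.
#' @param cds_fasta_path path to the coding-sequence FASTA.
#' @return A `GeneModel`.
#' @export
read_gene_model <- function(gff_path, cds_fasta_path) {
  lines <- readLines(gff_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(f, length, 0L) >= 8L
  f <- f[ok]
  types <- vapply(f, `[[`, "", 3L)
  cds <- f[types == "CDS"]
  if (!length(cds)) stop("no CDS features found in ", gff_path, call. = FALSE)
  chrom <- unique(vapply(cds, `[[`, "", 1L))
  strand <- unique(vapply(cds, `[[`, "", 7L))
  if (length(chrom) != 1L || length(strand) != 1L)
    stop("CDS features must share one chromosome and strand", call. = FALSE)
  starts <- as.integer(vapply(cds, `[[`, "", 4L))
  ends <- as.integer(vapply(cds, `[[`, "", 5L)) + 1L  # inclusive -> half-open
  ord <- order(starts)
  ivs <- Map(function(s, e) region(chrom, s, e), starts[ord], ends[ord])
  attr9 <- if (length(cds[[1L]]) >= 9L) cds[[1L]][[9L]] else ""
  tid <- sub(".*(?:ID|Parent)=([^;]+).*", "\\1", attr9)
  if (identical(tid, attr9) || !nzchar(tid)) tid <- "TX1"
  fa <- Biostrings::readDNAStringSet(cds_fasta_path)
  gene_model(chrom, strand, ivs, as.character(fa[[1L]]), tid)
}
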