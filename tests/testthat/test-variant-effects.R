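make_gene <- function(cds, start = 1000L, strand = "+", chrom = "3R") {
  gene_model(chrom, strand,
             list(region(chrom, start, start + nchar(cds))), cds)
}

test_that("plus-strand codon substitution classifies and labels correctly", {
  gene <- make_gene("ATGCTGAAA")           # M L K
  # codon 1 ATG, first base A>G -> GTG = Val: missense M1V
  eff <- annotate_variant(gene, variant_sites("3R", 1000L, "A", "G"))
  expect_equal(eff$effect_class, "missense")
  expect_equal(eff$label, "M1V")
  # codon 2 CTG, third base G>A -> CTA = Leu: synonymous L2L
  eff <- annotate_variant(gene, variant_sites("3R", 1005L, "G", "A"))
  expect_equal(eff$effect_class, "synonymous")
  expect_equal(eff$label, "L2L")
  # codon 3 AAA, first base A>T -> TAA: stop gained
  eff <- annotate_variant(gene, variant_sites("3R", 1006L, "A", "T"))
  expect_equal(eff$effect_class, "stop_gained")
  expect_equal(eff$aa_alt, "*")
  # outside the CDS: non-coding
  eff <- annotate_variant(gene, variant_sites("3R", 900L, "A", "G"))
  expect_equal(eff$effect_class, "non_coding")
  expect_true(is.na(eff$label))
})

test_that("minus-strand variants are reverse-complemented before translation", {
  # plus-strand genomic CAT reads ATG on the minus strand (codon 1 = Met)
  gene <- gene_model("3R", "-", list(region("3R", 1000, 1003)), "ATG")
  # plus-strand T at 1000 is the transcript A of ATG; T>C makes it GTG = Val
  eff <- annotate_variant(gene, variant_sites("3R", 1002L, "T", "C"))
  expect_equal(eff$effect_class, "missense")
  expect_equal(eff$label, "M1V")
})

test_that("inconsistent reference base is a data-integrity error", {
  gene <- make_gene("ATGCTGAAA")
  expect_error(annotate_variant(gene, variant_sites("3R", 1000L, "C", "G")),
               "inconsistent")
})

test_that("classification agrees with a six-frame translation oracle", {
  skip_if_not_installed("seqinr")
  set.seed(411)
  glen <- 60L
  for (i in 1:250) {
    strand <- sample(c("+", "-"), 1)
    gene <- plant_gene_model(region("3R", 5000, 5000 + glen), strand,
                             seed = i)
    tpos <- sample.int(glen, 1)
    cds <- strsplit(gene$ref_coding_sequence, "")[[1]]
    talt <- sample(setdiff(c("A", "C", "G", "T"), cds[tpos]), 1)
    # map the transcript position back to the genome
    gpos <- if (strand == "+") 5000L + tpos - 1L else 5000L + glen - tpos
    gref <- if (strand == "+") cds[tpos] else chartr("ACGT", "TGCA", cds[tpos])
    galt <- if (strand == "+") talt else chartr("ACGT", "TGCA", talt)
    eff <- annotate_variant(gene, variant_sites("3R", gpos, gref, galt))
    mut <- cds; mut[tpos] <- talt
    aa_ref <- seqinr::translate(cds)
    aa_mut <- seqinr::translate(mut)
    changed <- which(aa_ref != aa_mut)
    if (length(changed) == 0) {
      expect_equal(eff$effect_class, "synonymous")
    } else if (aa_mut[changed] == "*") {
      expect_equal(eff$effect_class, "stop_gained")
    } else {
      expect_equal(eff$effect_class, "missense")
      expect_equal(eff$label,
                   paste0(aa_ref[changed], changed, aa_mut[changed]))
    }
  }
})

test_that("planted gene models are deterministic and stop-free", {
  r <- region("3R", 7000, 7030)
  g1 <- plant_gene_model(r, "+", seed = 5)
  g2 <- plant_gene_model(r, "+", seed = 5)
  expect_identical(g1$ref_coding_sequence, g2$ref_coding_sequence)
  expect_equal(nchar(g1$ref_coding_sequence), 30L)
  for (seed in 1:200) {
    g <- plant_gene_model(r, sample(c("+", "-"), 1), seed = seed)
    aa <- haplosignal:::translate_codons(
      strsplit(g$ref_coding_sequence, "")[[1]])
    expect_false(any(aa == "*"))
  }
  expect_error(plant_gene_model(region("3R", 1, 4), "+"), "too short")
  expect_error(plant_gene_model(region("3R", 1, 8), "+"), "divisible by 3")
})

test_that("gene models with forced site alleles annotate their own lattice", {
  lat <- default_site_lattice(n_flank = 5, n_gene = 12)
  gene_region <- region("3R", 6928858, 6930547)
  g <- plant_gene_model(gene_region, "+", seed = 3, sites = lat)
  inside <- lat[lat$pos >= gene_region$start & lat$pos < gene_region$end, ]
  eff <- annotate_variants(g, inside)
  expect_true(all(eff$effect_class != "non_coding"))
  expect_true(all(eff$aa_pos >= 1 & eff$aa_pos <= 563))
})

test_that("gene model round-trips through GFF3-like + FASTA files", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  # two CDS intervals on the minus strand; GFF3 ends are inclusive
  writeLines(c("##gff-version 3",
               "3R\tsrc\tCDS\t100\t105\t.\t-\t0\tID=tx9",
               "3R\tsrc\tCDS\t200\t202\t.\t-\t0\tID=tx9"), gff)
  writeLines(c(">tx9", "ATGAAACCC"), fa)
  g <- read_gene_model(gff, fa)
  expect_equal(g$strand, "-")
  expect_equal(g$transcript_id, "tx9")
  expect_equal(length(g$cds_intervals), 2L)
  # transcript position 1 is the last base of the rightmost interval
  expect_equal(haplosignal:::transcript_position(g, c(202, 105, 100)),
               c(1L, 4L, 9L))
})

test_that("cohort frequencies match direct counting and pool correctly", {
  set.seed(7)
  mat <- random_hap_matrix(6, 20)
  hs <- toy_hapset(mat, population = rep(c("AO", "KE"), each = 5),
                   species = rep(c("coluzzii", "gambiae"), each = 5))
  ft <- population_allele_frequencies(hs)
  cohorts <- attr(ft, "cohorts")
  expect_equal(cohorts, c("AO_coluzzii", "KE_gambiae"))
  for (j in seq_len(6)) {
    expect_equal(ft$AO_coluzzii[j], sum(mat[j, 1:10]) / 10)
    expect_equal(ft$KE_gambiae[j], sum(mat[j, 11:20]) / 10)
    expect_equal(ft$All[j], sum(mat[j, ]) / 20)
  }
  # haplotype-weighted All: All * total = sum of cohort_count * cohort_freq
  sizes <- attr(ft, "cohort_sizes")
  expect_equal(ft$All * 20,
               ft$AO_coluzzii * sizes[["AO_coluzzii"]] +
                 ft$KE_gambiae * sizes[["KE_gambiae"]])
  # permuting haplotype columns within samples changes nothing
  perm <- sample(20)
  # (permute whole samples to keep the two-haplotypes-per-sample invariant)
  sperm <- sample(10)
  cols <- as.vector(rbind(2 * sperm - 1, 2 * sperm))
  hs2 <- haplotype_set(hs$sites, hs$matrix[, cols], hs$meta[cols, 1:4])
  ft2 <- population_allele_frequencies(hs2)
  expect_equal(ft2$All, ft$All)
})

test_that("the high-frequency filter is strict and cohort-based", {
  hs <- toy_hapset(matrix(0L, 3, 8))
  ft <- population_allele_frequencies(hs)
  ft$P1_spA <- c(0.04, 0.06, 0.05)
  ft$All <- c(0.04, 0.06, 0.05)
  kept <- filter_high_frequency(ft, 0.05)
  expect_equal(kept$pos, ft$pos[2])    # 4% excluded; exactly 5% excluded; 6% kept
  expect_error(filter_high_frequency(ft, 1.5), "proportion")
  # a variant needs only one cohort above threshold
  hs2 <- toy_hapset(rbind(c(1L, 1L, rep(0L, 6)), rep(0L, 8)),
                    population = c("A", "A", "B", "B"))
  ft2 <- population_allele_frequencies(hs2)
  expect_equal(filter_high_frequency(ft2, 0.05)$pos, ft2$pos[1])
})
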