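# internal helpers shared across modules

# run `code` under set.seed(seed), restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# reverse complement of a character vector of single bases
revcomp_bases <- function(bases) unname(rev(REV_COMP[bases]))

# complement without reversal (single bases)
comp_base <- function(base) unname(REV_COMP[base])

# collapse a haplotype column (0/1 vector) to a string key
hap_key <- function(mat) {
  if (nrow(mat) == 0L) return(rep("", ncol(mat)))
  apply(mat, 2L, paste0, collapse = "")
}
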