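#' Default SNP site lattice around a focal gene
#'
#' Lays out candidate SNP positions for the simulator: evenly spaced sites
#' across both flanks (out to `flank_bp` each side) plus a denser set inside
#' the gene itself, so coding variants exist and distance-based statistics
#' (LD and EHH versus bp) are meaningful. Reference and alternate alleles
#' are a fixed function of position, so independently simulated demes share
#' an identical site table and can be pooled.
#'
#' @param gene the focal gene [region()].
#' @param flank_bp flank width on each side, default 200000 (the maximum
#'   reach of the EHH scan).
#' @param n_flank number of sites per flank.
#' @param n_gene number of sites inside the gene.
#' @return A site tibble as from [variant_sites()].
#' @export
default_site_lattice <- function(gene = region("3R", 6928858, 6930547),
                                 flank_bp = 200000, n_flank = 100,
                                 n_gene = 24) {
  left <- round(seq(gene$start - flank_bp, gene$start - 1, length.out = n_flank))
  right <- round(seq(gene$end, gene$end + flank_bp - 1, length.out = n_flank))
  inside <- round(seq(gene$start, gene$end - 1, length.out = n_gene))
  pos <- sort(unique(c(left, inside, right)))
  nt <- c("A", "C", "G", "T")
  ref <- nt[pos %% 4L + 1L]
  alt <- nt[(pos + 1L) %% 4L + 1L]
  variant_sites(gene$chrom, pos, ref, alt)
}

#' Simulation configuration
#'
#' Parameters of the forward-time Wright-Fisher haplotype simulator: a fixed
#' lattice of candidate SNP sites, a diploid population of constant size
#' `n_pop` founded by `n_founders` distinct haplotypes, per-site mutation,
#' distance-dependent crossover, optional positive selection on a focal
#' allele (parent sampling weight `1 + s` per copy, multiplicative over the
#' diploid genotype) and an optional bottleneck epoch.
#'
#' Founder haplotypes are drawn from a neutral-like site frequency spectrum
#' (derived-allele count `k` among founders with probability proportional to
#' `1/k`); the focal allele, when a focal site is set, is instead planted on
#' exactly `focal_founders` founder haplotypes so its starting frequency is
#' controlled.
#'
#' @param n_pop diploid population size per generation.
#' @param n_founders number of distinct founder haplotypes
#'   (`<= 2 * n_pop`); founders are copied as evenly as possible to fill the
#'   founding generation.
#' @param sites site table from [variant_sites()] or
#'   [default_site_lattice()].
#' @param mu per-site per-generation mutation (allele-flip) probability.
#' @param r per-base per-generation crossover probability.
#' @param generations number of generations to evolve.
#' @param s selection coefficient of the focal allele (0 = neutral).
#' @param focal_site index into `sites` of the selected (or tracked) site;
#'   `NA` for none. Required when `s > 0`.
#' @param focal_founders how many founder haplotypes carry the focal
#'   alternate allele (initial frequency `focal_founders / n_founders`).
#' @param bottleneck optional `list(generation =, size =, duration =)`:
#'   the diploid size drops to `size` for `duration` generations starting
#'   at `generation` (1-based), then returns to `n_pop`.
#' @param founders optional 0/1 matrix of founder haplotypes (sites in
#'   rows) used verbatim instead of the random draw; `n_founders` is then
#'   taken from its column count. Passing the haplotype matrix of a
#'   finished neutral run as the founders of a selection run realises a
#'   sweep on an equilibrated background (see [simulate_two_phase()]).
#' @param seed RNG seed; the whole simulation is deterministic given the
#'   config.
#' @param pop_label,species_label labels written into the output panel.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(n_pop = 200L, n_founders = 20L,
                       sites = default_site_lattice(),
                       mu = 1e-5, r = 1e-6, generations = 20L,
                       s = 0, focal_site = NA_integer_, focal_founders = 1L,
                       bottleneck = NULL, founders = NULL, seed = 1L,
                       pop_label = "SIM", species_label = "simulans") {
  if (!is.null(founders)) {
    if (!is.matrix(founders) || nrow(founders) != nrow(sites) ||
        !all(founders %in% c(0L, 1L)))
      stop("founders must be a 0/1 matrix with one row per site", call. = FALSE)
    n_founders <- ncol(founders)
  }
  if (mu < 0 || mu > 1 || r < 0 || r > 1)
    stop("mu and r must be probabilities in [0, 1]", call. = FALSE)
  if (n_founders < 1L || n_founders > 2L * n_pop)
    stop("n_founders must be between 1 and 2 * n_pop", call. = FALSE)
  if (generations < 0L) stop("generations must be >= 0", call. = FALSE)
  if (s > 0 && (is.na(focal_site)))
    stop("a focal_site is required when s > 0", call. = FALSE)
  if (!is.na(focal_site) &&
      (focal_site < 1L || focal_site > nrow(sites)))
    stop("focal_site index out of range", call. = FALSE)
  if (!is.na(focal_site) &&
      (focal_founders < 1L || focal_founders >= n_founders))
    stop("focal_founders must be in [1, n_founders)", call. = FALSE)
  if (!is.null(bottleneck)) {
    need <- c("generation", "size", "duration")
    if (!all(need %in% names(bottleneck)))
      stop("bottleneck needs fields: generation, size, duration", call. = FALSE)
    if (bottleneck$size < 1L || bottleneck$size > n_pop)
      stop("bottleneck size must be in [1, n_pop]", call. = FALSE)
  }
  structure(list(n_pop = as.integer(n_pop), n_founders = as.integer(n_founders),
                 sites = sites, mu = mu, r = r,
                 generations = as.integer(generations), s = s,
                 focal_site = as.integer(focal_site),
                 focal_founders = as.integer(focal_founders),
                 bottleneck = bottleneck, founders = founders,
                 seed = as.integer(seed),
                 pop_label = pop_label, species_label = species_label),
            class = "SimConfig")
}

# diploid population size at each generation 0..G
sim_pop_sizes <- function(config) {
  sizes <- rep(config$n_pop, config$generations + 1L)
  b <- config$bottleneck
  if (!is.null(b)) {
    gens <- seq(b$generation, min(b$generation + b$duration - 1L,
                                  config$generations))
    sizes[gens + 1L] <- b$size
  }
  sizes
}

# founder haplotype matrix (n_sites x n_founders)
sim_founders <- function(config) {
  n_sites <- nrow(config$sites)
  nf <- config$n_founders
  if (!is.null(config$founders)) {
    F <- config$founders
    storage.mode(F) <- "integer"
    # focal_founders == NA marks founders whose focal row is already planted
    if (!is.na(config$focal_site) && !is.na(config$focal_founders)) {
      F[config$focal_site, ] <- 0L
      F[config$focal_site, seq_len(config$focal_founders)] <- 1L
    }
    return(F)
  }
  F <- matrix(0L, n_sites, nf)
  if (nf >= 2L) {
    kmax <- nf - 1L
    pk <- (1 / seq_len(kmax)) / sum(1 / seq_len(kmax))
    for (j in seq_len(n_sites)) {
      k <- sample.int(kmax, 1L, prob = pk)
      F[j, sample.int(nf, k)] <- 1L
    }
  }
  if (!is.na(config$focal_site)) {
    F[config$focal_site, ] <- 0L
    F[config$focal_site, seq_len(config$focal_founders)] <- 1L
  }
  F
}

#' Run a forward-time Wright-Fisher haplotype simulation
#'
#' Each offspring haplotype is a crossover mosaic of the two haplotypes of
#' one parent, the parent drawn from the previous generation with
#' probability proportional to its diploid fitness (`(1+s)` per focal-allele
#' copy, multiplicative; uniform when `s = 0`). Crossovers fall between
#' adjacent lattice sites with probability `1 - exp(-r * gap)`; mutations
#' flip alleles with probability `mu` per site per transmission. Output is
#' bit-identical for identical configurations.
#'
#' @param config a [sim_config()].
#' @param stop_if_lost stop evolving once the focal allele is lost (its
#'   frequency trajectory is zero-filled from that point); used by
#'   rejection-sampling drivers that discard such runs.
#' @return A list with components:
#'   \describe{
#'     \item{hapset}{the final generation as a [haplotype_set()].}
#'     \item{panel}{the matching sample panel tibble.}
#'     \item{truth}{a `SimTruth` list: `trajectory` (focal-allele frequency
#'       at generations `0..G`), `carrier` (per-haplotype focal-allele
#'       flag), `founder_origin` (per-site founder-of-origin matrix, the
#'       mosaic record), `founders` (founder haplotype matrix) and
#'       `focal_site`.}
#'   }
#' @export
simulate_population <- function(config, stop_if_lost = FALSE) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(config$seed, {
    n_sites <- nrow(config$sites)
    sizes <- sim_pop_sizes(config)
    F <- sim_founders(config)
    f0 <- rep_len(seq_len(config$n_founders), 2L * sizes[1L])
    X <- F[, f0, drop = FALSE]
    A <- matrix(rep(f0, each = n_sites), n_sites)
    pc <- -expm1(-config$r * diff(config$sites$pos))
    # lower-triangular ones: cumulative crossover parity via one BLAS product
    L <- matrix(0, n_sites, n_sites)
    L[lower.tri(L, diag = TRUE)] <- 1
    traj <- rep(NA_real_, config$generations + 1L)
    if (!is.na(config$focal_site)) traj[1L] <- mean(X[config$focal_site, ])
    for (g in seq_len(config$generations)) {
      n_cur <- ncol(X) %/% 2L
      m <- 2L * sizes[g + 1L]
      w <- NULL
      if (config$s > 0) {
        cnt <- X[config$focal_site, seq(1L, 2L * n_cur, 2L)] +
          X[config$focal_site, seq(2L, 2L * n_cur, 2L)]
        w <- (1 + config$s)^cnt
      }
      par <- sample.int(n_cur, m, replace = TRUE, prob = w)
      matA <- X[, 2L * par - 1L, drop = FALSE]
      matB <- X[, 2L * par, drop = FALSE]
      ancA <- A[, 2L * par - 1L, drop = FALSE]
      ancB <- A[, 2L * par, drop = FALSE]
      flips <- rbind(stats::rbinom(m, 1L, 0.5),
                     matrix(stats::rbinom((n_sites - 1L) * m, 1L,
                                          rep(pc, m)), n_sites - 1L))
      strand <- (L %*% flips) %% 2
      X <- matA * (1L - strand) + matB * strand
      A <- ancA * (1L - strand) + ancB * strand
      if (config$mu > 0) {
        mut <- matrix(stats::rbinom(n_sites * m, 1L, config$mu), n_sites)
        X <- (X + mut) %% 2L
      }
      if (!is.na(config$focal_site)) {
        traj[g + 1L] <- mean(X[config$focal_site, ])
        # a lost focal allele cannot recover by drift; when the caller only
        # needs the survival outcome the remaining generations are moot
        if (stop_if_lost && traj[g + 1L] == 0) {
          traj[(g + 1L):(config$generations + 1L)] <- 0
          break
        }
      }
    }
    n_out <- ncol(X) %/% 2L
    sample_id <- sprintf("%s-%04d", config$pop_label, seq_len(n_out))
    meta <- tibble::tibble(sample_id = rep(sample_id, each = 2L),
                           hap_index = rep(c(1L, 2L), n_out),
                           population = config$pop_label,
                           species = config$species_label)
    panel <- tibble::tibble(sample_id = sample_id,
                            population = config$pop_label,
                            species = config$species_label)
    truth <- structure(list(trajectory = traj,
                            carrier = if (is.na(config$focal_site)) NULL
                                      else X[config$focal_site, ] == 1L,
                            founder_origin = A, founders = F,
                            focal_site = config$focal_site),
                       class = "SimTruth")
    list(hapset = haplotype_set(config$sites, X, meta),
         panel = panel, truth = truth)
  })
}

#' Simulate conditional on the focal allele surviving
#'
#' Reruns [simulate_population()] with successive seeds until the final
#' focal-allele frequency lies inside `[min_freq, max_freq]` (by default:
#' segregating, neither lost nor fixed). Used for sweep-versus-neutral
#' contrasts, where a lost sweep carries no signal. Rejected attempts are
#' reported via `message()`.
#'
#' @param config a [sim_config()] with a focal site.
#' @param min_freq,max_freq acceptance bounds on the final focal frequency.
#' @param max_tries maximum attempts before giving up with an error.
#' @return As [simulate_population()], with the extra attributes
#'   `seed_used` and `tries`.
#' @export
simulate_surviving <- function(config, min_freq = NULL, max_freq = NULL,
                               max_tries = 100L) {
  stopifnot(inherits(config, "SimConfig"), !is.na(config$focal_site))
  two_n <- 2 * config$n_pop
  if (is.null(min_freq)) min_freq <- 2 / two_n
  if (is.null(max_freq)) max_freq <- 1 - 2 / two_n
  seed <- config$seed
  for (try in seq_len(max_tries)) {
    cfg <- config
    cfg$seed <- seed
    sim <- simulate_population(cfg)
    fq <- sim$truth$trajectory[length(sim$truth$trajectory)]
    if (fq >= min_freq && fq <= max_freq) {
      if (try > 1L)
        message("focal allele lost/fixed in ", try - 1L,
                " attempt(s); accepted seed ", seed)
      attr(sim, "seed_used") <- seed
      attr(sim, "tries") <- try
      return(sim)
    }
    seed <- seed + 1L
  }
  stop("no surviving replicate in ", max_tries, " attempts", call. = FALSE)
}

#' Sweep on an equilibrated background: burn-in plus selection phase
#'
#' Runs a neutral burn-in of `burn_in` generations (no focal allele), then
#' uses the resulting haplotypes as the founders of a second phase in which
#' the focal allele is planted and selection `config$s` applies for
#' `config$generations` generations. Without the burn-in every lineage in
#' the cohort is equally young and small neutral clades mimic sweep
#' haplotypes; the burn-in ages the background so a recently expanded
#' lineage stands out, which is the contrast EHH is designed to detect.
#'
#' Two planting modes are available. `"standing"` (default) marks every
#' copy of an existing core-haplotype class — the class whose frequency is
#' nearest `target_freq` over the `core` region — as the focal carrier;
#' under neutrality the carrier is then an ordinary standing class,
#' exchangeable with any other class of its size, which calibrates
#' null comparisons at one half. `"de_novo"` plants the allele on
#' `config$focal_founders` haplotype(s), a new mutation.
#'
#' The selection phase is conditioned on the focal allele reaching a final
#' frequency in `[min_freq, max_freq]`; rejected attempts rerun only the
#' second phase with the next seed, reusing the burn-in.
#'
#' @param config a [sim_config()] describing the selection phase (its
#'   `focal_site` is required; its `n_founders` and SFS draw seed the
#'   burn-in).
#' @param burn_in neutral generations before the focal allele appears.
#' @param plant `"standing"` or `"de_novo"`.
#' @param core region over which standing core-haplotype classes are
#'   defined; defaults to the default gene region.
#' @param target_freq desired starting frequency of the standing carrier
#'   class.
#' @param min_freq,max_freq acceptance bounds on the final focal frequency.
#' @param max_tries maximum selection-phase attempts.
#' @return As [simulate_population()], with attributes `tries`,
#'   `burn_in` and `start_freq` (realised planting frequency).
#' @export
simulate_two_phase <- function(config, burn_in = 100L,
                               plant = c("standing", "de_novo"),
                               core = region("3R", 6928858, 6930547),
                               target_freq = 0.02, min_freq = 0.01,
                               max_freq = 0.995, max_tries = 200L) {
  stopifnot(inherits(config, "SimConfig"), !is.na(config$focal_site))
  plant <- match.arg(plant)
  cfg_burn <- config
  cfg_burn$s <- 0
  cfg_burn$focal_site <- NA_integer_
  cfg_burn$generations <- as.integer(burn_in)
  cfg_burn$bottleneck <- NULL
  burn <- simulate_population(cfg_burn)
  founders <- burn$hapset$matrix
  cfg2 <- config
  if (plant == "standing") {
    # classes are keyed on the core sites excluding the focal site itself,
    # so planting the allele is a pure label on an existing class and can
    # neither split nor merge the class structure
    core_rows <- which(region_contains(core, config$sites$chrom,
                                       config$sites$pos))
    core_rows <- setdiff(core_rows, config$focal_site)
    keys <- hap_key(burn$hapset$matrix[core_rows, , drop = FALSE])
    tab <- table(keys)
    tab <- tab[tab >= 2L]
    if (!length(tab))
      stop("no standing core class with at least two copies", call. = FALSE)
    freqs <- as.numeric(tab) / ncol(founders)
    pick <- names(tab)[order(abs(freqs - target_freq), names(tab))][1L]
    founders[config$focal_site, ] <- as.integer(keys == pick)
    # planting is done by hand above; disable the founder-planting path
    cfg2$focal_founders <- NA_integer_
    start_freq <- mean(keys == pick)
  } else {
    founders[config$focal_site, ] <- 0L
    founders[config$focal_site, seq_len(config$focal_founders)] <- 1L
    cfg2$focal_founders <- NA_integer_
    start_freq <- config$focal_founders / ncol(founders)
  }
  cfg2$founders <- founders
  cfg2$n_founders <- ncol(founders)
  # core-haplotype class frequencies at the start of the selection phase
  # (founders fill the first generation one copy each, so founder class
  # frequency equals starting frequency)
  start_keys <- hap_key(founders[region_contains(core, config$sites$chrom,
                                                 config$sites$pos), ,
                                 drop = FALSE])
  start_core_freq <- table(start_keys) / length(start_keys)
  seed2 <- config$seed + 500000L
  for (try in seq_len(max_tries)) {
    cfg2$seed <- seed2
    sim <- simulate_population(cfg2, stop_if_lost = TRUE)
    fq <- sim$truth$trajectory[length(sim$truth$trajectory)]
    if (fq >= min_freq && fq <= max_freq) {
      if (try > 1L)
        message("focal allele lost/fixed in ", try - 1L,
                " attempt(s); accepted phase-2 seed ", seed2)
      attr(sim, "tries") <- try
      attr(sim, "burn_in") <- burn_in
      attr(sim, "start_freq") <- start_freq
      attr(sim, "start_core_freq") <- start_core_freq
      return(sim)
    }
    seed2 <- seed2 + 1L
  }
  stop("no surviving selection phase in ", max_tries, " attempts",
       call. = FALSE)
}

# mean pairwise identity among a set of haplotype columns over given site rows
mean_pairwise_identity <- function(mat, cols, rows) {
  if (length(cols) < 2L || length(rows) == 0L) return(NA_real_)
  sub <- mat[rows, cols, drop = FALSE]
  d <- hamming_dist(sub)
  1 - mean(d) / length(rows)
}

#' Sweep-versus-neutral carrier-identity contrast
#'
#' Runs paired replicates of two configurations that differ only in the
#' selection coefficient, conditioning each on the focal allele segregating,
#' and records the final focal-allele frequency and the mean pairwise
#' haplotype identity among focal-allele carriers over a flanking window.
#' Under a sweep the carriers' flanking identity is stochastically larger
#' than under neutrality.
#'
#' @param config_neutral,config_sweep [sim_config()]s identical except in
#'   `s` (and seed).
#' @param n_reps number of replicate pairs (`>= 2`).
#' @param flank_bp half-width of the identity window around the focal site.
#' @return A tibble with one row per replicate and scenario: `rep`,
#'   `scenario`, `focal_freq`, `carrier_identity`.
#' @export
simulate_sweep_contrast <- function(config_neutral, config_sweep,
                                    n_reps = 20L, flank_bp = 50000) {
  stopifnot(inherits(config_neutral, "SimConfig"),
            inherits(config_sweep, "SimConfig"))
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  a <- config_neutral; a$s <- NULL; a$seed <- NULL
  b <- config_sweep; b$s <- NULL; b$seed <- NULL
  if (!identical(a, b))
    stop("the two configurations must be identical except for s (and seed)",
         call. = FALSE)
  rows <- list()
  for (i in seq_len(n_reps)) {
    for (scen in c("neutral", "sweep")) {
      cfg <- if (scen == "neutral") config_neutral else config_sweep
      cfg$seed <- cfg$seed + (i - 1L) * 1000L
      sim <- suppressMessages(simulate_surviving(cfg))
      pos <- cfg$sites$pos
      fpos <- pos[cfg$focal_site]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = i, scenario = scen,
        focal_freq = sim$truth$trajectory[length(sim$truth$trajectory)],
        carrier_identity = mean_pairwise_identity(
          sim$hapset$matrix, which(sim$truth$carrier),
          which(abs(pos - fpos) <= flank_bp & seq_along(pos) != cfg$focal_site)))
    }
  }
  do.call(rbind, rows)
}

#' Write simulation truth records as TSV
#'
#' @param truth a `SimTruth` from [simulate_population()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(tibble::tibble(generation = seq_along(truth$trajectory) - 1L,
                                 focal_freq = truth$trajectory),
                  file.path(dir, "trajectory.tsv"))
  if (!is.null(truth$carrier))
    write_tsv_table(tibble::tibble(haplotype = seq_along(truth$carrier),
                                   carrier = truth$carrier),
                    file.path(dir, "carriers.tsv"))
  invisible(dir)
}
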