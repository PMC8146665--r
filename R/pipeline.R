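#' Pipeline configuration
#'
#' Bundles the inputs and thresholds of a full analysis run. Input is
#' either a phased VCF plus sample panel, or one or more simulator
#' configurations (in which case the cohort is generated and written out);
#' exactly one of the two must be given. The defaults carry the analysis'
#' standard parameterisation: the > 5% cohort frequency filter, the 7-SNP
#' dendrogram cut, the 2-SNP network edge filter, core groups at >= 1%
#' frequency and a 200 kb EHH reach.
#'
#' @param vcf,panel input file paths (both or neither).
#' @param sim a [sim_config()] or list of them (one per deme), or `NULL`.
#' @param gene_region the focal gene [region()] (clustering, LD and network
#'   stages operate on its sites; the effect annotator uses it as the CDS).
#' @param core_region the EHH core [region()]; defaults to the gene region.
#' @param gene_strand strand of the focal gene.
#' @param freq_threshold high-frequency filter (proportion, default 0.05).
#' @param cut_height dendrogram cut in SNPs (default 7).
#' @param max_edge network edge filter in SNPs (default 2).
#' @param min_core_freq minimum core-group frequency (default 0.01).
#' @param max_distance EHH reach in bp (default 200000).
#' @param seed master seed for the run.
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(vcf = NULL, panel = NULL, sim = NULL,
                            gene_region = region("3R", 6928858, 6930547),
                            core_region = gene_region, gene_strand = "+",
                            freq_threshold = 0.05, cut_height = 7,
                            max_edge = 2, min_core_freq = 0.01,
                            max_distance = 200000, seed = 1L) {
  has_files <- !is.null(vcf) || !is.null(panel)
  if (has_files && (is.null(vcf) || is.null(panel)))
    stop("vcf and panel must be given together", call. = FALSE)
  if (has_files && !is.null(sim))
    stop("give either input files or a simulate block, not both", call. = FALSE)
  if (!has_files && is.null(sim))
    stop("either input files or a simulate block is required", call. = FALSE)
  if (inherits(sim, "SimConfig")) sim <- list(sim)
  if (freq_threshold < 0 || freq_threshold > 1)
    stop("freq_threshold must be in [0, 1]", call. = FALSE)
  if (cut_height < 0 || max_edge < 1 || min_core_freq < 0 ||
      min_core_freq > 1 || max_distance < 1)
    stop("threshold outside its documented range", call. = FALSE)
  structure(list(vcf = vcf, panel = panel, sim = sim,
                 gene_region = gene_region, core_region = core_region,
                 gene_strand = gene_strand, freq_threshold = freq_threshold,
                 cut_height = cut_height, max_edge = max_edge,
                 min_core_freq = min_core_freq, max_distance = max_distance,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full haplotype-signal pipeline
#'
#' Executes, in order: input (simulate or read), protein-effect annotation
#' and per-population allele frequencies with the high-frequency filter,
#' Hamming-distance hierarchical clustering over the gene region, the
#' all-pairs D' matrix over the retained missense variants, the
#' median-joining network over the gene-region haplotypes with the edge
#' filter and concordance against the clusters, and per-population EHH
#' decay around the core region. Every stage writes its table (TSV) or
#' graph (GraphML) under `out_dir`, and a manifest with MD5 content hashes
#' is written last; a rerun with the same configuration reproduces the
#' manifest bit for bit.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose log stage progress to stderr.
#' @return The manifest tibble (`file`, `md5`), invisibly; the concordance
#'   value and other scalar summaries are written to `summary.tsv`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    vlog(verbose, "stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  # -- input -----------------------------------------------------------------
  sim_truths <- NULL
  dat <- stage("input", {
    if (!is.null(config$sim)) {
      sims <- lapply(config$sim, simulate_population)
      sim_truths <- lapply(sims, `[[`, "truth")
      hapset <- bind_hapsets(lapply(sims, `[[`, "hapset"))
      panel <- do.call(rbind, lapply(sims, `[[`, "panel"))
      emit(write_phased_vcf(hapset, file.path(out_dir, "cohort.vcf.gz")))
      emit(write_panel(panel, file.path(out_dir, "panel.tsv")))
      traj <- do.call(rbind, Map(function(s, i) tibble::tibble(
        deme = i, generation = seq_along(s$truth$trajectory) - 1L,
        focal_freq = s$truth$trajectory), sims, seq_along(sims)))
      emit(write_tsv_table(traj, file.path(out_dir, "truth_trajectory.tsv")))
      list(hapset = hapset, panel = panel)
    } else {
      panel <- read_panel(config$panel)
      span <- region(config$gene_region$chrom, 1,
                     config$gene_region$end + config$max_distance + 1)
      list(hapset = read_phased_vcf(config$vcf, span, panel,
                                    verbose = verbose),
           panel = panel)
    }
  })
  hapset <- dat$hapset

  # -- variant effects and frequencies ---------------------------------------
  gene <- stage("gene_model",
    plant_gene_model(config$gene_region, config$gene_strand,
                     seed = config$seed, sites = hapset$sites))
  gene_set <- subset_region(hapset, config$gene_region)
  eff <- stage("annotate", annotate_variants(gene, gene_set$sites))
  emit(write_tsv_table(eff, file.path(out_dir, "effects.tsv")))
  freqs <- stage("frequencies", {
    f <- population_allele_frequencies(gene_set, dat$panel)
    tibble::as_tibble(cbind(f, eff[c("effect_class", "label")]))
  })
  attr(freqs, "cohorts") <- unique(cohort_label(hapset$meta$population,
                                                hapset$meta$species))
  emit(write_tsv_table(format_frequency_table(freqs),
                       file.path(out_dir, "frequencies.tsv")))
  hifreq <- stage("filter",
    filter_high_frequency(freqs, config$freq_threshold))
  hifreq_missense <- hifreq[hifreq$effect_class == "missense", , drop = FALSE]
  emit(write_tsv_table(format_frequency_table(hifreq_missense),
                       file.path(out_dir, "high_frequency_missense.tsv")))

  # -- clustering ------------------------------------------------------------
  clusters <- stage("cluster", {
    d <- hamming_matrix(hapset, config$gene_region)
    hierarchical_clusters(d, cut_height = config$cut_height,
                          min_cluster_freq = config$min_core_freq)
  })
  emit(write_tsv_table(
    tibble::tibble(haplotype_id = hapset$meta$haplotype_id,
                   sample_id = hapset$meta$sample_id,
                   population = hapset$meta$population,
                   species = hapset$meta$species,
                   cluster = clusters$labels),
    file.path(out_dir, "clusters.tsv")))
  emit(write_tsv_table(cluster_population_summary(clusters, hapset),
                       file.path(out_dir, "cluster_population_summary.tsv")))
  if (nrow(hifreq_missense))
    emit(write_tsv_table(
      cluster_signature_variants(clusters, hapset, hifreq_missense),
      file.path(out_dir, "cluster_signatures.tsv")))

  # -- linkage disequilibrium ------------------------------------------------
  if (nrow(hifreq_missense)) {
    ld <- stage("ld", dprime_matrix(hapset, hifreq_missense))
    emit(write_ld_matrix(ld, file.path(out_dir, "dprime.tsv")))
  } else vlog(verbose, "ld: no high-frequency missense variants, skipped")

  # -- median-joining network ------------------------------------------------
  net <- stage("mjn", median_join(gene_set))
  emit(write_network(net, file.path(out_dir, "network.graphml"), "graphml"))
  comp <- stage("components", components_by_edge_filter(net, config$max_edge))
  emit(write_tsv_table(
    tibble::tibble(haplotype_id = hapset$meta$haplotype_id,
                   component = comp$hap_component),
    file.path(out_dir, "network_components.tsv")))
  conc <- concordance(comp, clusters)

  # -- EHH -------------------------------------------------------------------
  ehh <- stage("ehh",
    ehh_by_population(hapset, config$core_region, config$min_core_freq,
                      config$max_distance, clusters = clusters,
                      verbose = verbose))
  emit(write_tsv_table(ehh$curves, file.path(out_dir, "ehh_curves.tsv")))
  emit(write_tsv_table(ehh$groups, file.path(out_dir, "ehh_group_areas.tsv")))

  # -- summary and manifest --------------------------------------------------
  summary <- tibble::tibble(
    quantity = c("n_haplotypes", "n_gene_sites", "n_high_frequency_missense",
                 "n_named_clusters", "network_concordance"),
    value = c(ncol(hapset$matrix), nrow(gene_set$sites),
              nrow(hifreq_missense),
              length(setdiff(unique(clusters$labels), "wt")), conc))
  emit(write_tsv_table(summary, file.path(out_dir, "summary.tsv")))
  manifest <- tibble::tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)))
  write_tsv_table(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
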