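#' Core-haplotype groups over a core region
#'
#' Partitions haplotypes by their allele pattern across the core region.
#' Without a cluster assignment, the groups are the distinct core
#' haplotypes at frequency `min_core_freq` or above, named `H1..Hm` by
#' decreasing size. With a cluster assignment, each named cluster
#' contributes its core haplotypes (suffixed `.1`, `.2`, ... when a cluster
#' spans several) and the wild-type remainder contributes one group per
#' distinct core haplotype at or above the threshold (`wt.1`, `wt.2`, ...);
#' every group's members are identical across the whole core region.
#'
#' @param hapset a `HaplotypeSet`.
#' @param core the core [region()]; must contain at least one site.
#' @param min_core_freq minimum within-cohort frequency for a group
#'   (default 0.01).
#' @param clusters optional `ClusterAssignment` over the same haplotypes.
#' @return A list of `CoreGroup` objects: each a list with `group_id`,
#'   `members` (haplotype column indices), `frequency`, `core_key` and
#'   `core` (the region).
#' @export
core_groups <- function(hapset, core, min_core_freq = 0.01, clusters = NULL) {
  stopifnot(inherits(hapset, "HaplotypeSet"), inherits(core, "Region"))
  sub <- subset_region(hapset, core)
  if (nrow(sub$sites) == 0L)
    stop("no sites inside the core region", call. = FALSE)
  n <- ncol(sub$matrix)
  keys <- hap_key(sub$matrix)
  make_group <- function(id, members, key)
    structure(list(group_id = id, members = members,
                   frequency = length(members) / n,
                   core_key = key, core = core),
              class = "CoreGroup")
  split_by_key <- function(members, prefix, always_suffix = FALSE) {
    tab <- sort(table(keys[members]), decreasing = TRUE)
    tab <- tab[tab / n >= min_core_freq]
    if (!length(tab)) return(list())
    ids <- if (length(tab) == 1L && !always_suffix) prefix
           else paste0(prefix, ".", seq_along(tab))
    Map(function(id, key) make_group(id, members[keys[members] == key], key),
        ids, names(tab))
  }
  if (is.null(clusters)) {
    tab <- sort(table(keys), decreasing = TRUE)
    tab <- tab[tab / n >= min_core_freq]
    groups <- Map(function(id, key) make_group(id, which(keys == key), key),
                  paste0("H", seq_along(tab)), names(tab))
  } else {
    stopifnot(inherits(clusters, "ClusterAssignment"))
    if (length(clusters$labels) != n)
      stop("cluster assignment covers a different haplotype universe",
           call. = FALSE)
    groups <- list()
    for (lab in setdiff(sort(unique(clusters$labels)), "wt"))
      groups <- c(groups, split_by_key(which(clusters$labels == lab), lab))
    groups <- c(groups, split_by_key(which(clusters$labels == "wt"), "wt",
                                     always_suffix = TRUE))
  }
  unname(groups)
}

#' @export
print.CoreGroup <- function(x, ...) {
  cat(sprintf("<CoreGroup> %s: %d haplotypes (%.1f%%) identical over %s:%d-%d\n",
              x$group_id, length(x$members), 100 * x$frequency,
              x$core$chrom, as.integer(x$core$start), as.integer(x$core$end)))
  invisible(x)
}

#' EHH decay away from the core region
#'
#' Extended haplotype homozygosity for one core group: at each successive
#' polymorphic site beyond the core edge, the `c` group members are
#' partitioned by identity over every site from the core edge through that
#' site, and `EHH = sum_s C(e_s, 2) / C(c, 2)` over the subgroup sizes
#' `e_s` — the probability that two randomly drawn group members are
#' identical over the whole stretch. Identity is cumulative from the core
#' edge, so EHH starts at 1 and never increases with distance; the curve is
#' truncated at `max_distance` or at the first zero. Distances are genomic
#' base pairs from the core edge (the region start leftwards, the region
#' end rightwards); EHH is evaluated at polymorphic site positions and is
#' constant between them.
#'
#' @param hapset the `HaplotypeSet` the group was derived from.
#' @param group a `CoreGroup` with at least two members.
#' @param direction `"left"` or `"right"`.
#' @param max_distance maximum reach in bp from the core edge
#'   (default 200000).
#' @return An `EHHCurve`: tibble with columns `distance` (bp from the core
#'   edge, first row 0), `position` (genomic, `NA` for the core point) and
#'   `ehh`; attributes `direction`, `group_id` and `c` (group size).
#' @export
ehh_decay <- function(hapset, group, direction = c("left", "right"),
                      max_distance = 200000) {
  direction <- match.arg(direction)
  stopifnot(inherits(hapset, "HaplotypeSet"), inherits(group, "CoreGroup"))
  c_n <- length(group$members)
  if (c_n < 2L)
    stop("EHH is undefined for a group of fewer than two haplotypes (C(c,2) = 0)",
         call. = FALSE)
  pos <- hapset$sites$pos
  core <- group$core
  if (direction == "left") {
    idx <- which(hapset$sites$chrom == core$chrom & pos < core$start)
    idx <- idx[order(pos[idx], decreasing = TRUE)]
    dist <- core$start - pos[idx]
  } else {
    idx <- which(hapset$sites$chrom == core$chrom & pos >= core$end)
    idx <- idx[order(pos[idx])]
    dist <- pos[idx] - core$end + 1
  }
  keep <- dist <= max_distance
  idx <- idx[keep]; dist <- dist[keep]
  classes <- rep(1L, c_n)
  denom <- choose(c_n, 2)
  out_d <- 0; out_p <- NA_integer_; out_e <- 1
  for (t in seq_along(idx)) {
    alle <- hapset$matrix[idx[t], group$members]
    key <- paste(classes, alle)
    classes <- match(key, unique(key))
    e <- sum(choose(tabulate(classes), 2)) / denom
    out_d <- c(out_d, dist[t]); out_p <- c(out_p, pos[idx[t]])
    out_e <- c(out_e, e)
    if (e == 0) break
  }
  curve <- tibble::tibble(distance = out_d, position = out_p, ehh = out_e)
  attr(curve, "direction") <- direction
  attr(curve, "group_id") <- group$group_id
  attr(curve, "c") <- c_n
  class(curve) <- c("EHHCurve", class(curve))
  curve
}

#' Area under an EHH decay curve
#'
#' Trapezoidal integral of EHH over genomic distance, in units of base
#' pairs (an EHH of 1 held over a 10 kb flank contributes an area of
#' 10000). Given a list of curves (e.g. the left and right curves of one
#' group) the areas are summed.
#'
#' @param curve an `EHHCurve`, or a list of them.
#' @return Numeric area in bp.
#' @export
ehh_area <- function(curve) {
  if (inherits(curve, "EHHCurve")) curve <- list(curve)
  if (!length(curve) || !all(vapply(curve, inherits, TRUE, "EHHCurve")))
    stop("curve must be an EHHCurve or a non-empty list of them", call. = FALSE)
  sum(vapply(curve, function(cv) {
    if (nrow(cv) == 0L) stop("empty EHH curve", call. = FALSE)
    if (nrow(cv) == 1L) return(0)
    pracma::trapz(cv$distance, cv$ehh)
  }, 0))
}

#' Two-sided EHH areas for every core group
#'
#' Derives the core groups and computes, for each group with at least two
#' members, the summed left + right EHH decay area. When a per-haplotype
#' carrier flag is supplied (e.g. the simulator's truth record for the
#' focal allele), each group's carrier fraction is reported so the
#' focal-carrier group can be identified.
#'
#' @param hapset a `HaplotypeSet`.
#' @param core the core [region()].
#' @param min_core_freq minimum group frequency (default 0.01).
#' @param max_distance EHH reach in bp (default 200000).
#' @param carrier optional logical vector, one per haplotype.
#' @param clusters optional `ClusterAssignment` to define the groups.
#' @return A tibble with `group`, `core_key` (the core allele pattern),
#'   `n`, `frequency`, `area` and (when `carrier` is given)
#'   `carrier_frac`.
#' @export
ehh_group_areas <- function(hapset, core, min_core_freq = 0.01,
                            max_distance = 200000, carrier = NULL,
                            clusters = NULL) {
  groups <- core_groups(hapset, core, min_core_freq, clusters)
  groups <- Filter(function(g) length(g$members) >= 2L, groups)
  if (!length(groups)) return(tibble::tibble(group = character(0),
                                             core_key = character(0),
                                             n = integer(0),
                                             frequency = numeric(0),
                                             area = numeric(0)))
  rows <- lapply(groups, function(g) {
    area <- ehh_area(list(ehh_decay(hapset, g, "left", max_distance),
                          ehh_decay(hapset, g, "right", max_distance)))
    tibble::tibble(group = g$group_id, core_key = g$core_key,
                   n = length(g$members),
                   frequency = g$frequency, area = area,
                   carrier_frac = if (is.null(carrier)) NA_real_
                                  else mean(carrier[g$members]))
  })
  out <- do.call(rbind, rows)
  if (is.null(carrier)) out$carrier_frac <- NULL
  out
}

#' Carrier-versus-wild-type EHH area contrast for one replicate
#'
#' From a group-area table with carrier fractions, identifies the
#' focal-carrier group (the largest group with carrier fraction above 0.5)
#' and summarises its standing: whether its area exceeds that of every
#' non-carrier group, and whether it exceeds that of the size-matched
#' non-carrier group (the one closest in size, which under neutrality is
#' the exchangeable comparison with expected win rate one half). Ties score
#' 0.5.
#'
#' When the table has a `start_freq` column (the group's core-class
#' frequency at the start of a selection epoch, see
#' [simulate_two_phase()]), `min_wt_start_freq` restricts the comparison
#' set to standing wild-type classes — classes already present at that
#' frequency when the epoch began. Clades born during the epoch are
#' necessarily young and carry high EHH areas regardless of selection, so
#' excluding them keeps the comparison symmetric with the (standing,
#' survival-conditioned) carrier class.
#'
#' @param areas output of [ehh_group_areas()] with a `carrier_frac` column
#'   (and optionally `start_freq`).
#' @param min_wt_start_freq minimum starting frequency for wild-type
#'   comparison groups; 0 disables the restriction.
#' @return A one-row tibble: `carrier_area`, `max_wt_area`,
#'   `matched_wt_area`, `win_all`, `win_matched` (each win in
#'   `{0, 0.5, 1}`), or all-`NA` when either side is missing.
#' @export
carrier_area_contrast <- function(areas, min_wt_start_freq = 0) {
  stopifnot("carrier_frac" %in% names(areas))
  na_row <- tibble::tibble(carrier_area = NA_real_, max_wt_area = NA_real_,
                           matched_wt_area = NA_real_, win_all = NA_real_,
                           win_matched = NA_real_)
  carr <- areas[areas$carrier_frac > 0.5, , drop = FALSE]
  wt <- areas[areas$carrier_frac <= 0.5, , drop = FALSE]
  if (min_wt_start_freq > 0 && "start_freq" %in% names(areas))
    wt <- wt[wt$start_freq >= min_wt_start_freq, , drop = FALSE]
  if (nrow(carr) == 0L || nrow(wt) == 0L) return(na_row)
  cg <- carr[which.max(carr$n), , drop = FALSE]
  matched <- wt[which.min(abs(wt$n - cg$n)), , drop = FALSE]
  win <- function(a, b) (a > b) + 0.5 * (a == b)
  tibble::tibble(carrier_area = cg$area, max_wt_area = max(wt$area),
                 matched_wt_area = matched$area,
                 win_all = win(cg$area, max(wt$area)),
                 win_matched = win(cg$area, matched$area))
}

#' EHH decay per population cohort
#'
#' Re-derives the core groups and recomputes the EHH decay curves within
#' each population-by-species cohort independently. Cohort groups with
#' fewer than two members are skipped (reported via `message()` when
#' `verbose`).
#'
#' @param hapset a `HaplotypeSet` spanning one or more cohorts.
#' @param core the core [region()].
#' @param min_core_freq minimum within-cohort group frequency.
#' @param max_distance EHH reach in bp.
#' @param clusters optional `ClusterAssignment` over all haplotypes.
#' @param verbose report skipped groups.
#' @return A list with `curves` — a long tibble (`population`, `group`,
#'   `direction`, `distance`, `position`, `ehh`) — and `groups`, a
#'   per-(population, group) summary with sizes, frequencies and areas.
#' @export
ehh_by_population <- function(hapset, core, min_core_freq = 0.01,
                              max_distance = 200000, clusters = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(hapset, "HaplotypeSet"))
  cohorts <- cohort_label(hapset$meta$population, hapset$meta$species)
  curves <- list(); summaries <- list()
  for (co in unique(cohorts)) {
    cols <- which(cohorts == co)
    sub <- subset_haplotypes(hapset, cols)
    subclust <- NULL
    if (!is.null(clusters)) {
      subclust <- clusters
      subclust$labels <- clusters$labels[cols]
    }
    groups <- core_groups(sub, core, min_core_freq, subclust)
    for (g in groups) {
      if (length(g$members) < 2L) {
        vlog(verbose, "cohort ", co, ": group ", g$group_id,
             " has < 2 haplotypes, skipped")
        next
      }
      cl <- ehh_decay(sub, g, "left", max_distance)
      cr <- ehh_decay(sub, g, "right", max_distance)
      for (cv in list(cl, cr))
        curves[[length(curves) + 1L]] <- tibble::tibble(
          population = co, group = g$group_id,
          direction = attr(cv, "direction"),
          distance = cv$distance, position = cv$position, ehh = cv$ehh)
      summaries[[length(summaries) + 1L]] <- tibble::tibble(
        population = co, group = g$group_id, n = length(g$members),
        frequency = g$frequency, area = ehh_area(list(cl, cr)))
    }
  }
  list(curves = if (length(curves)) do.call(rbind, curves) else
         tibble::tibble(population = character(0), group = character(0),
                        direction = character(0), distance = numeric(0),
                        position = integer(0), ehh = numeric(0)),
       groups = if (length(summaries)) do.call(rbind, summaries) else
         tibble::tibble(population = character(0), group = character(0),
                        n = integer(0), frequency = numeric(0),
                        area = numeric(0)))
}
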