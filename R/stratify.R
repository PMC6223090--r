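# two-sided Welch t-test p, with the degenerate case (both vectors
# constant) resolved to 1 for equal means instead of an error
safe_t_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b)$p.value
}

#' Subset a window set by site index
#'
#' @param windows `summit_windows` object.
#' @param idx Integer or logical index over sites.
#' @return A `summit_windows` containing only the selected sites.
#' @export
subset_windows <- function(windows, idx) {
  structure(list(site_id = windows$site_id[idx],
                 chrom = windows$chrom[idx],
                 summit = windows$summit[idx],
                 flank = windows$flank,
                 offsets = windows$offsets,
                 valid = windows$valid[idx, , drop = FALSE]),
            class = "summit_windows")
}

#' Stratify sites into value quantiles and test each stratum
#'
#' Splits sites into `k` groups at the `i/k` sample quantiles of a
#' per-site value (typically binding intensity), runs the core-vs-flank
#' enrichment test per group (BH across the `k` groups), and reports the
#' Pearson correlation between group mean value and group core mutation
#' rate. Ties at quantile edges are broken by stable site order.
#'
#' @param windows `summit_windows` object.
#' @param mutations Mutation data frame.
#' @param values Numeric vector, one value per site.
#' @param k Number of quantile groups (default 4).
#' @param core_halfwidth,flank_max Enrichment geometry in bp.
#' @return List with `groups` (integer group per site, 1 = lowest),
#'   `table` (per-group enrichment data frame with `mean_value` and
#'   `core_rate`), and `pearson_r`.
#' @export
stratify_by_quantile <- function(windows, mutations, values, k = 4L,
                                 core_halfwidth = 200L, flank_max = 1000L) {
  n <- length(windows$site_id)
  stopifnot(length(values) == n)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of sites")
  if (length(unique(values)) == 1L) {
    warning("all values equal; grouping by stable site order")
    grp <- as.integer(ceiling(seq_len(n) / (n / k)))
  } else {
    # rank with ties broken by original order, then cut into k equal bins
    r <- rank(values, ties.method = "first")
    grp <- as.integer(ceiling(r * k / n))
  }
  res <- list()
  mean_value <- core_rate <- numeric(k)
  for (g in seq_len(k)) {
    w <- subset_windows(windows, grp == g)
    prof <- observed_rate_profile(w, mutations)
    res[[paste0("q", g)]] <- enrichment_test(prof, core_halfwidth, flank_max)
    mean_value[g] <- mean(values[grp == g])
    core <- abs(prof$offsets) <= core_halfwidth
    core_rate[g] <- sum(prof$mut_count[core]) / sum(prof$n_valid[core])
  }
  tab <- enrichment_family(res)
  tab$mean_value <- mean_value
  tab$core_rate <- core_rate
  r_groups <- if (stats::sd(mean_value) == 0 || stats::sd(core_rate) == 0)
    NA_real_ else stats::cor(mean_value, core_rate, method = "pearson")
  list(groups = grp, table = tab, pearson_r = r_groups)
}

#' Stratify sites by patient-sharing class and test each stratum
#'
#' Classifies sites by the number of patient samples sharing them
#' (default classes: patient-specific `= 1`, shared by `2-3`, shared by
#' `> 3`) and runs the enrichment test per class with BH across classes.
#'
#' @param windows `summit_windows` object.
#' @param mutations Mutation data frame.
#' @param sharing_count Integer vector, one sharing count per site.
#' @param edges List of class definitions: named list mapping class label
#'   to an inclusive `c(lo, hi)` range of sharing counts.
#' @param core_halfwidth,flank_max Enrichment geometry in bp.
#' @return List with `classes` (label per site, `NA` if unassigned) and
#'   `table` (per-class enrichment data frame, in `edges` order).
#' @export
stratify_by_sharing <- function(windows, mutations, sharing_count,
                                edges = list("patient_specific" = c(1, 1),
                                             "shared_2" = c(2, 3),
                                             "shared_gt3" = c(4, Inf)),
                                core_halfwidth = 200L, flank_max = 1000L) {
  n <- length(windows$site_id)
  stopifnot(length(sharing_count) == n)
  labels <- rep(NA_character_, n)
  for (nm in names(edges)) {
    rng <- edges[[nm]]
    labels[sharing_count >= rng[1] & sharing_count <= rng[2]] <- nm
  }
  present <- names(edges)[vapply(names(edges), function(nm) any(labels == nm, na.rm = TRUE), TRUE)]
  res <- list()
  for (nm in present) {
    w <- subset_windows(windows, which(labels == nm))
    res[[nm]] <- enrichment_test(observed_rate_profile(w, mutations),
                                 core_halfwidth, flank_max)
  }
  list(classes = labels, table = enrichment_family(res))
}

#' Outcome-group burden comparison by repeated site sampling
#'
#' For each outcome group, repeatedly samples `n_sample` sites without
#' replacement, counts mutations within `core_halfwidth` bp of their
#' summits, and records the per-site mean; group mean vectors are then
#' compared with pairwise two-sided t-tests.
#'
#' @param windows `summit_windows` object.
#' @param mutations Mutation data frame.
#' @param groups Named list of site index vectors (e.g. `good`,
#'   `poor_met`, `core`).
#' @param n_sample Sites sampled per repetition (default 100).
#' @param n_reps Repetitions (default 50).
#' @param core_halfwidth Core half-width in bp (default 200).
#' @param seed Integer seed.
#' @return List with `means` (n_reps x n_groups matrix of rep means),
#'   `group_means`, and `pairwise` (data frame of two-sided t-test
#'   p-values per group pair).
#' @export
outcome_burden_test <- function(windows, mutations, groups, n_sample = 100L,
                                n_reps = 50L, core_halfwidth = 200L, seed) {
  if (missing(seed)) stop("an integer seed is required")
  if (n_reps < 2L) stop("n_reps must be >= 2 for a t-test")
  too_small <- names(groups)[vapply(groups, length, 1L) < n_sample]
  if (length(too_small) > 0L) {
    stop("group(s) smaller than n_sample: ", paste(too_small, collapse = ", "))
  }
  core_counts <- site_core_counts(windows, mutations, core_halfwidth)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  means <- sapply(groups, function(idx) {
    vapply(seq_len(n_reps), function(r) {
      mean(core_counts[idx[sample.int(length(idx), n_sample)]])
    }, numeric(1L))
  })
  nm <- colnames(means)
  pairs <- utils::combn(nm, 2L)
  pairwise <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                         p_value = apply(pairs, 2L, function(pr) {
                           safe_t_p(means[, pr[1L]], means[, pr[2L]])
                         }), stringsAsFactors = FALSE)
  list(means = means, group_means = colMeans(means), pairwise = pairwise)
}

#' Per-site mutation count within the core
#'
#' Counts mutations within `core_halfwidth` bp of each site summit
#' (valid positions only).
#'
#' @param windows `summit_windows` object.
#' @param mutations Mutation data frame.
#' @param core_halfwidth Core half-width in bp (default 200).
#' @return Integer vector, one count per site.
#' @export
site_core_counts <- function(windows, mutations, core_halfwidth = 200L) {
  hits <- map_mutations_to_windows(windows, mutations)
  hits <- hits[abs(hits$offset) <= core_halfwidth, , drop = FALSE]
  tabulate(hits$site_idx, nbins = length(windows$site_id))
}

#' Rank sites by core mutation burden
#'
#' Orders sites by the number of mutations within `core_halfwidth` bp of
#' the summit, reporting the number of distinct mutated donors and
#' whether any exact (position, ref, alt) change recurs in at least two
#' donors.
#'
#' @param windows `summit_windows` object.
#' @param mutations Mutation data frame with `donor_id`.
#' @param core_halfwidth Core half-width in bp (default 200).
#' @return Data frame sorted by decreasing `mut_count` with columns
#'   `site_id`, `chrom`, `summit`, `mut_count`, `n_donors`,
#'   `has_recurrent`.
#' @export
rank_sites_by_burden <- function(windows, mutations, core_halfwidth = 200L) {
  hits <- map_mutations_to_windows(windows, mutations)
  hits <- hits[abs(hits$offset) <= core_halfwidth, , drop = FALSE]
  n <- length(windows$site_id)
  mut_count <- tabulate(hits$site_idx, nbins = n)
  n_donors <- integer(n)
  has_recurrent <- logical(n)
  if (nrow(hits) > 0L) {
    m <- mutations[hits$mut_idx, , drop = FALSE]
    m$site_idx <- hits$site_idx
    n_donors_tab <- tapply(m$donor_id, m$site_idx,
                           function(d) length(unique(d)))
    n_donors[as.integer(names(n_donors_tab))] <- as.integer(n_donors_tab)
    key <- paste(m$site_idx, m$chrom, m$pos, m$ref, m$alt, sep = ":")
    rec <- tapply(m$donor_id, key, function(d) length(unique(d)) >= 2L)
    rec_sites <- unique(as.integer(sub(":.*$", "", names(rec)[rec])))
    has_recurrent[rec_sites] <- TRUE
  }
  out <- data.frame(site_id = windows$site_id, chrom = windows$chrom,
                    summit = windows$summit, mut_count = mut_count,
                    n_donors = n_donors, has_recurrent = has_recurrent,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mut_count, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
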