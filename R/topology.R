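#' Read chromatin loops from a BEDPE file
#'
#' @param path BEDPE path (6+ tab-separated columns, no header); column 7
#'   is kept as an interaction weight when numeric. Unordered duplicate
#'   anchor pairs are removed.
#' @return Data frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `weight` (0-based half-open anchors).
#' @export
read_bedpe <- function(path) {
  empty <- data.frame(chrom_a = character(), start_a = integer(),
                      end_a = integer(), chrom_b = character(),
                      start_b = integer(), end_b = integer(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(readLines(path, n = 1L)) == 0L) return(empty)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(raw) < 6L) stop("BEDPE requires at least 6 columns")
  out <- data.frame(chrom_a = raw[[1L]], start_a = as.integer(raw[[2L]]),
                    end_a = as.integer(raw[[3L]]), chrom_b = raw[[4L]],
                    start_b = as.integer(raw[[5L]]), end_b = as.integer(raw[[6L]]),
                    stringsAsFactors = FALSE)
  # BEDPE convention: column 7 is a name, column 8 a score; accept a bare
  # numeric column 7 as a weight too
  out$weight <- if (ncol(raw) >= 8L) {
    suppressWarnings(as.numeric(raw[[8L]]))
  } else if (ncol(raw) >= 7L) {
    suppressWarnings(as.numeric(raw[[7L]]))
  } else NA_real_
  if (any(out$end_a <= out$start_a) || any(out$end_b <= out$start_b)) {
    stop("anchor with end <= start")
  }
  # canonical anchor order so unordered pairs deduplicate
  key_a <- paste(out$chrom_a, out$start_a, out$end_a)
  key_b <- paste(out$chrom_b, out$start_b, out$end_b)
  swap <- key_b < key_a
  if (any(swap)) {
    tmp <- out[swap, c("chrom_a", "start_a", "end_a")]
    out[swap, c("chrom_a", "start_a", "end_a")] <-
      out[swap, c("chrom_b", "start_b", "end_b")]
    out[swap, c("chrom_b", "start_b", "end_b")] <- tmp
  }
  out <- out[!duplicated(paste(out$chrom_a, out$start_a, out$end_a,
                               out$chrom_b, out$start_b, out$end_b)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write loops as BEDPE
#' @param loops Loop data frame (see [read_bedpe()]).
#' @param path Output path.
#' @export
write_bedpe <- function(loops, path) {
  if (nrow(loops) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- loops[, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")]
  df$name <- "."
  df$weight <- ifelse(is.na(loops$weight), 1, loops$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' Six-column TSV with header: `gene_id`, `chrom`, `start`, `end`
#' (0-based half-open gene body), `strand`, `expression` (median
#' normalized expression across samples).
#'
#' @param path TSV path.
#' @return Data frame with a derived 1-based `tss` column.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "start", "end", "strand", "expression")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("gene table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id")
  if (any(df$expression < 0)) stop("negative expression")
  df$tss <- ifelse(df$strand == "-", df$end, df$start + 1L)
  df
}

# anchors of a loop set as a 2n-row GRanges with loop index metadata
loop_anchor_granges <- function(loops) {
  GenomicRanges::GRanges(
    seqnames = c(loops$chrom_a, loops$chrom_b),
    ranges = IRanges::IRanges(start = c(loops$start_a, loops$start_b) + 1L,
                              end = c(loops$end_a, loops$end_b)),
    loop = rep(seq_len(nrow(loops)), 2L),
    side = rep(c(1L, 2L), each = nrow(loops)))
}

#' Chromatin contact frequency per site
#'
#' Counts, per site, the loops with at least 1 bp overlap between the
#' site interval and either anchor; a loop touching both anchors is
#' counted once.
#'
#' @param sites Interval data frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param loops Loop data frame (see [read_bedpe()]).
#' @return Integer vector of loop counts, one per site.
#' @export
contact_frequency <- function(sites, loops) {
  n <- nrow(sites)
  if (n == 0L || nrow(loops) == 0L) return(integer(n))
  site_gr <- intervals_to_granges(sites)
  anchors <- loop_anchor_granges(loops)
  hits <- GenomicRanges::findOverlaps(site_gr, anchors)
  if (length(hits) == 0L) return(integer(n))
  pair <- unique(data.frame(site = S4Vectors::queryHits(hits),
                            loop = anchors$loop[S4Vectors::subjectHits(hits)]))
  tabulate(pair$site, nbins = n)
}

#' Topologically associated target genes of one site
#'
#' Genes whose body overlaps the distal anchor of any loop whose other
#' anchor overlaps the site, restricted to genes lying in the same
#' topological domain (TAD) as the site summit. A site in no TAD has no
#' topological targets.
#'
#' @param site One-row interval data frame with `chrom`, `start`, `end`
#'   and 1-based `summit`.
#' @param loops Loop data frame.
#' @param tads TAD interval data frame (non-overlapping).
#' @param genes Gene table (see [read_gene_table()]).
#' @return Character vector of gene ids (possibly empty).
#' @export
topo_target_genes <- function(site, loops, tads, genes) {
  sets <- topo_target_gene_sets(site, loops, tads, genes)
  sets[[1L]]
}

# vectorized engine: per-site list of topological target gene ids
topo_target_gene_sets <- function(sites, loops, tads, genes) {
  n <- nrow(sites)
  empty <- replicate(n, character(0), simplify = FALSE)
  if (nrow(loops) == 0L || nrow(tads) == 0L || nrow(genes) == 0L) return(empty)
  site_gr <- intervals_to_granges(sites)
  summit_gr <- GenomicRanges::GRanges(sites$chrom,
    IRanges::IRanges(sites$summit, width = 1L))
  tad_gr <- intervals_to_granges(tads)
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end))
  anchors <- loop_anchor_granges(loops)
  # TAD of each summit (at most one, TADs non-overlapping)
  site_tad <- GenomicRanges::findOverlaps(summit_gr, tad_gr, select = "first")
  gene_tads <- GenomicRanges::findOverlaps(gene_gr, tad_gr)
  gene_tad_keys <- paste(S4Vectors::queryHits(gene_tads),
                         S4Vectors::subjectHits(gene_tads))
  # site -> loops via either anchor
  sl <- GenomicRanges::findOverlaps(site_gr, anchors)
  if (length(sl) == 0L) return(empty)
  sl_df <- data.frame(site = S4Vectors::queryHits(sl),
                      loop = anchors$loop[S4Vectors::subjectHits(sl)],
                      side = anchors$side[S4Vectors::subjectHits(sl)])
  # distal anchor = the other side of each matched loop
  distal <- GenomicRanges::GRanges(
    ifelse(sl_df$side == 1L, loops$chrom_b[sl_df$loop], loops$chrom_a[sl_df$loop]),
    IRanges::IRanges(
      ifelse(sl_df$side == 1L, loops$start_b[sl_df$loop], loops$start_a[sl_df$loop]) + 1L,
      ifelse(sl_df$side == 1L, loops$end_b[sl_df$loop], loops$end_a[sl_df$loop])))
  dg <- GenomicRanges::findOverlaps(distal, gene_gr)
  if (length(dg) == 0L) return(empty)
  cand <- data.frame(site = sl_df$site[S4Vectors::queryHits(dg)],
                     gene = S4Vectors::subjectHits(dg))
  cand <- unique(cand)
  # same-TAD conjunction
  cand_tad <- site_tad[cand$site]
  ok <- !is.na(cand_tad) & paste(cand$gene, cand_tad) %in% gene_tad_keys
  cand <- cand[ok, , drop = FALSE]
  out <- empty
  if (nrow(cand) > 0L) {
    sp <- split(genes$gene_id[cand$gene], cand$site)
    for (nm in names(sp)) out[[as.integer(nm)]] <- unique(sp[[nm]])
  }
  out
}

# per-site list of genes with TSS-agnostic body overlap of summit +/- dist
proximity_target_gene_sets <- function(sites, genes, distance_bp) {
  n <- nrow(sites)
  out <- replicate(n, character(0), simplify = FALSE)
  if (nrow(genes) == 0L) return(out)
  win_gr <- GenomicRanges::GRanges(sites$chrom,
    IRanges::IRanges(pmax(sites$summit - distance_bp, 1L),
                     sites$summit + distance_bp))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(win_gr, gene_gr)
  if (length(hits) == 0L) return(out)
  sp <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  for (nm in names(sp)) out[[as.integer(nm)]] <- unique(sp[[nm]])
  out
}

#' Target-gene expression by site mutation group
#'
#' Groups sites by core mutation count (0, 1, 2, >= 3), then per group:
#' samples `n_region_sample` sites `n_region_reps` times, pools the
#' (deduplicated) target genes of all sampled sites — topological
#' (loop + same-TAD) or linear-proximity targets depending on `mode` —
#' then draws `n_gene_sample` genes `n_gene_reps` times (without
#' replacement within a draw) recording the mean expression per draw.
#' Group mean vectors are compared with pairwise two-sided t-tests.
#'
#' @param sites Interval data frame with `summit` and `mut_count`
#'   columns (core mutation count per site, e.g. from
#'   [site_core_counts()]).
#' @param loops,tads,genes Topology inputs (ignored by proximity modes
#'   except `genes`).
#' @param mode One of `"topological"`, `"proximity_50kb"`,
#'   `"proximity_100kb"`.
#' @param n_region_sample,n_region_reps Region sampling parameters
#'   (defaults 500 and 10).
#' @param n_gene_sample,n_gene_reps Gene sampling parameters (defaults
#'   200 and 100).
#' @param seed Integer seed.
#' @return Object of class `expression_comparison`: list with `mode`,
#'   `group_sizes`, `pool_sizes`, `means` (n_gene_reps x 4 matrix),
#'   `pairwise` (two-sided t-test p per group pair).
#' @export
expression_by_mutation_group <- function(sites, loops, tads, genes,
                                         mode = c("topological", "proximity_50kb", "proximity_100kb"),
                                         n_region_sample = 500L,
                                         n_region_reps = 10L,
                                         n_gene_sample = 200L,
                                         n_gene_reps = 100L, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("an integer seed is required")
  if (n_gene_reps < 2L) stop("n_gene_reps must be >= 2 for a t-test")
  if (is.null(sites$mut_count)) stop("sites must carry a mut_count column")
  grp <- cut(sites$mut_count, breaks = c(-Inf, 0, 1, 2, Inf),
             labels = c("0", "1", "2", "3+"))
  sizes <- table(grp)
  small <- names(sizes)[sizes < n_region_sample]
  if (length(small) > 0L) {
    stop("mutation group(s) with fewer than n_region_sample sites: ",
         paste(small, collapse = ", "))
  }
  target_sets <- switch(mode,
    topological = topo_target_gene_sets(sites, loops, tads, genes),
    proximity_50kb = proximity_target_gene_sets(sites, genes, 50000L),
    proximity_100kb = proximity_target_gene_sets(sites, genes, 100000L))
  expr <- stats::setNames(genes$expression, genes$gene_id)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  levels4 <- levels(grp)
  means <- matrix(NA_real_, nrow = n_gene_reps, ncol = length(levels4),
                  dimnames = list(NULL, levels4))
  pool_sizes <- stats::setNames(integer(length(levels4)), levels4)
  for (g in levels4) {
    idx <- which(grp == g)
    sampled <- unlist(lapply(seq_len(n_region_reps), function(r) {
      idx[sample.int(length(idx), n_region_sample)]
    }))
    pool <- unique(unlist(target_sets[sampled]))
    pool_sizes[g] <- length(pool)
    if (length(pool) < n_gene_sample) {
      stop("gene pool for mutation group ", g, " has ", length(pool),
           " genes; n_gene_sample = ", n_gene_sample)
    }
    pe <- expr[pool]
    means[, g] <- vapply(seq_len(n_gene_reps), function(r) {
      mean(pe[sample.int(length(pe), n_gene_sample)])
    }, numeric(1L))
  }
  pairs <- utils::combn(levels4, 2L)
  pairwise <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                         p_value = apply(pairs, 2L, function(pr) {
                           safe_t_p(means[, pr[1L]], means[, pr[2L]])
                         }), stringsAsFactors = FALSE)
  structure(list(mode = mode, group_sizes = as.integer(sizes),
                 pool_sizes = pool_sizes, means = means, pairwise = pairwise),
            class = "expression_comparison")
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat("expression_comparison (", x$mode, "): group means ",
      paste(signif(colMeans(x$means), 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}
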