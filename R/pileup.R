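#' Read a text pileup table
#'
#' Documented per-read pileup format: tab-separated with header, columns
#' `chrom`, `pos` (1-based), `base` (A/C/G/T, N, or `*` for a
#' deletion/reference skip), `baseq`, `mapq`, `sample`. One row per read
#' observation at a position.
#'
#' @param path TSV path.
#' @return Data frame with those columns.
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "base", "baseq", "mapq", "sample")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("pileup missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df
}

#' Count alleles at candidate positions from a pileup
#'
#' Tallies read bases per candidate position after base- and
#' mapping-quality filtering. Reads showing a deletion or reference skip
#' at the position (base `*`), or an N, count toward `count_other`.
#' Merged-group analysis is modeled by concatenating the pileups of a
#' group's samples before counting.
#'
#' @param pileup Pileup data frame (see [read_pileup()]) or path to one.
#' @param candidate_positions Data frame with `chrom` and 1-based `pos`.
#' @param min_baseq Minimum base quality (default 13).
#' @param min_mapq Minimum mapping quality (default 0).
#' @return Data frame, one row per candidate position: `chrom`, `pos`,
#'   `depth`, `A`, `C`, `G`, `T`, `count_other`.
#' @export
count_alleles <- function(pileup, candidate_positions, min_baseq = 13L,
                          min_mapq = 0L) {
  if (is.character(pileup)) pileup <- read_pileup(pileup)
  keep <- pileup$baseq >= min_baseq & pileup$mapq >= min_mapq
  pp <- pileup[keep, , drop = FALSE]
  key <- paste(candidate_positions$chrom, candidate_positions$pos)
  pkey <- paste(pp$chrom, pp$pos)
  idx <- match(pkey, key)
  pp <- pp[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  n <- nrow(candidate_positions)
  out <- data.frame(chrom = candidate_positions$chrom,
                    pos = candidate_positions$pos,
                    depth = 0L, A = 0L, C = 0L, G = 0L, T = 0L,
                    count_other = 0L, stringsAsFactors = FALSE)
  if (nrow(pp) > 0L) {
    for (b in c("A", "C", "G", "T")) {
      tb <- tabulate(idx[pp$base == b], nbins = n)
      out[[b]] <- as.integer(tb)
    }
    out$count_other <- as.integer(tabulate(idx[!pp$base %in% c("A", "C", "G", "T")],
                                           nbins = n))
    out$depth <- out$A + out$C + out$G + out$T + out$count_other
  }
  out
}

#' Screen allele counts for potential somatic mutations
#'
#' Applies the coverage/allele filter used when mining candidate variant
#' positions from ChIP-seq alignments: a position passes iff it is
#' covered by at least `min_depth` reads and both the reference and the
#' alternative allele from the external somatic catalog are observed at
#' least once.
#'
#' @param counts Allele-count data frame (see [count_alleles()]).
#' @param known_alleles Data frame aligned to `counts` rows (or joined on
#'   `chrom` + `pos`) with `ref` and `alt` single-base alleles.
#' @param min_depth Minimum read depth (default 10).
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `ref_count`, `alt_count`, `passes_filter`.
#' @export
call_potential_somatic <- function(counts, known_alleles, min_depth = 10L) {
  if (!all(c("ref", "alt") %in% names(known_alleles))) {
    stop("known_alleles must carry ref and alt columns")
  }
  if (all(c("chrom", "pos") %in% names(known_alleles))) {
    idx <- match(paste(counts$chrom, counts$pos),
                 paste(known_alleles$chrom, known_alleles$pos))
    if (anyNA(idx)) stop("candidate position missing from known_alleles")
    known_alleles <- known_alleles[idx, , drop = FALSE]
  } else if (nrow(known_alleles) == 1L && nrow(counts) > 1L) {
    known_alleles <- known_alleles[rep(1L, nrow(counts)), , drop = FALSE]
  } else if (nrow(known_alleles) != nrow(counts)) {
    stop("known_alleles must align with counts")
  }
  if (any(known_alleles$ref == known_alleles$alt)) stop("alt equals ref")
  base_cols <- as.matrix(counts[, c("A", "C", "G", "T")])
  ref_count <- base_cols[cbind(seq_len(nrow(counts)),
                               match(known_alleles$ref, c("A", "C", "G", "T")))]
  alt_count <- base_cols[cbind(seq_len(nrow(counts)),
                               match(known_alleles$alt, c("A", "C", "G", "T")))]
  data.frame(chrom = counts$chrom, pos = counts$pos,
             ref = known_alleles$ref, alt = known_alleles$alt,
             depth = counts$depth, ref_count = ref_count,
             alt_count = alt_count,
             passes_filter = counts$depth >= min_depth &
               ref_count >= 1L & alt_count >= 1L,
             stringsAsFactors = FALSE)
}

#' Fraction of outcome-class sites carrying a passing call
#'
#' @param calls Call data frame (see [call_potential_somatic()]) with an
#'   added `site_id` column mapping each position to its site.
#' @param site_groups Named list mapping outcome class (e.g. `good`,
#'   `poor_met`) to a character vector of site ids in that class.
#' @return Named numeric vector: per class, the fraction of its sites
#'   containing at least one passing call (`NA` for an empty class).
#' @export
outcome_fraction <- function(calls, site_groups) {
  if (is.null(calls$site_id)) stop("calls must carry a site_id column")
  passing_sites <- unique(calls$site_id[calls$passes_filter])
  vapply(site_groups, function(ids) {
    if (length(ids) == 0L) return(NA_real_)
    mean(ids %in% passing_sites)
  }, numeric(1L))
}
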