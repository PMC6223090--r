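#' Build summit-centered analysis windows with exclusion masking
#'
#' Extends each site's summit by `flank` bp on both sides and applies the
#' exclusion filters used before rate profiling: positions overlapping
#' coding sequence, blacklisted regions, or low-mappability regions are
#' masked wherever they fall in the window; other-TF binding sites mask
#' only flank positions (`|offset| > core_halfwidth`), since the site
#' core itself is expected to be bound by the focal factor. Sites whose
#' core overlaps a hard exclusion region are dropped entirely by default.
#'
#' @param sites Data frame with `chrom` and 1-based `summit` (e.g. from
#'   [read_interval_file()] with the narrowPeak dialect); an optional
#'   `site_id` column is carried through (row index otherwise).
#' @param flank Window half-width in bp (window = summit +/- flank).
#' @param exclude_sets Named list of interval data frames; recognised
#'   names: `coding`, `blacklist`, `low_mappability` (hard exclusions)
#'   and `other_tf` (flank-only).
#' @param core_halfwidth Core half-width in bp used for the flank-only
#'   rule and the core-overlap drop rule (default 200).
#' @param drop_excluded_cores Drop sites whose core overlaps a hard
#'   exclusion region (default `TRUE`); if `FALSE` such positions are
#'   only masked.
#' @return An object of class `summit_windows`: list with `site_id`,
#'   `chrom`, `summit`, `flank`, `offsets` (`-flank:flank`) and `valid`
#'   (n_sites x n_offsets logical mask).
#' @export
build_analysis_windows <- function(sites, flank, exclude_sets = list(),
                                   core_halfwidth = 200L,
                                   drop_excluded_cores = TRUE) {
  if (flank <= 0L) stop("flank must be positive")
  n <- nrow(sites)
  if (n == 0L) stop("no sites supplied")
  if (is.null(sites$summit)) stop("sites must carry a summit column")
  site_id <- if (!is.null(sites$site_id)) as.character(sites$site_id)
             else as.character(seq_len(n))
  offsets <- seq.int(-flank, flank)
  n_off <- length(offsets)
  valid <- matrix(TRUE, nrow = n, ncol = n_off)
  hard <- c("coding", "blacklist", "low_mappability")
  win_gr <- GenomicRanges::GRanges(sites$chrom,
    IRanges::IRanges(sites$summit - flank, sites$summit + flank))
  mask_hits <- function(excl, flank_only) {
    if (is.null(excl) || nrow(excl) == 0L) return(NULL)
    gr <- intervals_to_granges(excl)
    hits <- GenomicRanges::findOverlaps(win_gr, gr)
    if (length(hits) == 0L) return(NULL)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    # overlap of exclusion interval with window, in offset coordinates
    lo <- pmax(GenomicRanges::start(gr)[si] - sites$summit[qi], -flank)
    hi <- pmin(GenomicRanges::end(gr)[si] - sites$summit[qi], flank)
    for (k in seq_along(qi)) {
      off <- lo[k]:hi[k]
      if (flank_only) off <- off[abs(off) > core_halfwidth]
      if (length(off) > 0L) valid[qi[k], off + flank + 1L] <<- FALSE
    }
    data.frame(site = qi, lo = lo, hi = hi)
  }
  core_hit <- rep(FALSE, n)
  for (nm in names(exclude_sets)) {
    flank_only <- identical(nm, "other_tf")
    ov <- mask_hits(exclude_sets[[nm]], flank_only)
    if (!flank_only && !is.null(ov)) {
      touches_core <- ov$lo <= core_halfwidth & ov$hi >= -core_halfwidth
      core_hit[unique(ov$site[touches_core])] <- TRUE
    }
  }
  keep <- if (drop_excluded_cores) !core_hit else rep(TRUE, n)
  structure(list(site_id = site_id[keep],
                 chrom = sites$chrom[keep],
                 summit = as.integer(sites$summit[keep]),
                 flank = as.integer(flank),
                 offsets = offsets,
                 valid = valid[keep, , drop = FALSE]),
            class = "summit_windows")
}

#' @export
print.summit_windows <- function(x, ...) {
  cat("summit_windows:", length(x$site_id), "sites, flank", x$flank, "bp;",
      sum(x$valid), "of", length(x$valid), "positions valid\n")
  invisible(x)
}

# map mutation positions to (site, offset) pairs within windows.
# Returns a data frame (mut_idx, site_idx, offset) including only
# mutations landing at valid positions of some window.
map_mutations_to_windows <- function(windows, mutations) {
  if (nrow(mutations) == 0L) {
    return(data.frame(mut_idx = integer(), site_idx = integer(),
                      offset = integer()))
  }
  flank <- windows$flank
  mut_gr <- GenomicRanges::GRanges(mutations$chrom,
    IRanges::IRanges(mutations$pos, width = 1L))
  win_gr <- GenomicRanges::GRanges(windows$chrom,
    IRanges::IRanges(windows$summit - flank, windows$summit + flank))
  hits <- GenomicRanges::findOverlaps(mut_gr, win_gr)
  mi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  off <- mutations$pos[mi] - windows$summit[si]
  ok <- windows$valid[cbind(si, off + flank + 1L)]
  data.frame(mut_idx = mi[ok], site_idx = si[ok], offset = off[ok])
}
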