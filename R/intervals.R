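#' Read genomic intervals from a BED-family file
#'
#' Parses BED3, BED6 or ENCODE narrowPeak files into a data frame of
#' 0-based half-open intervals. For narrowPeak input the summit column
#' (column 10, the 0-based offset of the point source from the interval
#' start) is converted to an absolute 1-based summit position; when the
#' offset is absent (`-1`) the interval midpoint is used, ties to the
#' lower coordinate.
#'
#' @param path Path to a tab-separated interval file without header.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @return A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) plus, depending on dialect, `name`, `score`, `strand`,
#'   and for narrowPeak `signal`, `pvalue`, `qvalue`, `summit` (1-based).
#' @export
read_interval_file <- function(path, dialect = c("bed3", "bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  min_cols <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_interval_frame(dialect))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_cols)
  if (length(bad) > 0L) {
    stop("malformed line ", bad[1L], ": expected >= ", min_cols,
         " tab-separated columns, found ", nf[bad[1L]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer coordinate at line ", which(is.na(start) | is.na(end))[1L])
  }
  bad <- which(end <= start | start < 0L)
  if (length(bad) > 0L) {
    stop("end <= start at line ", bad[1L])
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (dialect %in% c("bed6", "narrowPeak")) {
    out$name <- vapply(fields, `[[`, "", 4L)
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    out$strand <- vapply(fields, `[[`, "", 6L)
  }
  if (dialect == "narrowPeak") {
    out$signal <- as.numeric(vapply(fields, `[[`, "", 7L))
    out$pvalue <- as.numeric(vapply(fields, `[[`, "", 8L))
    out$qvalue <- as.numeric(vapply(fields, `[[`, "", 9L))
    peak <- as.integer(vapply(fields, `[[`, "", 10L))
    out$summit <- ifelse(peak >= 0L, out$start + peak + 1L,
                         midpoint_summit(out$start, out$end))
  }
  out
}

empty_interval_frame <- function(dialect) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  if (dialect %in% c("bed6", "narrowPeak")) {
    out$name <- character(); out$score <- numeric(); out$strand <- character()
  }
  if (dialect == "narrowPeak") {
    out$signal <- numeric(); out$pvalue <- numeric(); out$qvalue <- numeric()
    out$summit <- integer()
  }
  out
}

# 1-based midpoint of a 0-based half-open interval; ties to lower coordinate
midpoint_summit <- function(start, end) {
  as.integer(start + floor((end - start - 1L) / 2L) + 1L)
}

#' Write genomic intervals to a BED-family file
#'
#' Inverse of [read_interval_file()]; round trips are identity for the
#' columns the dialect carries.
#'
#' @param intervals Data frame as returned by [read_interval_file()].
#' @param path Output path.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @export
write_interval_file <- function(intervals, path,
                                dialect = c("bed3", "bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  df <- data.frame(intervals$chrom, intervals$start, intervals$end)
  if (dialect %in% c("bed6", "narrowPeak")) {
    df$name <- if (is.null(intervals$name)) "." else intervals$name
    df$score <- if (is.null(intervals$score)) 0 else intervals$score
    df$strand <- if (is.null(intervals$strand)) "." else intervals$strand
  }
  if (dialect == "narrowPeak") {
    df$signal <- if (is.null(intervals$signal)) 0 else intervals$signal
    df$pvalue <- if (is.null(intervals$pvalue)) -1 else intervals$pvalue
    df$qvalue <- if (is.null(intervals$qvalue)) -1 else intervals$qvalue
    df$peak <- if (is.null(intervals$summit)) -1L else
      as.integer(intervals$summit - 1L - intervals$start)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal: 0-based half-open interval data frame -> GRanges (1-based closed)
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
}

# internal: merge overlapping/adjacent intervals within one sample
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Multi-sample interval intersection with sharing counts
#'
#' Partitions the union of per-sample interval sets into maximal segments
#' of constant sample membership (the classic multi-way intersection used
#' to classify binding sites by how many patient samples share them).
#' Each sample's intervals are merged internally first; adjacent output
#' segments with identical membership are merged.
#'
#' @param sample_interval_lists Named (or unnamed) list of interval data
#'   frames (`chrom`, `start`, `end`; 0-based half-open), one per sample.
#' @return A data frame of non-overlapping segments with columns `chrom`,
#'   `start`, `end`, `sharing_count`, and one logical membership column
#'   per sample (`in_<sample>`).
#' @export
multi_intersect <- function(sample_interval_lists) {
  if (length(sample_interval_lists) == 0L) stop("no samples supplied")
  nms <- names(sample_interval_lists)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- paste0("s", seq_along(sample_interval_lists))
  }
  merged <- lapply(sample_interval_lists, merge_intervals)
  # sweep line per chromosome over all boundary coordinates
  all_chroms <- unique(unlist(lapply(merged, function(m) m$chrom)))
  res <- list()
  for (ch in all_chroms) {
    per <- lapply(merged, function(m) m[m$chrom == ch, , drop = FALSE])
    bounds <- sort(unique(unlist(lapply(per, function(m) c(m$start, m$end)))))
    if (length(bounds) < 2L) next
    seg_start <- bounds[-length(bounds)]
    seg_end <- bounds[-1L]
    memb <- vapply(per, function(m) {
      if (nrow(m) == 0L) return(rep(FALSE, length(seg_start)))
      # segment covered iff its start falls inside some merged interval
      idx <- findInterval(seg_start, m$start)
      idx > 0L & seg_start < m$end[pmax(idx, 1L)]
    }, logical(length(seg_start)))
    if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1L)
    count <- rowSums(memb)
    keep <- count > 0L
    if (!any(keep)) next
    df <- data.frame(chrom = ch, start = seg_start[keep], end = seg_end[keep],
                     sharing_count = as.integer(count[keep]),
                     stringsAsFactors = FALSE)
    mm <- memb[keep, , drop = FALSE]
    colnames(mm) <- paste0("in_", nms)
    df <- cbind(df, as.data.frame(mm))
    # merge adjacent segments with identical membership
    key <- apply(mm, 1L, paste, collapse = "")
    run <- cumsum(c(TRUE, df$start[-1L] != df$end[-nrow(df)] |
                      key[-1L] != key[-length(key)]))
    first <- !duplicated(run)
    out <- df[first, , drop = FALSE]
    out$end <- as.integer(tapply(df$end, run, max))
    res[[ch]] <- out
  }
  if (length(res) == 0L) {
    stop("no intervals in any sample")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate sites by genomic context
#'
#' Labels each site `promoter`, `intronic` or `intergenic` from its summit
#' position relative to a gene table, with precedence
#' promoter > intronic > intergenic. The promoter window is
#' `[TSS - upstream, TSS + downstream]` on the gene's strand.
#'
#' @param sites Data frame with a 1-based `summit` column and `chrom`.
#' @param gene_table Gene data frame with `chrom`, `start`, `end` (0-based
#'   half-open gene body), `strand` (`+`/`-`).
#' @param promoter_upstream_bp,promoter_downstream_bp Promoter window
#'   extent around the TSS in bp.
#' @return Character vector of labels, one per site.
#' @export
annotate_genomic_context <- function(sites, gene_table,
                                     promoter_upstream_bp = 2000L,
                                     promoter_downstream_bp = 500L) {
  n <- nrow(sites)
  labels <- rep("intergenic", n)
  if (nrow(gene_table) == 0L || n == 0L) return(labels)
  tss1 <- ifelse(gene_table$strand == "-", gene_table$end, gene_table$start + 1L)
  prom_lo <- ifelse(gene_table$strand == "-",
                    tss1 - promoter_downstream_bp, tss1 - promoter_upstream_bp)
  prom_hi <- ifelse(gene_table$strand == "-",
                    tss1 + promoter_upstream_bp, tss1 + promoter_downstream_bp)
  summit_gr <- GenomicRanges::GRanges(sites$chrom,
    IRanges::IRanges(sites$summit, width = 1L))
  prom_gr <- GenomicRanges::GRanges(gene_table$chrom,
    IRanges::IRanges(pmax(prom_lo, 1L), prom_hi))
  body_gr <- GenomicRanges::GRanges(gene_table$chrom,
    IRanges::IRanges(gene_table$start + 1L, gene_table$end))
  # disjoint chromosome sets are a legitimate no-overlap case, not a warning
  in_body <- suppressWarnings(IRanges::overlapsAny(summit_gr, body_gr))
  in_prom <- suppressWarnings(IRanges::overlapsAny(summit_gr, prom_gr))
  labels[in_body] <- "intronic"
  labels[in_prom] <- "promoter"
  labels
}
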