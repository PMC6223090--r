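#' Observed mutation-rate profile around summits
#'
#' For each offset in `-flank:flank`, the observed rate is the number of
#' mutations landing at that offset across all sites (valid positions
#' only) divided by the number of valid positions at that offset.
#' Insertions and deletions are assigned to their 1-based start
#' position; mutations at masked positions are ignored.
#'
#' @param windows `summit_windows` object.
#' @param mutations Mutation data frame.
#' @param mut_types Mutation types to include (subset of SNV, INS, DEL).
#' @return Object of class `rate_profile`: list with `offsets`,
#'   `mut_count`, `n_valid`, `rate` (`NA` where no valid positions),
#'   `n_sites`, `mut_types`.
#' @export
observed_rate_profile <- function(windows, mutations, mut_types = "SNV") {
  stopifnot(all(mut_types %in% c("SNV", "INS", "DEL")))
  muts <- mutations[mutations$mut_type %in% mut_types, , drop = FALSE]
  hits <- map_mutations_to_windows(windows, muts)
  n_off <- length(windows$offsets)
  counts <- tabulate(hits$offset + windows$flank + 1L, nbins = n_off)
  n_valid <- colSums(windows$valid)
  rate <- ifelse(n_valid > 0L, counts / n_valid, NA_real_)
  structure(list(offsets = windows$offsets, mut_count = counts,
                 n_valid = n_valid, rate = rate,
                 n_sites = length(windows$site_id), mut_types = mut_types),
            class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, ...) {
  cat("rate_profile: ", x$n_sites, " sites, offsets ", min(x$offsets), "..",
      max(x$offsets), ", ", sum(x$mut_count), " mutations (",
      paste(x$mut_types, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

# pyrimidine-collapsed trinucleotide context codes (1..32, order of
# trinuc_contexts()) for 1-based positions; NA at N or contig edges.
# Chromosome strings are decoded once per unique chromosome.
context_codes <- function(genome, chrom, pos) {
  base_code <- rep(NA_integer_, 128L)
  base_code[utf8ToInt("A")] <- 0L; base_code[utf8ToInt("C")] <- 1L
  base_code[utf8ToInt("G")] <- 2L; base_code[utf8ToInt("T")] <- 3L
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    codes <- base_code[utf8ToInt(as.character(genome[[ch]]))]
    p <- pos[i]
    ok <- p >= 2L & p <= length(codes) - 1L
    b0 <- rep(NA_integer_, length(p)); b1 <- b0; b2 <- b0
    b0[ok] <- codes[p[ok] - 1L]
    b1[ok] <- codes[p[ok]]
    b2[ok] <- codes[p[ok] + 1L]
    pyr <- b1 %in% c(1L, 3L)
    x <- ifelse(pyr, b0, 3L - b2)
    y <- ifelse(pyr, b2, 3L - b0)
    r <- ifelse(pyr, b1, 3L - b1)
    idx <- ifelse(r == 3L, 16L, 0L) + x * 4L + y + 1L
    idx[is.na(b0) | is.na(b1) | is.na(b2)] <- NA_integer_
    out[i] <- idx
  }
  out
}

# context index (1..32) of each of the 96 classes, in class order
class_context_index <- function() {
  s <- rep(1:6, each = 16L)
  ifelse(s > 3L, 16L, 0L) + ((seq_len(96L) - 1L) %% 16L) + 1L
}

#' Context-expected mutation-rate profile by constrained resampling
#'
#' Estimates the mutation rate expected from sequence composition alone:
#' in each resample, for every trinucleotide substitution class the
#' model's observed count of that class is placed uniformly at random
#' (without replacement within a resample) among valid window positions
#' whose pyrimidine-collapsed reference trinucleotide matches the class.
#' The expected rate at an offset is the mean placed count over
#' resamples divided by the number of valid positions at that offset.
#'
#' @param windows `summit_windows` object.
#' @param genome `DNAStringSet`.
#' @param model `trinuc_model` fitted on the same window set.
#' @param n_resamples Number of resampling rounds (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return A `rate_profile` whose `rate` is the expected rate and whose
#'   `mut_count` is the mean placed count per offset.
#' @export
expected_rate_profile <- function(windows, genome, model,
                                  n_resamples = 1000L, seed) {
  if (missing(seed)) stop("an integer seed is required")
  stopifnot(inherits(model, "trinuc_model"))
  flank <- windows$flank
  n_off <- length(windows$offsets)
  valid_idx <- which(windows$valid, arr.ind = TRUE)
  site_i <- valid_idx[, 1L]
  off_i <- valid_idx[, 2L]
  abspos <- windows$summit[site_i] + (off_i - flank - 1L)
  ctx <- context_codes(genome, windows$chrom[site_i], abspos)
  ctx_counts <- as.integer(rowsum(model$counts, class_context_index())[, 1L])
  # positions grouped by context
  keep <- !is.na(ctx)
  off_i <- off_i[keep]; ctx <- ctx[keep]
  by_ctx <- split(seq_along(ctx), ctx)
  for (cx in seq_len(32L)) {
    avail <- length(by_ctx[[as.character(cx)]])
    if (ctx_counts[cx] > avail) {
      classes <- trinuc_classes()[class_context_index() == cx &
                                    model$counts > 0L]
      stop("context ", trinuc_contexts()[cx], " (classes ",
           paste(classes, collapse = ","), "): ", ctx_counts[cx],
           " mutations to place but only ", avail, " matching positions")
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  acc <- numeric(n_off)
  for (r in seq_len(n_resamples)) {
    for (cx in seq_len(32L)) {
      cnt <- ctx_counts[cx]
      if (cnt == 0L) next
      pool <- by_ctx[[as.character(cx)]]
      picked <- pool[sample.int(length(pool), cnt)]
      acc <- acc + tabulate(off_i[picked], nbins = n_off)
    }
  }
  mean_count <- acc / n_resamples
  n_valid <- colSums(windows$valid)
  rate <- ifelse(n_valid > 0L, mean_count / n_valid, NA_real_)
  structure(list(offsets = windows$offsets, mut_count = mean_count,
                 n_valid = n_valid, rate = rate,
                 n_sites = length(windows$site_id),
                 mut_types = "SNV", n_resamples = n_resamples),
            class = "rate_profile")
}

#' Write a rate profile as TSV
#'
#' @param profile `rate_profile` object.
#' @param path Output path.
#' @export
write_rate_profile <- function(profile, path) {
  utils::write.table(
    data.frame(offset = profile$offsets, mut_count = profile$mut_count,
               n_valid = profile$n_valid, rate = profile$rate),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rolling-mean smoothing of a profile (plotting only)
#'
#' Statistics always use raw counts; this is a display helper.
#'
#' @param profile `rate_profile`.
#' @param width Rolling window width in bp (default 50).
#' @return Numeric vector of smoothed rates.
#' @export
smooth_profile <- function(profile, width = 50L) {
  k <- rep(1 / width, width)
  as.numeric(stats::filter(profile$rate, k, sides = 2L))
}
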