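# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# a genome from explicit sequences
toy_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# n sites on one chromosome with evenly spaced summits
toy_sites <- function(n, spacing = 3000L, chrom = "chr1", first = 2000L,
                      width = 200L) {
  summit <- first + spacing * (seq_len(n) - 1L)
  data.frame(site_id = sprintf("s%03d", seq_len(n)), chrom = chrom,
             start = summit - width %/% 2L - 1L, end = summit + width %/% 2L,
             summit = summit, stringsAsFactors = FALSE)
}

# minimal mutation table
toy_mutations <- function(chrom, pos, ref = "C", alt = "T", donor = "D1",
                          mut_type = "SNV") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
             donor_id = rep_len(donor, length(pos)),
             mut_type = rep_len(mut_type, length(pos)),
             control_tissue = "unknown", stringsAsFactors = FALSE)
}

# per-base membership oracle for interval sets over a small coordinate span
per_bp_membership <- function(interval_lists, span) {
  vapply(interval_lists, function(df) {
    cov <- rep(FALSE, span)
    for (i in seq_len(nrow(df))) {
      lo <- df$start[i] + 1L
      hi <- min(df$end[i], span)
      if (hi >= lo) cov[lo:hi] <- TRUE
    }
    cov
  }, logical(span))
}

# write a data frame as headered TSV into tempdir, returning the path
write_tsv_tmp <- function(df, name) {
  path <- file.path(tempdir(), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
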