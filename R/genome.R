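#' Load a genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning an
#' uppercase `DNAStringSet` keyed by the first word of each FASTA header.
#'
#' @param path FASTA file path.
#' @return A named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Extract genome subsequences
#'
#' Random access by 1-based closed coordinates, the convention used for
#' mutation positions. Returns plain uppercase character strings.
#'
#' @param genome A `DNAStringSet` (see [read_genome()]).
#' @param chrom Chromosome name(s), recycled against positions.
#' @param start,end 1-based inclusive coordinates.
#' @return Character vector of sequences, `end - start + 1` bases each.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  if (any(!chrom %in% names(genome))) {
    stop("unknown chromosome: ",
         paste(unique(setdiff(chrom, names(genome))), collapse = ", "))
  }
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(start < 1L) || any(end > lens)) stop("coordinates out of range")
  out <- character(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = start[i], end = end[i])
    out[i] <- as.character(v)
  }
  out
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
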