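#' The 96 strand-collapsed trinucleotide substitution classes
#'
#' Class labels follow the standard mutational-signature convention
#' `X[R>A]Y` with a pyrimidine reference center (R in C,T), ordered by
#' substitution type (C>A, C>G, C>T, T>A, T>C, T>G) then 5' and 3'
#' context base.
#'
#' @return Character vector of 96 labels.
#' @export
trinuc_classes <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) for (x in bases) for (y in bases) {
    out <- c(out, paste0(x, "[", s, "]", y))
  }
  out
}

# the 32 pyrimidine-centered reference trinucleotides, in class order
trinuc_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (r in c("C", "T")) for (x in bases) for (y in bases) {
    out <- c(out, paste0(x, r, y))
  }
  out
}

#' Classify SNVs into the 96 trinucleotide substitution classes
#'
#' Reads the reference 3-mer centered at each mutation position; when the
#' center base is a purine the 3-mer and both alleles are
#' reverse-complemented so every class is pyrimidine-centered. Mutations
#' whose context contains N, or whose stated reference allele disagrees
#' with the genome, classify to `NA`.
#'
#' @param genome `DNAStringSet` (see [read_genome()]).
#' @param mutations Mutation data frame; all records must be SNVs.
#' @return Character vector of class labels (`NA` where unclassifiable).
#' @export
classify_trinucleotide <- function(genome, mutations) {
  if (nrow(mutations) == 0L) return(character(0))
  if (any(mutations$mut_type != "SNV")) stop("classify_trinucleotide expects SNVs only")
  lens <- Biostrings::width(genome)[match(mutations$chrom, names(genome))]
  if (any(mutations$pos < 2L | mutations$pos > lens - 1L)) {
    stop("SNV position too close to a contig end for trinucleotide context")
  }
  ctx <- get_sequence(genome, mutations$chrom, mutations$pos - 1L,
                      mutations$pos + 1L)
  center <- substr(ctx, 2L, 2L)
  ref <- mutations$ref
  alt <- mutations$alt
  flip <- center %in% c("A", "G")
  if (any(flip)) {
    ctx[flip] <- revcomp(ctx[flip])
    ref[flip] <- revcomp(ref[flip])
    alt[flip] <- revcomp(alt[flip])
    center[flip] <- substr(ctx[flip], 2L, 2L)
  }
  label <- paste0(substr(ctx, 1L, 1L), "[", center, ">", alt, "]",
                  substr(ctx, 3L, 3L))
  bad <- grepl("N", ctx, fixed = TRUE) | center != ref
  label[bad] <- NA_character_
  label[!label %in% trinuc_classes()] <- NA_character_
  label
}

#' Fit the 96-class trinucleotide substitution model
#'
#' Counts the trinucleotide classes of SNVs falling at valid window
#' positions and normalizes the counts to probabilities — the empirical
#' context spectrum that drives expected-rate resampling.
#'
#' @param mutations Mutation data frame (SNVs are selected internally).
#' @param genome `DNAStringSet`.
#' @param windows `summit_windows` object.
#' @return Object of class `trinuc_model`: list with `classes`, `counts`
#'   (96 integers), `probs` (sum 1), `n_unclassifiable`.
#' @export
fit_trinucleotide_model <- function(mutations, genome, windows) {
  snv <- mutations[mutations$mut_type == "SNV", , drop = FALSE]
  hits <- map_mutations_to_windows(windows, snv)
  in_win <- snv[hits$mut_idx, , drop = FALSE]
  if (nrow(in_win) == 0L) stop("no SNVs inside the analysis windows")
  labels <- classify_trinucleotide(genome, in_win)
  n_bad <- sum(is.na(labels))
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) stop("no classifiable SNVs inside the windows")
  counts <- table(factor(labels, levels = trinuc_classes()))
  counts <- as.integer(counts)
  structure(list(classes = trinuc_classes(), counts = counts,
                 probs = counts / sum(counts), n_unclassifiable = n_bad),
            class = "trinuc_model")
}

#' @export
print.trinuc_model <- function(x, ...) {
  cat("trinuc_model: ", sum(x$counts), " SNVs over ",
      sum(x$counts > 0L), " of 96 classes\n", sep = "")
  invisible(x)
}

#' Write / read a trinucleotide model as a two-column TSV
#'
#' @param model `trinuc_model` object.
#' @param path Output path.
#' @export
write_trinuc_model <- function(model, path) {
  utils::write.table(
    data.frame(class = model$classes, count = model$counts,
               probability = model$probs),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
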