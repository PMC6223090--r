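#' Read a somatic mutation table
#'
#' Reads a tab-separated simple-somatic-mutation table in the consortium
#' style: header line required, columns `chrom`, `pos` (1-based), `ref`,
#' `alt`, `donor_id`, optional `mut_type` and `control_tissue`. When
#' `mut_type` is absent it is inferred: single-base equal-length
#' substitution is an SNV, longer alt an insertion, longer ref a
#' deletion. Multi-base substitutions and indels longer than
#' `max_indel_bp` are dropped; the number dropped is reported via a
#' message and an attribute.
#'
#' @param path Path to the TSV.
#' @param max_indel_bp Maximum retained indel length in bp (default 200).
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `donor_id`, `mut_type`, `control_tissue`, carrying attribute
#'   `n_dropped` (records removed by the length/multi-base filters).
#' @export
read_mutation_table <- function(path, max_indel_bp = 200L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  required <- c("chrom", "pos", "ref", "alt", "donor_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) stop("non-integer pos at row ", which(is.na(pos))[1L])
  df$pos <- pos
  mt <- if ("mut_type" %in% names(df)) df$mut_type else NA_character_
  ct <- if ("control_tissue" %in% names(df)) df$control_tissue else "unknown"
  out <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
                    donor_id = df$donor_id, mut_type = mt, control_tissue = ct,
                    stringsAsFactors = FALSE)
  build_mutation_table(out, max_indel_bp = max_indel_bp)
}

# classify and filter raw mutation records; shared by the reader and the
# simulator so emitted tables always satisfy the same invariants
build_mutation_table <- function(df, max_indel_bp = 200L) {
  nr <- nchar(df$ref)
  na_ <- nchar(df$alt)
  inferred <- ifelse(nr == 1L & na_ == 1L, "SNV",
              ifelse(na_ > nr & nr == 1L, "INS",
              ifelse(nr > na_ & na_ == 1L, "DEL", "MBS")))
  if (is.null(df$mut_type)) df$mut_type <- NA_character_
  if (is.null(df$control_tissue)) df$control_tissue <- "unknown"
  df$mut_type <- ifelse(is.na(df$mut_type) | !nzchar(df$mut_type),
                        inferred, df$mut_type)
  indel_len <- abs(na_ - nr)
  keep <- (df$mut_type == "SNV" & nr == 1L & na_ == 1L & df$ref != df$alt) |
    (df$mut_type %in% c("INS", "DEL") & indel_len >= 1L &
       indel_len <= max_indel_bp)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " mutation record(s) dropped ",
            "(multi-base substitutions or indels > ", max_indel_bp, " bp)")
  }
  out <- df[keep, c("chrom", "pos", "ref", "alt", "donor_id", "mut_type",
                    "control_tissue"), drop = FALSE]
  if (any(out$pos < 1L)) stop("mutation pos < 1")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a mutation table
#'
#' @param mutations Mutation data frame (see [read_mutation_table()]).
#' @param path Output path.
#' @export
write_mutation_table <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
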