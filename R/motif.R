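#' Build a position probability matrix from counts
#'
#' Converts a JASPAR-style count matrix to per-position base
#' probabilities with a pseudocount split by background frequencies.
#'
#' @param counts 4 x width numeric matrix with rownames A, C, G, T.
#' @param motif_id Motif identifier string.
#' @param background Background base frequencies (named, sums to 1;
#'   default uniform).
#' @param pseudocount Total pseudocount added per position (default 0.8),
#'   split across bases proportionally to the background.
#' @return Object of class `pwm`: list with `motif_id`, `matrix`
#'   (probabilities), `background`, `width`.
#' @export
pwm_from_counts <- function(counts, motif_id,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (!all(c("A", "C", "G", "T") %in% rownames(counts))) {
    stop("count matrix must have rows A, C, G, T")
  }
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(counts) < 4L) stop("motif width must be >= 4")
  background <- background[c("A", "C", "G", "T")] / sum(background)
  probs <- sweep(counts, 2L, colSums(counts), "/")
  if (pseudocount > 0) {
    probs <- sweep(counts + pseudocount * background, 2L,
                   colSums(counts) + pseudocount, "/")
  }
  structure(list(motif_id = motif_id, matrix = probs,
                 background = background, width = ncol(counts)),
            class = "pwm")
}

#' Read a JASPAR-style PWM library
#'
#' Plain-text format: `>motif_id` header lines, each followed by four
#' rows `A [ n n n ... ]` (also accepted without the base letter, in
#' A/C/G/T order).
#'
#' @param path Library file path.
#' @param background,pseudocount Passed to [pwm_from_counts()].
#' @return Named list of `pwm` objects.
#' @export
read_pwm_library <- function(path, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no motif headers ('>') found")
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4L) stop("motif block with fewer than 4 rows")
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("[][]", " ", l)
      toks <- strsplit(trimws(l), "\\s+")[[1L]]
      if (toks[1L] %in% c("A", "C", "G", "T")) toks <- toks[-1L]
      as.numeric(toks)
    })
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[id]] <- pwm_from_counts(counts, id, background, pseudocount)
  }
  out
}

# integer base codes (1=A..4=T, NA otherwise) for a sequence string
seq_codes <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1L]], c("A", "C", "G", "T"))
}

# reverse complement on integer codes
rc_codes <- function(codes) rev(5L - codes)

# log likelihood-ratio matrix of a pwm (cached on the object would be
# overkill; this is cheap relative to scanning)
pwm_logratio <- function(pwm) log(pwm$matrix) - log(pwm$background)

# log likelihood-ratio score of every window on one strand, from codes
window_scores <- function(codes, pwm, lr = pwm_logratio(pwm)) {
  w <- pwm$width
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  for (j in seq_len(w)) {
    scores <- scores + lr[, j][codes[j:(j + n - 1L)]]
  }
  unname(scores)  # NA where a window contains a non-ACGT base
}

# best log score over both strands, from codes; -Inf if no valid window
best_log_score <- function(codes, pwm, lr = pwm_logratio(pwm)) {
  s <- c(window_scores(codes, pwm, lr), window_scores(rc_codes(codes), pwm, lr))
  s <- s[!is.na(s)]
  if (length(s) == 0L) return(-Inf)
  max(s)
}

#' Best PWM match in a sequence
#'
#' Scores every window of the sequence against the PWM with the
#' likelihood-ratio score `prod p(base) / background(base)` (computed in
#' log space) on both strands (optionally) and returns the best match.
#' Windows containing N are skipped.
#'
#' @param sequence Character scalar over A/C/G/T/N.
#' @param pwm `pwm` object.
#' @param scan_both_strands Also scan the reverse complement (default
#'   `TRUE`).
#' @return List with `score` (likelihood ratio, linear scale),
#'   `log_score`, `offset` (1-based window start on the input), `strand`.
#' @export
pwm_score <- function(sequence, pwm, scan_both_strands = TRUE) {
  codes <- seq_codes(sequence)
  if (length(codes) < pwm$width) stop("sequence shorter than motif width")
  lr <- pwm_logratio(pwm)
  fwd <- window_scores(codes, pwm, lr)
  score <- fwd
  offset <- seq_along(fwd)
  strand <- rep("+", length(fwd))
  if (scan_both_strands) {
    rev <- window_scores(rc_codes(codes), pwm, lr)
    # window starting at i on the reverse strand covers input positions
    # (L - i - w + 2) .. (L - i + 1)
    off <- length(codes) - seq_along(rev) - pwm$width + 2L
    score <- c(score, rev)
    offset <- c(offset, off)
    strand <- c(strand, rep("-", length(rev)))
  }
  ok <- !is.na(score)
  if (!any(ok)) stop("no valid scoring window (all contain N)")
  i <- which(ok)[which.max(score[ok])]
  list(score = exp(score[i]), log_score = score[i],
       offset = offset[i], strand = strand[i])
}

#' Empirical score threshold for a target p-value
#'
#' Draws random sequences of the query length from the background base
#' distribution, records the best-window score of each, and returns the
#' `1 - p_target` empirical quantile — the score exceeded by chance with
#' probability `p_target`.
#'
#' @param pwm `pwm` object.
#' @param seq_length Length of the query sequences being scored.
#' @param p_target Target tail probability (default 1e-3).
#' @param n_draws Number of random sequences (must be >= 10 / p_target).
#' @param seed Integer seed.
#' @return Score threshold on the linear likelihood-ratio scale.
#' @export
calibrate_threshold <- function(pwm, seq_length, p_target = 1e-3,
                                n_draws = ceiling(10 / p_target), seed) {
  if (missing(seed)) stop("an integer seed is required")
  if (n_draws < 10 / p_target) stop("n_draws must be >= 10 / p_target")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  lr <- pwm_logratio(pwm)
  draws <- vapply(seq_len(n_draws), function(i) {
    codes <- sample.int(4L, seq_length, replace = TRUE, prob = pwm$background)
    best_log_score(codes, pwm, lr)
  }, numeric(1L))
  exp(as.numeric(stats::quantile(draws, probs = 1 - p_target, type = 1L)))
}

#' Motif score ratios between reference and mutant sequences
#'
#' For each motif in a library, compares the best score on the mutant
#' sequence to the best score on the reference sequence, restricted to
#' windows overlapping the mutation position(s). A ratio above
#' `1 + epsilon` classifies as `created` (higher score with the
#' mutation), below `1 - epsilon` as `disrupted`, otherwise `unchanged`.
#' A result is `confident` when the better of the two scores passes the
#' motif's calibrated threshold.
#'
#' @param ref_seq,mut_seq Equal-length sequences differing only at
#'   `mut_positions`.
#' @param pwm_library Named list of `pwm` objects.
#' @param mut_positions 1-based position(s) of the mutation within the
#'   sequences; inferred from the mismatches when omitted.
#' @param epsilon Classification dead zone around ratio 1 (default 0.05).
#' @param thresholds Optional named numeric vector of confidence score
#'   thresholds per motif (see [calibrate_threshold()]); `confident` is
#'   `NA` for motifs without one.
#' @return Data frame, one row per motif: `motif_id`, `score_ref`,
#'   `score_mut`, `score_ratio`, `log2_ratio`, `classification`,
#'   `mutation_offset_in_motif`, `strand`, `confident`; sorted by
#'   decreasing `|log2_ratio|`.
#' @export
motif_score_ratio <- function(ref_seq, mut_seq, pwm_library,
                              mut_positions = NULL, epsilon = 0.05,
                              thresholds = NULL) {
  ref_chars <- seq_codes(ref_seq)
  mut_chars <- seq_codes(mut_seq)
  if (length(ref_chars) != length(mut_chars)) {
    stop("ref and mut sequences differ in length")
  }
  diffs <- which(ref_chars != mut_chars |
                   xor(is.na(ref_chars), is.na(mut_chars)))
  if (is.null(mut_positions)) {
    mut_positions <- diffs
    if (length(mut_positions) == 0L) stop("sequences are identical")
  } else if (!all(diffs %in% mut_positions)) {
    stop("sequences differ outside the declared mutation positions")
  }
  rows <- lapply(names(pwm_library), function(id) {
    pwm <- pwm_library[[id]]
    best_ref <- best_overlapping_score(ref_chars, pwm, mut_positions)
    best_mut <- best_overlapping_score(mut_chars, pwm, mut_positions)
    if (is.null(best_ref) || is.null(best_mut)) return(NULL)
    ratio <- best_mut$score / best_ref$score
    cls <- if (ratio > 1 + epsilon) "created"
           else if (ratio < 1 - epsilon) "disrupted" else "unchanged"
    # offset of the (first) mutation within the better-scoring window
    top <- if (best_mut$score >= best_ref$score) best_mut else best_ref
    conf <- if (is.null(thresholds) || !id %in% names(thresholds)) NA else
      max(best_ref$score, best_mut$score) >= thresholds[[id]]
    data.frame(motif_id = id, score_ref = best_ref$score,
               score_mut = best_mut$score, score_ratio = ratio,
               log2_ratio = log2(ratio), classification = cls,
               mutation_offset_in_motif = mut_positions[1L] - top$offset + 1L,
               strand = top$strand, confident = conf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no motif produced a valid window overlapping the mutation")
  }
  out <- out[order(-abs(out$log2_ratio), out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# best score over windows (both strands) overlapping any mutation
# position; `chars` is an integer code vector
best_overlapping_score <- function(chars, pwm, mut_positions) {
  w <- pwm$width
  L <- length(chars)
  n <- L - w + 1L
  if (n < 1L) return(NULL)
  starts <- seq_len(n)
  overlaps <- vapply(starts, function(s) {
    any(mut_positions >= s & mut_positions <= s + w - 1L)
  }, logical(1L))
  fwd <- window_scores(chars, pwm)
  rev <- window_scores(rc_codes(chars), pwm)
  rev_start_on_input <- L - seq_along(rev) - w + 2L
  cand <- rbind(
    data.frame(score = fwd[overlaps], offset = starts[overlaps], strand = "+"),
    data.frame(score = rev[overlaps[rev_start_on_input]],
               offset = rev_start_on_input[overlaps[rev_start_on_input]],
               strand = "-"))
  cand <- cand[!is.na(cand$score), , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  i <- which.max(cand$score)
  list(score = exp(cand$score[i]), offset = cand$offset[i],
       strand = cand$strand[i])
}
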