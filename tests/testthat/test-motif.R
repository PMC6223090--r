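consensus_pwm <- function(consensus, id = "m", pseudocount = 0) {
  chars <- strsplit(consensus, "")[[1L]]
  counts <- matrix(0, 4L, length(chars),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(chars, c("A", "C", "G", "T")), seq_along(chars))] <- 100
  pwm_from_counts(counts, id, pseudocount = pseudocount)
}

test_that("PWM scoring matches closed forms and strand symmetry", {
  p <- consensus_pwm("TGACCA")
  s <- pwm_score("TGACCA", p)
  expect_equal(s$score, (1 / 0.25)^6)
  expect_equal(s$strand, "+")

  # uniform PWM scores 1 everywhere
  u <- pwm_from_counts(matrix(1, 4L, 5L,
                              dimnames = list(c("A", "C", "G", "T"), NULL)),
                       "unif", pseudocount = 0)
  expect_equal(pwm_score("ACGTACGT", u)$score, 1)

  # scoring a sequence equals scoring its reverse complement
  set.seed(101)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE), collapse = "")
  }, "")
  lib <- demo_pwm_library()
  for (sq in seqs[1:5]) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    for (m in lib[1:3]) {
      expect_equal(pwm_score(sq, m)$score, pwm_score(rc, m)$score,
                   tolerance = 1e-12)
    }
  }
})

test_that("best-window scan agrees with an exhaustive oracle", {
  set.seed(102)
  p <- demo_pwm_library()$synthD   # width 8
  probs <- p$matrix
  for (rep in 1:10) {
    sq <- paste(sample(c("A", "C", "G", "T"), 40L, replace = TRUE), collapse = "")
    got <- pwm_score(sq, p)
    # oracle: direct product over all windows on both strands
    score_window <- function(win) {
      chars <- strsplit(win, "")[[1L]]
      prod(probs[cbind(match(chars, c("A", "C", "G", "T")),
                       seq_along(chars))] / 0.25)
    }
    best <- -Inf
    for (i in 1:(40L - 8L + 1L)) {
      win <- substr(sq, i, i + 7L)
      rcw <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
      best <- max(best, score_window(win), score_window(rcw))
    }
    expect_equal(got$score, best, tolerance = 1e-9)
  }
})

test_that("threshold calibration follows quantile semantics", {
  u <- pwm_from_counts(matrix(1, 4L, 5L,
                              dimnames = list(c("A", "C", "G", "T"), NULL)),
                       "unif", pseudocount = 0)
  expect_equal(calibrate_threshold(u, seq_length = 20L, seed = 103L), 1)

  p <- demo_pwm_library()$synthB
  t50 <- calibrate_threshold(p, 30L, p_target = 0.5, n_draws = 2000L, seed = 104L)
  t05 <- calibrate_threshold(p, 30L, p_target = 0.05, n_draws = 2000L, seed = 104L)
  t01 <- calibrate_threshold(p, 30L, p_target = 0.01, n_draws = 2000L, seed = 104L)
  expect_true(t50 <= t05 && t05 <= t01)
  expect_error(calibrate_threshold(p, 30L, p_target = 1e-3, n_draws = 100L,
                                   seed = 1L), "n_draws")
})

test_that("score ratios classify planted creation and disruption", {
  lib <- list(target = consensus_pwm("TGACCA", "target", pseudocount = 0.8),
              other = consensus_pwm("CCCGGG", "other", pseudocount = 0.8))
  ref <- "AAAATGACCAAAAA"
  mut <- "AAAATGTCCAAAAA"   # A>T at consensus position 3 of target
  res <- motif_score_ratio(ref, mut, lib, mut_positions = 7L)
  tg <- res[res$motif_id == "target", ]
  expect_equal(tg$classification, "disrupted")
  expect_lt(tg$score_ratio, 1)

  # swapping ref and mut inverts every ratio
  res_sw <- motif_score_ratio(mut, ref, lib, mut_positions = 7L)
  for (id in res$motif_id) {
    expect_equal(res_sw$score_ratio[res_sw$motif_id == id],
                 1 / res$score_ratio[res$motif_id == id], tolerance = 1e-9)
  }

  # a library motif matching only the mutant allele is classified created,
  # with a hand-computed ratio of per-window products
  lib2 <- list(mutmatch = consensus_pwm("TGTCCA", "mutmatch", pseudocount = 0))
  res2 <- motif_score_ratio(ref, mut, lib2, mut_positions = 7L)
  expect_equal(res2$classification, "created")
  # ref best overlapping window has one mismatch at probability 0 -> score 0
  expect_equal(res2$score_ref, 0)
  expect_equal(res2$score_mut, 4^6)

  expect_error(motif_score_ratio("AAAA", "TTTT", lib, mut_positions = 1L),
               "outside the declared mutation")
  # log-space and direct products agree
  p <- consensus_pwm("TGACCA", pseudocount = 0.8)
  direct <- prod(p$matrix[cbind(match(strsplit("TGACCA", "")[[1L]],
                                      c("A", "C", "G", "T")), 1:6)] / 0.25)
  expect_equal(pwm_score("TGACCA", p)$score, direct, tolerance = 1e-9)
})
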