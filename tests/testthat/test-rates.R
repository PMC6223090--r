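test_that("observed rates normalize counts by valid positions", {
  sites <- toy_sites(10L, spacing = 3000L)
  w <- build_analysis_windows(sites, flank = 1000L)
  m <- toy_mutations("chr1", sites$summit[1L])   # offset 0 of site 1
  prof <- observed_rate_profile(w, m)
  expect_equal(prof$rate[prof$offsets == 0L], 0.1)
  expect_equal(sum(prof$mut_count), 1L)
  expect_true(all(prof$rate[prof$offsets != 0L] == 0))

  # same mutation at a masked position is ignored and the denominator drops
  bl <- data.frame(chrom = "chr1", start = sites$summit[1L] - 1L,
                   end = sites$summit[1L])
  w2 <- build_analysis_windows(sites, flank = 1000L,
                               exclude_sets = list(blacklist = bl),
                               drop_excluded_cores = FALSE)
  prof2 <- observed_rate_profile(w2, m)
  expect_equal(prof2$mut_count[prof2$offsets == 0L], 0L)
  expect_equal(prof2$n_valid[prof2$offsets == 0L], 9L)
  expect_equal(prof2$rate[prof2$offsets == 0L], 0)
})

test_that("per-offset counts equal a nested-loop tally on random data", {
  set.seed(41)
  sites <- toy_sites(100L, spacing = 2500L)
  w <- build_analysis_windows(sites, flank = 500L)
  pos <- sample.int(260000L, 500L, replace = TRUE)
  m <- toy_mutations("chr1", pos)
  prof <- observed_rate_profile(w, m)
  oracle <- integer(length(w$offsets))
  for (i in seq_len(nrow(sites))) {
    for (p in pos) {
      off <- p - sites$summit[i]
      if (abs(off) <= 500L) oracle[off + 501L] <- oracle[off + 501L] + 1L
    }
  }
  expect_equal(prof$mut_count, oracle)
  # conservation: sum rate * n_valid = mapped mutations
  expect_equal(sum(prof$rate * prof$n_valid), sum(oracle))
})

test_that("expected rate is uniform when every position shares one context", {
  g <- toy_genome(chr1 = strrep("C", 9L))
  sites <- data.frame(chrom = "chr1", summit = 5L)
  w <- build_analysis_windows(sites, flank = 1L)  # 3 positions, context CCC
  model <- structure(list(classes = trinuc_classes(),
                          counts = as.integer(trinuc_classes() == "C[C>T]C"),
                          probs = as.numeric(trinuc_classes() == "C[C>T]C"),
                          n_unclassifiable = 0L), class = "trinuc_model")
  prof <- expected_rate_profile(w, g, model, n_resamples = 400L, seed = 42L)
  expect_equal(sum(prof$mut_count), 1)          # one placed mutation per resample
  expect_true(all(abs(prof$rate - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 400)))

  # zero counts give a zero curve
  model0 <- model
  model0$counts <- rep(0L, 96L)
  prof0 <- expected_rate_profile(w, g, model0, n_resamples = 10L, seed = 1L)
  expect_true(all(prof0$rate == 0))

  # more mutations of a class than matching positions is an error
  model_big <- model
  model_big$counts[trinuc_classes() == "C[C>T]C"] <- 10L
  expect_error(expected_rate_profile(w, g, model_big, n_resamples = 2L, seed = 1L),
               "matching positions")
})

test_that("resampled expected rates converge to analytic placement probabilities", {
  set.seed(43)
  g <- toy_genome(chr1 = paste(sample(c("A", "C", "G", "T"), 400L, replace = TRUE),
                               collapse = ""))
  sites <- data.frame(chrom = "chr1", summit = c(60L, 200L, 340L))
  w <- build_analysis_windows(sites, flank = 15L)   # 93 positions total
  # counts: a few mutations spread over whatever contexts exist in-window
  valid_pos <- as.vector(outer(w$offsets, sites$summit, "+"))
  ctx <- tfburden:::context_codes(g, rep("chr1", length(valid_pos)), valid_pos)
  present <- as.integer(names(sort(table(ctx), decreasing = TRUE)))[1:3]
  counts <- rep(0L, 96L)
  for (cx in present) {
    cls <- which(tfburden:::class_context_index() == cx)[1L]
    counts[cls] <- 2L
  }
  model <- structure(list(classes = trinuc_classes(), counts = counts,
                          probs = counts / sum(counts), n_unclassifiable = 0L),
                     class = "trinuc_model")
  n_res <- 10000L
  prof <- expected_rate_profile(w, g, model, n_resamples = n_res, seed = 44L)
  # analytic mean placed count per offset: sum over contexts of
  # count_ctx * (matching positions at that offset / total matching)
  n_off <- length(w$offsets)
  ctx_mat <- matrix(ctx, nrow = n_off)   # offsets x sites
  expected <- numeric(n_off)
  mc_se <- numeric(n_off)
  for (cx in present) {
    m_off <- rowSums(ctx_mat == cx, na.rm = TRUE)
    tot <- sum(m_off)
    p_off <- m_off / tot
    expected <- expected + 2 * p_off
    mc_se <- sqrt(mc_se^2 + 2 * p_off * (1 - p_off) / n_res)
  }
  dev <- abs(prof$mut_count - expected)
  expect_true(all(dev <= 3 * sqrt(mc_se^2) + 1e-9))
})
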