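test_that("quantile stratification splits sites as expected", {
  sites <- toy_sites(8L, spacing = 3000L)
  w <- build_analysis_windows(sites, flank = 1000L)
  m <- toy_mutations("chr1", sites$summit)
  res <- stratify_by_quantile(w, m, values = 1:8, k = 4L)
  expect_equal(res$groups, rep(1:4, each = 2L))
  expect_warning(stratify_by_quantile(w, m, values = rep(1, 8L), k = 4L),
                 "all values equal")
  expect_error(stratify_by_quantile(w, m, values = 1:8, k = 9L), "exceeds")
})

test_that("quantile strata recover a planted intensity-burden correlation", {
  set.seed(61)
  cfg <- sim_config(genome_length = 5e6, n_chroms = 1L, n_sites = 2000L,
                    intensity_burden_effect = 0.8, sharing_effect = 0,
                    outcome_burden_mult = 1, background_rate = 4e-3,
                    indel_rate = 0, seed = 62L)
  g <- simulate_genome(cfg)
  sm <- simulate_sites_and_mutations(cfg, g)
  w <- build_analysis_windows(sm$sites, flank = 1000L)
  res <- stratify_by_quantile(w, sm$mutations, sm$sites$intensity, k = 4L)
  expect_gt(res$pearson_r, 0.9)
  expect_true(all(diff(res$table$core_rate) > 0))
})

test_that("sharing classes follow the configured edges", {
  sites <- toy_sites(3L, spacing = 3000L)
  w <- build_analysis_windows(sites, flank = 1000L)
  m <- toy_mutations("chr1", sites$summit)
  res <- stratify_by_sharing(w, m, sharing_count = c(1L, 2L, 4L))
  expect_equal(res$classes, c("patient_specific", "shared_2", "shared_gt3"))
  res1 <- stratify_by_sharing(w, m, sharing_count = c(1L, 1L, 1L))
  expect_equal(nrow(res1$table), 1L)
  expect_equal(res1$table$group, "patient_specific")
})

test_that("outcome burden sampling detects a planted 2x burden and not a null", {
  set.seed(63)
  sites <- toy_sites(400L, spacing = 2500L)
  w <- build_analysis_windows(sites, flank = 1000L)
  # group B sites carry double the core mutation rate
  groups <- list(A = 1:200, B = 201:400)
  mk_muts <- function(idx, lambda) {
    counts <- rpois(length(idx), lambda)
    pos <- unlist(mapply(function(i, k) {
      if (k == 0L) return(integer(0))
      sites$summit[i] + sample(-200:200, k, replace = TRUE)
    }, idx, counts, SIMPLIFY = FALSE))
    if (length(pos) == 0L) return(NULL)
    toy_mutations("chr1", pos)
  }
  m <- rbind(mk_muts(groups$A, 1.0), mk_muts(groups$B, 2.0))
  res <- outcome_burden_test(w, m, groups, n_sample = 100L, n_reps = 50L,
                             seed = 64L)
  expect_lt(res$pairwise$p_value, 0.01)
  expect_gt(res$group_means[["B"]], res$group_means[["A"]])

  # identical groups: no detectable difference
  res0 <- outcome_burden_test(w, m, list(A = 1:200, A2 = 1:200),
                              n_sample = 100L, n_reps = 50L, seed = 65L)
  expect_gt(res0$pairwise$p_value, 0.05)
  expect_lt(abs(diff(res0$group_means)), 0.2)

  expect_error(outcome_burden_test(w, m, groups, n_sample = 100L, n_reps = 1L,
                                   seed = 1L), "n_reps")
  expect_error(outcome_burden_test(w, m, list(A = 1:50), n_sample = 100L,
                                   seed = 1L), "smaller than n_sample")
})

test_that("burden ranking tracks counts, donors and allele-exact recurrence", {
  sites <- toy_sites(3L, spacing = 3000L)
  w <- build_analysis_windows(sites, flank = 1000L)
  s1 <- sites$summit[1L]; s2 <- sites$summit[2L]
  m <- rbind(
    toy_mutations("chr1", c(s1, s1, s1 + 5L), donor = c("D1", "D2", "D2")),
    # same position, different alt alleles: not recurrent
    toy_mutations("chr1", c(s2, s2), alt = c("T", "G"), donor = c("D1", "D2")))
  r <- rank_sites_by_burden(w, m)
  expect_equal(r$site_id[1L], "s001")
  expect_equal(r$mut_count[1L], 3L)
  expect_equal(r$n_donors[1L], 2L)
  expect_true(r$has_recurrent[1L])
  expect_false(r$has_recurrent[r$site_id == "s002"])

  # ranking equals a brute-force sort on random data
  set.seed(66)
  sites2 <- toy_sites(50L, spacing = 2500L)
  w2 <- build_analysis_windows(sites2, flank = 1000L)
  pos <- sample.int(130000L, 300L, replace = TRUE)
  m2 <- toy_mutations("chr1", pos,
                      donor = sample(sprintf("D%d", 1:5), 300L, replace = TRUE))
  r2 <- rank_sites_by_burden(w2, m2)
  brute <- vapply(seq_len(50L), function(i) {
    sum(abs(pos - sites2$summit[i]) <= 200L)
  }, integer(1L))
  expect_equal(r2$mut_count, sort(brute, decreasing = TRUE))
  expect_equal(r2$mut_count[match(sites2$site_id, r2$site_id)], brute)
})
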