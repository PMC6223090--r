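make_loop <- function(ca, sa, ea, cb, sb, eb, w = 1) {
  data.frame(chrom_a = ca, start_a = sa, end_a = ea, chrom_b = cb,
             start_b = sb, end_b = eb, weight = w, stringsAsFactors = FALSE)
}

test_that("contact frequency counts loops once per site", {
  site <- data.frame(chrom = "chr1", start = 1000L, end = 1500L)
  loops <- rbind(make_loop("chr1", 1100L, 1200L, "chr1", 9000L, 9500L),
                 make_loop("chr1", 1300L, 1400L, "chr1", 20000L, 20500L),
                 make_loop("chr1", 900L, 1100L, "chr1", 30000L, 30500L))
  expect_equal(contact_frequency(site, loops), 3L)
  # both anchors overlapping one site still count once
  both <- make_loop("chr1", 1000L, 1100L, "chr1", 1400L, 1500L)
  expect_equal(contact_frequency(site, both), 1L)
})

test_that("contact frequency equals an all-pairs overlap oracle", {
  set.seed(81)
  sites <- data.frame(chrom = "chr1", start = sort(sample.int(99000L, 100L)))
  sites$end <- sites$start + 500L
  loops <- make_loop("chr1", sample.int(99000L, 100L), 0L,
                     "chr1", sample.int(99000L, 100L), 0L)
  loops$end_a <- loops$start_a + 300L
  loops$end_b <- loops$start_b + 300L
  got <- contact_frequency(sites, loops)
  ovl <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  oracle <- vapply(seq_len(100L), function(i) {
    sum(ovl(sites$start[i], sites$end[i], loops$start_a, loops$end_a) |
          ovl(sites$start[i], sites$end[i], loops$start_b, loops$end_b))
  }, integer(1L))
  expect_equal(got, oracle)
})

test_that("topological targets require both a loop and a shared TAD", {
  tads <- data.frame(chrom = "chr1", start = c(0L, 100000L),
                     end = c(100000L, 200000L))
  genes <- data.frame(gene_id = c("inTAD", "acrossTAD"), chrom = "chr1",
                      start = c(80000L, 150000L), end = c(82000L, 152000L),
                      strand = "+", expression = c(5, 5))
  site <- data.frame(chrom = "chr1", start = 19750L, end = 20250L,
                     summit = 20000L)
  loop_in <- make_loop("chr1", 19800L, 20200L, "chr1", 80000L, 82000L)
  loop_out <- make_loop("chr1", 19800L, 20200L, "chr1", 150000L, 152000L)
  expect_equal(topo_target_genes(site, loop_in, tads, genes), "inTAD")
  expect_equal(topo_target_genes(site, loop_out, tads, genes), character(0))
  # a site outside every TAD has no topological targets
  site_out <- data.frame(chrom = "chr1", start = 250000L, end = 250500L,
                         summit = 250250L)
  expect_equal(topo_target_genes(site_out, loop_in, tads, genes), character(0))
})

test_that("topological target sets match a brute-force conjunction oracle", {
  set.seed(82)
  tads <- data.frame(chrom = "chr1", start = seq(0L, 180000L, by = 20000L),
                     end = seq(20000L, 200000L, by = 20000L))
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60), chrom = "chr1",
                      start = sort(sample.int(198000L, 60L)), strand = "+",
                      expression = 1)
  genes$end <- genes$start + 1500L
  sites <- data.frame(chrom = "chr1", start = sort(sample.int(195000L, 25L)))
  sites$end <- sites$start + 400L
  sites$summit <- sites$start + 200L
  loops <- make_loop("chr1", sample.int(195000L, 80L), 0L,
                     "chr1", sample.int(195000L, 80L), 0L)
  loops$end_a <- loops$start_a + 400L
  loops$end_b <- loops$start_b + 400L
  got <- tfburden:::topo_target_gene_sets(sites, loops, tads, genes)
  ovl <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  for (i in seq_len(25L)) {
    tad_i <- which(sites$summit[i] > tads$start & sites$summit[i] <= tads$end)
    expected <- character(0)
    if (length(tad_i) == 1L) {
      for (l in seq_len(nrow(loops))) {
        hit_a <- ovl(sites$start[i], sites$end[i], loops$start_a[l], loops$end_a[l])
        hit_b <- ovl(sites$start[i], sites$end[i], loops$start_b[l], loops$end_b[l])
        distal <- list()
        if (hit_a) distal <- c(distal, list(c(loops$start_b[l], loops$end_b[l])))
        if (hit_b) distal <- c(distal, list(c(loops$start_a[l], loops$end_a[l])))
        for (d in distal) {
          gsel <- ovl(genes$start, genes$end, d[1L], d[2L]) &
            ovl(genes$start, genes$end, tads$start[tad_i], tads$end[tad_i])
          expected <- union(expected, genes$gene_id[gsel])
        }
      }
    }
    expect_setequal(got[[i]], expected)
  }
  # topological targets are always same-TAD genes; proximity is monotone
  p50 <- tfburden:::proximity_target_gene_sets(sites, genes, 50000L)
  p100 <- tfburden:::proximity_target_gene_sets(sites, genes, 100000L)
  for (i in seq_len(25L)) expect_true(all(p50[[i]] %in% p100[[i]]))
})

test_that("expression comparison is seed-reproducible and handles the null", {
  set.seed(83)
  n <- 60L
  tad_len <- 50000L
  sites <- data.frame(chrom = "chr1",
                      summit = as.integer(tad_len * (seq_len(n) - 1L) + 10000L),
                      intensity = rlnorm(n), mut_count = rep(0:3, each = 15L))
  sites$start <- sites$summit - 250L
  sites$end <- sites$summit + 250L
  cfg <- sim_config(tad_length = tad_len, genes_per_tad = 15L,
                    min_loop_distance = 15000L, expression_shift = 0,
                    contact_a = 1.5, contact_b = 0, seed = 84L)
  topo <- simulate_topology_expression(cfg, sites)
  run <- function(seed) {
    expression_by_mutation_group(sites, topo$loops, topo$tads, topo$genes,
                                 mode = "topological", n_region_sample = 10L,
                                 n_region_reps = 3L, n_gene_sample = 20L,
                                 n_gene_reps = 30L, seed = seed)
  }
  a <- run(85L); b <- run(85L)
  expect_identical(a$means, b$means)
  expect_identical(a$pairwise, b$pairwise)

  # constant expression: all group means equal, p = 1
  topo_const <- topo
  topo_const$genes$expression <- 7
  cst <- expression_by_mutation_group(sites, topo_const$loops, topo_const$tads,
                                      topo_const$genes, mode = "topological",
                                      n_region_sample = 10L, n_region_reps = 3L,
                                      n_gene_sample = 20L, n_gene_reps = 30L,
                                      seed = 86L)
  expect_true(all(cst$means == 7))
  expect_true(all(cst$pairwise$p_value == 1))

  expect_error(
    expression_by_mutation_group(sites, topo$loops, topo$tads, topo$genes,
                                 mode = "topological", n_region_sample = 10L,
                                 n_region_reps = 3L, n_gene_sample = 20L,
                                 n_gene_reps = 1L, seed = 1L),
    "n_gene_reps")
})

test_that("BEDPE round trip deduplicates unordered anchor pairs", {
  loops <- rbind(make_loop("chr1", 100L, 200L, "chr1", 900L, 1000L),
                 make_loop("chr1", 900L, 1000L, "chr1", 100L, 200L),
                 make_loop("chr2", 0L, 50L, "chr2", 500L, 600L))
  p <- file.path(tempdir(), "loops.bedpe")
  write_bedpe(loops, p)
  back <- read_bedpe(p)
  expect_equal(nrow(back), 2L)
})
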