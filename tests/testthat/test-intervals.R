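test_that("BED-family parsing honors coordinates, summits and errors", {
  path <- file.path(tempdir(), "toy.bed")
  writeLines(c("chr1\t100\t200", "chr2\t0\t50"), path)
  iv <- read_interval_file(path, "bed3")
  expect_equal(iv$chrom, c("chr1", "chr2"))
  expect_equal(iv$start, c(100L, 0L))
  expect_equal(iv$end, c(200L, 50L))

  np <- file.path(tempdir(), "toy.narrowPeak")
  writeLines(c("chr1\t100\t200\tp1\t500\t.\t8.5\t-1\t-1\t50",
               "chr1\t300\t401\tp2\t200\t.\t4.0\t-1\t-1\t-1"), np)
  peaks <- read_interval_file(np, "narrowPeak")
  expect_equal(peaks$summit[1L], 151L)      # start + offset + 1
  expect_equal(peaks$summit[2L], 351L)      # midpoint fallback, lower tie

  bad <- file.path(tempdir(), "bad.bed")
  writeLines(c("chr1\t1\t10", "chr1\t200\t100"), bad)
  expect_error(read_interval_file(bad, "bed3"), "end <= start at line 2")
})

test_that("interval read-write round trips are identity", {
  for (dialect in c("bed3", "bed6", "narrowPeak")) {
    df <- data.frame(chrom = c("chr1", "chr2"), start = c(10L, 0L),
                     end = c(20L, 7L), name = c("a", "b"), score = c(1, 2.5),
                     strand = c("+", "-"), signal = c(3, 4), pvalue = c(-1, -1),
                     qvalue = c(-1, -1), summit = c(15L, 4L))
    p <- file.path(tempdir(), paste0("rt.", dialect))
    write_interval_file(df, p, dialect)
    back <- read_interval_file(p, dialect)
    expect_equal(back$start, df$start)
    expect_equal(back$end, df$end)
    if (dialect != "bed3") expect_equal(back$name, df$name)
    if (dialect == "narrowPeak") expect_equal(back$summit, df$summit)
  }
})

test_that("multi-sample intersection matches the sweep-line examples", {
  res <- multi_intersect(list(a = data.frame(chrom = "chr1", start = 0L, end = 10L),
                              b = data.frame(chrom = "chr1", start = 5L, end = 15L)))
  expect_equal(res$start, c(0L, 5L, 10L))
  expect_equal(res$end, c(5L, 10L, 15L))
  expect_equal(res$sharing_count, c(1L, 2L, 1L))

  one <- data.frame(chrom = "chr1", start = c(3L, 30L), end = c(9L, 44L))
  res3 <- multi_intersect(list(one, one, one))
  expect_true(all(res3$sharing_count == 3L))
  expect_equal(sum(res3$end - res3$start), sum(one$end - one$start))

  expect_error(multi_intersect(list()), "no samples")
})

test_that("multi-sample intersection agrees with a per-bp counting oracle", {
  set.seed(11)
  span <- 500L
  samples <- lapply(1:5, function(i) {
    start <- sort(sample.int(span - 20L, 20L))
    data.frame(chrom = "chrX", start = start,
               end = pmin(start + sample.int(30L, 20L, replace = TRUE), span))
  })
  res <- multi_intersect(samples)
  memb <- per_bp_membership(samples, span)
  oracle_count <- rowSums(memb)
  # reconstruct per-bp counts from segments
  seg_count <- rep(0L, span)
  for (i in seq_len(nrow(res))) {
    seg_count[(res$start[i] + 1L):res$end[i]] <- res$sharing_count[i]
  }
  expect_equal(seg_count, as.integer(oracle_count))
  # segments tile the union exactly: covered bp conserved
  expect_equal(sum(res$end - res$start), sum(oracle_count > 0L))
  # segments non-overlapping
  ord <- order(res$start)
  expect_true(all(res$start[ord][-1L] >= res$end[ord][-nrow(res)]))
})

test_that("genomic context labels respect promoter/intron precedence and strand", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
                      start = c(10000L, 50000L), end = c(30000L, 70000L),
                      strand = c("+", "-"), expression = c(1, 1))
  sites <- data.frame(chrom = rep("chr1", 4),
                      summit = c(9900L,   # 100 bp upstream of + TSS
                                 20000L,  # deep inside gA body
                                 70100L,  # 100 bp upstream of - strand TSS (end)
                                 90000L)) # nothing nearby
  labels <- annotate_genomic_context(sites, genes,
                                     promoter_upstream_bp = 2000L,
                                     promoter_downstream_bp = 500L)
  expect_equal(labels, c("promoter", "intronic", "promoter", "intergenic"))
  none <- annotate_genomic_context(data.frame(chrom = "chr9", summit = 5L),
                                   genes)
  expect_equal(none, "intergenic")
})
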