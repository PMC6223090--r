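test_that("simulated genomes respect GC content and determinism", {
  cfg <- sim_config(genome_length = 1e6, n_chroms = 1L, gc_content = 0.5,
                    seed = 111L)
  g <- simulate_genome(cfg)
  freq <- Biostrings::letterFrequency(g[[1L]], c("G", "C"))
  gc <- sum(freq) / 1e6
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e6))

  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g[[1L]]), as.character(g2[[1L]]))

  gc1 <- simulate_genome(sim_config(genome_length = 1e4, n_chroms = 1L,
                                    gc_content = 1, seed = 1L))
  expect_equal(Biostrings::letterFrequency(gc1[[1L]], "GC"), c("G|C" = 1e4))
})

test_that("a point-mass signature constrains every SNV's context", {
  sig <- stats::setNames(as.numeric(trinuc_classes() == "A[C>T]A"),
                         trinuc_classes())
  cfg <- sim_config(genome_length = 3e5, n_chroms = 1L, n_sites = 60L,
                    signature = sig, background_rate = 2e-3, indel_rate = 0,
                    seed = 112L)
  g <- simulate_genome(cfg)
  sm <- simulate_sites_and_mutations(cfg, g)
  snv <- sm$mutations[sm$mutations$mut_type == "SNV", ]
  ctx <- get_sequence(g, snv$chrom, snv$pos - 1L, snv$pos + 1L)
  expect_true(all(ctx %in% c("ACA", "TGT")))
  expect_true(all(ifelse(ctx == "ACA", snv$ref == "C" & snv$alt == "T",
                         snv$ref == "G" & snv$alt == "A")))
})

test_that("null enrichment stays at fold change 1 and the planted factor is recovered", {
  cfg0 <- sim_config(genome_length = 2e6, n_chroms = 1L, n_sites = 400L,
                     core_enrichment = 1, sharing_effect = 0,
                     intensity_burden_effect = 0, outcome_burden_mult = 1,
                     background_rate = 5e-3, indel_rate = 0, seed = 113L)
  g <- simulate_genome(cfg0)
  sm <- simulate_sites_and_mutations(cfg0, g)
  w <- build_analysis_windows(sm$sites, flank = 1000L)
  eng <- prepare_mutation_engine(cfg0, g, sm$sites)
  fcs <- vapply(1:20, function(r) {
    m <- simulate_mutation_draw(cfg0, g, sm$sites, seed = 1000L + r,
                                engine = eng)
    enrichment_test(observed_rate_profile(w, m))$fold_change
  }, numeric(1L))
  expect_lt(abs(mean(fcs) - 1), 0.05)

  cfg1 <- sim_config(genome_length = 2e6, n_chroms = 1L, n_sites = 400L,
                     core_enrichment = 1.5, sharing_effect = 0,
                     intensity_burden_effect = 0, outcome_burden_mult = 1,
                     background_rate = 5e-3, indel_rate = 0, seed = 114L)
  sm1 <- simulate_sites_and_mutations(cfg1, g)
  w1 <- build_analysis_windows(sm1$sites, flank = 1000L)
  m1 <- simulate_mutation_draw(cfg1, g, sm1$sites, seed = 115L)
  fc <- enrichment_test(observed_rate_profile(w1, m1))$fold_change
  expect_lt(abs(fc - 1.5), 0.2)
})

test_that("emitted dataset files parse through the package readers", {
  cfg <- sim_config(genome_length = 6e5, n_chroms = 1L, n_sites = 150L,
                    tad_length = 5e4, genes_per_tad = 8L,
                    min_loop_distance = 10000L, seed = 116L)
  out <- file.path(tempdir(), "simds")
  d <- simulate_dataset(cfg, out)
  expect_true(all(file.exists(unlist(d$paths))))

  g <- read_genome(d$paths$genome)
  expect_equal(Biostrings::width(g), 6e5)
  peaks <- read_interval_file(d$paths$peaks, "narrowPeak")
  expect_equal(nrow(peaks), 150L)
  expect_equal(peaks$summit, d$sites$summit)
  muts <- read_mutation_table(d$paths$mutations)
  expect_equal(nrow(muts), nrow(d$mutations))
  loops <- read_bedpe(d$paths$loops)
  expect_gt(nrow(loops), 0L)
  tads <- read_interval_file(d$paths$tads, "bed3")
  expect_true(all(tads$end > tads$start))
  genes <- read_gene_table(d$paths$genes)
  expect_true(all(genes$expression >= 0))
  pp <- read_pileup(d$paths$pileup_good)
  expect_true(all(pp$base %in% c("A", "C", "G", "T", "N", "*")))

  # truth sidecar is consistent with the emitted mutation table
  truth <- utils::read.delim(d$paths$truth_sites, stringsAsFactors = FALSE)
  w <- build_analysis_windows(peaks, flank = 1000L)
  expect_equal(truth$mut_count, site_core_counts(w, muts))
})

test_that("one master seed fixes every emitted byte", {
  cfg <- sim_config(genome_length = 3e5, n_chroms = 1L, n_sites = 60L,
                    tad_length = 5e4, genes_per_tad = 6L,
                    min_loop_distance = 10000L, seed = 117L)
  d1 <- simulate_dataset(cfg, file.path(tempdir(), "det1"))
  d2 <- simulate_dataset(cfg, file.path(tempdir(), "det2"))
  for (nm in names(d1$paths)) {
    expect_identical(readLines(d1$paths[[nm]]), readLines(d2$paths[[nm]]),
                     info = nm)
  }
})
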