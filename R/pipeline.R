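#' Pipeline configuration
#'
#' Analysis parameters with defaults matching the study design: 200 bp
#' core half-width, 1 kb profile flank (5 kb for indels), 1000
#' expected-rate resamples, 500 regions x 10 repetitions and 200 genes x
#' 100 repetitions for the expression comparison, and 100 sites x 50
#' repetitions for the outcome burden test.
#'
#' @param ... Named overrides.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(core_halfwidth = 200L, flank = 1000L, indel_flank = 5000L,
              n_resamples = 1000L,
              n_region_sample = 500L, n_region_reps = 10L,
              n_gene_sample = 200L, n_gene_reps = 100L,
              n_site_sample = 100L, n_site_reps = 50L,
              quantile_k = 4L,
              sharing_edges = list(patient_specific = c(1, 1),
                                   shared_2 = c(2, 3),
                                   shared_gt3 = c(4, Inf)),
              min_depth = 10L, min_baseq = 13L, min_mapq = 0L,
              motif_epsilon = 0.05, motif_p_target = 1e-3,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown pipeline_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

# resolve an input specification (directory or named path list) to paths
resolve_inputs <- function(input) {
  if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    nm <- c(genome = "genome.fa", peaks = "sites.narrowPeak",
            mutations = "mutations.tsv", loops = "loops.bedpe",
            tads = "tads.bed", genes = "genes.tsv",
            candidates = "candidates.tsv",
            truth_sites = "truth_sites.tsv",
            pileup_good = "pileup_good.tsv",
            pileup_poor_met = "pileup_poor_met.tsv")
    paths <- file.path(input, nm)
    names(paths) <- names(nm)
    as.list(paths[file.exists(paths)])
  } else {
    as.list(input)
  }
}

#' Run the full figure-equivalent analysis pipeline
#'
#' Orchestrates every stage over one input dataset: observed and
#' expected rate profiles with the core-vs-flank enrichment test,
#' intensity-quartile and sharing stratification, the outcome burden
#' sampling test and top-site ranking, negative binomial burden and
#' contact models with covariate-corrected contact frequency, the
#' topological versus proximity expression comparison, pileup-based
#' variant screening, and motif-shift scoring of the top recurrent
#' mutation. All statistical tables are written as TSV; re-running with
#' the same inputs and config is byte-identical.
#'
#' @param input Directory produced by [simulate_dataset()], or a named
#'   list of file paths (`genome`, `peaks`, `mutations`, and per stage
#'   `loops`, `tads`, `genes`, `candidates`, `pileup_*`).
#' @param outdir Output directory (created; existing files overwritten).
#' @param stages Character vector of stages to run, a subset of
#'   `rates`, `enrich`, `stratify`, `regress`, `topology`, `variants`,
#'   `motif`.
#' @param config `pipeline_config`.
#' @param pwm_library Named list of `pwm` objects for the motif stage
#'   (default: a small synthetic demonstration library).
#' @return Invisible named list of result objects per stage.
#' @export
run_full_analysis <- function(input, outdir,
                              stages = c("rates", "enrich", "stratify",
                                         "regress", "topology", "variants",
                                         "motif"),
                              config = pipeline_config(),
                              pwm_library = NULL) {
  paths <- resolve_inputs(input)
  need <- c("genome", "peaks", "mutations")
  if ("topology" %in% stages) need <- c(need, "loops", "tads", "genes")
  if ("variants" %in% stages) need <- c(need, "candidates", "pileup_good",
                                        "pileup_poor_met")
  missing_in <- setdiff(need, names(paths))
  if (length(missing_in) > 0L) {
    stop("missing input(s) for requested stages: ",
         paste(missing_in, collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  counts <- list()
  genome <- read_genome(paths$genome)
  sites <- read_interval_file(paths$peaks, dialect = "narrowPeak")
  sites$site_id <- if (all(nzchar(sites$name)) && !anyDuplicated(sites$name))
    sites$name else as.character(seq_len(nrow(sites)))
  mutations <- read_mutation_table(paths$mutations)
  windows <- build_analysis_windows(sites, flank = config$flank,
                                    core_halfwidth = config$core_halfwidth)
  meta <- NULL
  if (!is.null(paths$truth_sites)) {
    meta <- utils::read.delim(paths$truth_sites, stringsAsFactors = FALSE)
    meta <- meta[match(windows$site_id, meta$site_id), , drop = FALSE]
  }
  intensity <- if (!is.null(meta)) meta$intensity else
    sites$signal[match(windows$site_id, sites$site_id)]
  core_counts <- site_core_counts(windows, mutations, config$core_halfwidth)

  if ("rates" %in% stages) {
    obs <- observed_rate_profile(windows, mutations, "SNV")
    write_rate_profile(obs, file.path(outdir, "observed_profile_snv.tsv"))
    model <- fit_trinucleotide_model(mutations, genome, windows)
    write_trinuc_model(model, file.path(outdir, "trinuc_model.tsv"))
    expd <- expected_rate_profile(windows, genome, model,
                                  n_resamples = config$n_resamples,
                                  seed = derive_seed(config$seed, 11L))
    write_rate_profile(expd, file.path(outdir, "expected_profile_snv.tsv"))
    indel_windows <- build_analysis_windows(sites, flank = config$indel_flank,
                                            core_halfwidth = config$core_halfwidth)
    obs_indel <- observed_rate_profile(indel_windows, mutations,
                                       c("INS", "DEL"))
    write_rate_profile(obs_indel,
                       file.path(outdir, "observed_profile_indel.tsv"))
    res$rates <- list(observed = obs, expected = expd,
                      observed_indel = obs_indel, model = model)
    counts$rates <- length(obs$offsets)
  }
  if ("enrich" %in% stages) {
    obs <- res$rates$observed
    if (is.null(obs)) obs <- observed_rate_profile(windows, mutations, "SNV")
    fam <- list(all_sites = enrichment_test(obs, config$core_halfwidth,
                                            config$flank))
    tissue_groups <- split(seq_len(nrow(mutations)), mutations$control_tissue)
    for (tg in names(tissue_groups)) {
      fam[[paste0("control_", tg)]] <- enrichment_test(
        observed_rate_profile(windows,
                              mutations[tissue_groups[[tg]], , drop = FALSE],
                              "SNV"),
        config$core_halfwidth, config$flank)
    }
    enr <- enrichment_family(fam)
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    spec6 <- substitution_spectrum(windows, mutations, config$core_halfwidth,
                                   config$flank)
    utils::write.table(spec6, file.path(outdir, "substitution_spectrum.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$enrich <- list(enrichment = enr, spectrum = spec6)
    counts$enrich <- nrow(enr)
  }
  if ("stratify" %in% stages) {
    strat_q <- stratify_by_quantile(windows, mutations, intensity,
                                    k = config$quantile_k,
                                    core_halfwidth = config$core_halfwidth,
                                    flank_max = config$flank)
    utils::write.table(strat_q$table,
                       file.path(outdir, "stratify_intensity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$stratify <- list(intensity = strat_q)
    if (!is.null(meta) && !is.null(meta$sharing_count)) {
      strat_s <- stratify_by_sharing(windows, mutations, meta$sharing_count,
                                     edges = config$sharing_edges,
                                     core_halfwidth = config$core_halfwidth,
                                     flank_max = config$flank)
      utils::write.table(strat_s$table,
                         file.path(outdir, "stratify_sharing.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$stratify$sharing <- strat_s
    }
    if (!is.null(meta) && !is.null(meta$outcome)) {
      grp <- split(seq_along(windows$site_id), meta$outcome)
      grp <- grp[names(grp) %in% c("good", "poor_met", "core")]
      if (all(lengths(grp) >= config$n_site_sample) && length(grp) >= 2L) {
        ob <- outcome_burden_test(windows, mutations, grp,
                                  n_sample = config$n_site_sample,
                                  n_reps = config$n_site_reps,
                                  core_halfwidth = config$core_halfwidth,
                                  seed = derive_seed(config$seed, 12L))
        utils::write.table(ob$pairwise,
                           file.path(outdir, "outcome_burden.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res$stratify$outcome <- ob
      }
    }
    top <- rank_sites_by_burden(windows, mutations, config$core_halfwidth)
    utils::write.table(utils::head(top, 50L),
                       file.path(outdir, "top_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$stratify$top_sites <- top
    counts$stratify <- nrow(strat_q$table)
  }
  if ("regress" %in% stages) {
    preds <- data.frame(log_intensity = log(intensity))
    if (!is.null(meta) && !is.null(meta$sharing_count)) {
      preds$sharing_count <- meta$sharing_count
    }
    fit <- fit_negative_binomial(core_counts, preds)
    write_model_summary(fit, file.path(outdir, "regression_burden.tsv"))
    res$regress <- list(burden_fit = fit)
    counts$regress <- fit$n_obs
  }
  if ("topology" %in% stages) {
    loops <- read_bedpe(paths$loops)
    tads <- read_interval_file(paths$tads, dialect = "bed3")
    genes <- read_gene_table(paths$genes)
    site_df <- data.frame(chrom = windows$chrom,
                          start = windows$summit - 250L,
                          end = windows$summit + 250L,
                          summit = windows$summit,
                          mut_count = core_counts,
                          stringsAsFactors = FALSE)
    cf <- contact_frequency(site_df, loops)
    corrected <- covariate_corrected_residuals(
      cf, data.frame(log_intensity = log(intensity)))
    utils::write.table(
      data.frame(site_id = windows$site_id, contact = cf,
                 corrected_contact = corrected$values,
                 mut_count = core_counts),
      file.path(outdir, "corrected_contact.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    res$topology <- list(contact = cf, corrected = corrected)
    for (mode in c("topological", "proximity_50kb")) {
      cmp <- expression_by_mutation_group(
        site_df, loops, tads, genes, mode = mode,
        n_region_sample = config$n_region_sample,
        n_region_reps = config$n_region_reps,
        n_gene_sample = config$n_gene_sample,
        n_gene_reps = config$n_gene_reps,
        seed = derive_seed(config$seed, 13L))
      utils::write.table(cmp$pairwise,
                         file.path(outdir, paste0("expression_", mode, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$topology[[mode]] <- cmp
    }
    counts$topology <- length(cf)
  }
  if ("variants" %in% stages) {
    cand <- utils::read.delim(paths$candidates, stringsAsFactors = FALSE)
    frac <- numeric(0)
    calls_all <- list()
    for (g in c("good", "poor_met")) {
      counts_g <- count_alleles(paths[[paste0("pileup_", g)]], cand,
                                min_baseq = config$min_baseq,
                                min_mapq = config$min_mapq)
      calls <- call_potential_somatic(counts_g, cand,
                                      min_depth = config$min_depth)
      calls$site_id <- cand$site_id
      calls$sample_group <- g
      calls_all[[g]] <- calls
      groups <- split(unique(cand$site_id[cand$outcome == g]),
                      rep(g, length(unique(cand$site_id[cand$outcome == g]))))
      frac[g] <- outcome_fraction(calls, groups)[[g]]
    }
    calls_df <- do.call(rbind, calls_all)
    utils::write.table(calls_df, file.path(outdir, "variant_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_group = names(frac),
                                  fraction_sites_with_call = frac),
                       file.path(outdir, "outcome_fraction.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$variants <- list(calls = calls_df, outcome_fraction = frac)
    counts$variants <- nrow(calls_df)
  }
  if ("motif" %in% stages) {
    if (is.null(pwm_library)) pwm_library <- demo_pwm_library()
    top <- res$stratify$top_sites
    if (is.null(top)) top <- rank_sites_by_burden(windows, mutations,
                                                  config$core_halfwidth)
    ms <- motif_stage(genome, mutations, top, pwm_library,
                      epsilon = config$motif_epsilon,
                      p_target = config$motif_p_target,
                      seed = derive_seed(config$seed, 14L))
    utils::write.table(ms, file.path(outdir, "motif_shift.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$motif <- ms
    counts$motif <- nrow(ms)
  }
  manifest <- c(
    paste0("package_version=", as.character(utils::packageVersion("tfburden"))),
    paste0("seed=", config$seed),
    paste0("config=", paste(names(config), vapply(config, function(x)
      paste(deparse(x), collapse = ""), ""), sep = ":", collapse = "; ")),
    paste0("stage_rows=", paste(names(counts), unlist(counts), sep = ":",
                                collapse = ",")))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(res)
}

# score the top-burden site's most recurrent core SNV against a PWM library
motif_stage <- function(genome, mutations, top_sites, pwm_library,
                        window_bp = 20L, epsilon = 0.05, p_target = 1e-3,
                        seed) {
  snv <- mutations[mutations$mut_type == "SNV", , drop = FALSE]
  top <- top_sites[top_sites$mut_count > 0L, , drop = FALSE]
  if (nrow(top) == 0L) stop("no mutated site available for motif scoring")
  site <- top[1L, ]
  near <- snv[snv$chrom == site$chrom &
                abs(snv$pos - site$summit) <= 200L, , drop = FALSE]
  if (nrow(near) == 0L) stop("top site has no core SNV")
  key <- paste(near$pos, near$ref, near$alt)
  pick <- near[which.max(ave(rep(1L, nrow(near)), key, FUN = sum)), ]
  ref_seq <- get_sequence(genome, pick$chrom, pick$pos - window_bp,
                          pick$pos + window_bp)
  mut_seq <- ref_seq
  substr(mut_seq, window_bp + 1L, window_bp + 1L) <- pick$alt
  thr <- vapply(pwm_library, function(p) {
    calibrate_threshold(p, seq_length = nchar(ref_seq), p_target = p_target,
                        seed = seed)
  }, numeric(1L))
  out <- motif_score_ratio(ref_seq, mut_seq, pwm_library,
                           mut_positions = window_bp + 1L, epsilon = epsilon,
                           thresholds = thr)
  out$chrom <- pick$chrom
  out$pos <- pick$pos
  out
}

#' Small synthetic PWM library for demonstration runs
#'
#' Six synthetic motifs of widths 6-10 built from fixed consensus
#' sequences with moderate information content; used by the pipeline's
#' motif stage when no library is supplied. Synthetic: these are not
#' database motifs.
#'
#' @return Named list of `pwm` objects.
#' @export
demo_pwm_library <- function() {
  consensi <- c(synthA = "TGACCA", synthB = "CACGTG", synthC = "GGGCGG",
                synthD = "TTGACTCA", synthE = "CAGCTGTT", synthF = "GGATTACAGG")
  out <- list()
  for (nm in names(consensi)) {
    chars <- strsplit(consensi[[nm]], "")[[1L]]
    counts <- matrix(2, nrow = 4L, ncol = length(chars),
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(match(chars, c("A", "C", "G", "T")), seq_along(chars))] <- 40
    out[[nm]] <- pwm_from_counts(counts, nm)
  }
  out
}
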