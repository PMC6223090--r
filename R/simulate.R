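#' Synthetic-study configuration
#'
#' Returns the default configuration of the synthetic-data generator,
#' optionally overridden. The defaults define the study conditions every
#' emitted dataset emulates: a 10 Mb two-chromosome genome, 5000 binding
#' sites with log-normal intensity, 50 mutation donors, an aggregate
#' background rate of 2.5e-3 mutations per bp across the cohort, a
#' 1.25-fold planted enrichment within 200 bp of summits, an
#' APOBEC-weighted 96-class substitution signature, sharing and outcome
#' burden modifiers normalized to leave the mean core enrichment at the
#' planted value, a contact model whose log-mean is linear in log
#' intensity (and optionally mutation count), and a loop-target
#' expression shift for highly mutated sites.
#'
#' @param ... Named overrides of any default field.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    genome_length = 1.2e7, n_chroms = 2L, gc_content = 0.41,
    n_sites = 5000L, site_width = 300L,
    intensity_meanlog = 1, intensity_sdlog = 0.5,
    n_donors = 50L, n_chip_samples = 18L,
    sharing_logit_a = 0, sharing_logit_b = 1.5,
    background_rate = 2.5e-3, core_enrichment = 1.25, core_halfwidth = 200L,
    signature = apobec_signature(),
    sharing_effect = 0.3, intensity_burden_effect = 0.3,
    outcome_fracs = c(good = 0.1, poor_met = 0.1, core = 0.1),
    outcome_burden_mult = 1.5,
    indel_rate = 2e-4, indel_core_mult = 0.8, indel_max_len = 10L,
    control_tissue_fracs = c(blood = 0.107, adjacent = 0.018, unknown = 0.875),
    tad_length = 2e5, genes_per_tad = 12L, gene_length = 2000L,
    expr_meanlog = 3, expr_sdlog = 1,
    contact_a = 0.5, contact_b = 0.8, contact_c = 0, contact_theta = 5,
    min_loop_distance = 60000L, expression_shift = 1, shift_min_mut = 3L,
    pileup_depth_mean = 30, pileup_alt_fraction = 0.3,
    pileup_variant_prob = c(good = 0.1, poor_met = 0.3),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$core_enrichment >= 0, cfg$gc_content >= 0, cfg$gc_content <= 1,
            abs(sum(cfg$signature) - 1) < 1e-8, length(cfg$signature) == 96L)
  structure(cfg, class = "sim_config")
}

#' APOBEC-weighted default substitution signature
#'
#' Places extra mass on C>T and C>G changes at TpC contexts (T\[C>T\]N and
#' T\[C>G\]N), the hallmark of APOBEC cytidine-deaminase activity, over a
#' uniform floor across all 96 classes.
#'
#' @param apobec_weight Total mass on the eight TpC APOBEC classes
#'   (default 0.5).
#' @return Named 96-vector of class probabilities summing to 1.
#' @export
apobec_signature <- function(apobec_weight = 0.5) {
  classes <- trinuc_classes()
  w <- rep(1, 96)
  apo <- grepl("^T\\[C>[GT]\\]", classes)
  w <- w * (1 - apobec_weight) / sum(w)
  w[apo] <- w[apo] + apobec_weight / sum(apo)
  stats::setNames(w / sum(w), classes)
}

# deterministic stream of sub-seeds below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 999331 * k) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Simulate a random genome
#'
#' I.i.d. bases at the configured GC content, split evenly over
#' `n_chroms` chromosomes named `chr1..chrN`.
#'
#' @param config `sim_config`.
#' @return Named `DNAStringSet`.
#' @export
simulate_genome <- function(config) {
  stopifnot(config$genome_length >= 1e4)
  gc <- config$gc_content
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chrom_len <- floor(config$genome_length / config$n_chroms)
  with_seed(derive_seed(config$seed, 1L), {
    seqs <- vapply(seq_len(config$n_chroms), function(i) {
      idx <- sample.int(4L, chrom_len, replace = TRUE, prob = prob)
      intToUtf8(c(65L, 67L, 71L, 84L)[idx])
    }, character(1L))
    names(seqs) <- paste0("chr", seq_len(config$n_chroms))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulate binding sites and somatic mutations
#'
#' Sites are laid on a jittered grid (guaranteeing non-overlapping
#' analysis windows at the default flank), given log-normal intensities,
#' per-patient sharing counts whose inclusion probability increases with
#' intensity, and outcome labels. SNVs are drawn by sampling class
#' counts from the 96-class signature and placing each class only at
#' matching trinucleotide positions, with placement weight multiplied by
#' the core enrichment factor (modulated by sharing, intensity and
#' outcome, normalized to mean 1 across sites) within
#' `core_halfwidth` bp of summits. Indels are placed uniformly with a
#' separate core multiplier and carry no context model.
#'
#' @param config `sim_config`.
#' @param genome `DNAStringSet` from [simulate_genome()].
#' @return List with `sites` (data frame: site_id, chrom, start, end,
#'   summit, intensity, sharing_count, outcome, burden_mult),
#'   `mutations` (mutation data frame) and `truth` (per-site planted
#'   quantities plus scalar parameters).
#' @export
simulate_sites_and_mutations <- function(config, genome) {
  chrom_names <- names(genome)
  chrom_len <- Biostrings::width(genome)[1L]
  n <- config$n_sites
  per_chrom <- diff(floor(seq(0, n, length.out = length(chrom_names) + 1L)))
  margin <- 1200L
  sites_list <- list()
  with_seed(derive_seed(config$seed, 2L), {
    for (ci in seq_along(chrom_names)) {
      nc <- per_chrom[ci]
      if (nc == 0L) next
      spacing <- floor((chrom_len - 2L * margin) / nc)
      min_spacing <- max(config$site_width + 10L, 2L * config$core_halfwidth + 200L)
      if (spacing < min_spacing) {
        stop("cannot place ", nc, " non-overlapping sites on a ",
             chrom_len, " bp chromosome")
      }
      jitter_max <- max(1L, min(300L, floor((spacing - min_spacing) / 2L)))
      centers <- margin + spacing * (seq_len(nc) - 1L) + floor(spacing / 2L)
      summit <- as.integer(centers +
                             sample.int(2L * jitter_max + 1L, nc, replace = TRUE) -
                             jitter_max - 1L)
      sites_list[[ci]] <- data.frame(chrom = chrom_names[ci], summit = summit,
                                     stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, sites_list)
    sites$site_id <- sprintf("site_%05d", seq_len(nrow(sites)))
    half_w <- floor(config$site_width / 2L)
    sites$start <- sites$summit - half_w - 1L
    sites$end <- sites$summit + half_w
    sites$intensity <- stats::rlnorm(nrow(sites), config$intensity_meanlog,
                                     config$intensity_sdlog)
    z_int <- as.numeric(scale(log(sites$intensity)))
    incl_p <- stats::plogis(config$sharing_logit_a + config$sharing_logit_b * z_int)
    sites$sharing_count <- stats::rbinom(nrow(sites), config$n_chip_samples, incl_p)
    sites$sharing_count <- pmax(sites$sharing_count, 1L)
    outc <- rep("none", nrow(sites))
    fr <- config$outcome_fracs
    n_lab <- floor(fr * nrow(sites))
    pick <- sample.int(nrow(sites), sum(n_lab))
    outc[pick] <- rep(names(n_lab), n_lab)
    sites$outcome <- outc
    # per-site relative burden multiplier inside the core, mean-normalized
    z_sh <- as.numeric(scale(sites$sharing_count))
    raw <- pmax(0.1, (1 + config$sharing_effect * z_sh) *
                  (1 + config$intensity_burden_effect * z_int) *
                  ifelse(outc == "poor_met", config$outcome_burden_mult, 1))
    sites$burden_mult <- raw / mean(raw)
    rownames(sites) <- NULL
    sites <- sites[, c("site_id", "chrom", "start", "end", "summit",
                       "intensity", "sharing_count", "outcome", "burden_mult")]
    mutations <- simulate_mutation_draw(config, genome, sites,
                                        derive_seed(config$seed, 3L))
    truth <- list(sites = sites,
                  params = list(core_enrichment = config$core_enrichment,
                                background_rate = config$background_rate,
                                core_halfwidth = config$core_halfwidth,
                                seed = config$seed))
    list(sites = sites, mutations = mutations, truth = truth)
  })
}

#' Precompute the mutation placement engine
#'
#' Builds the state shared by replicated mutation draws over a fixed
#' genome and site layout: linearized per-position core weights and the
#' per-context position pools. Pass the result to
#' [simulate_mutation_draw()] when drawing many mutation realizations of
#' the same study design.
#'
#' @param config `sim_config`.
#' @param genome `DNAStringSet`.
#' @param sites Site data frame from [simulate_sites_and_mutations()].
#' @return Opaque engine list.
#' @export
prepare_mutation_engine <- function(config, genome, sites) {
  chrom_names <- names(genome)
  chrom_len <- Biostrings::width(genome)
  offsets_chrom <- c(0, cumsum(as.numeric(chrom_len)))[seq_along(chrom_names)]
  L <- sum(chrom_len)
  # linearized per-position placement weight: 1 outside cores
  weight <- rep(1, L)
  core_lo <- offsets_chrom[match(sites$chrom, chrom_names)] +
    sites$summit - config$core_halfwidth
  core_hi <- core_lo + 2L * config$core_halfwidth
  core_w <- config$core_enrichment * sites$burden_mult
  for (i in seq_len(nrow(sites))) {
    weight[core_lo[i]:core_hi[i]] <- core_w[i]
  }
  ctx <- unlist(lapply(chrom_names, function(ch) {
    context_codes(genome, rep(ch, chrom_len[match(ch, chrom_names)]),
                  seq_len(chrom_len[match(ch, chrom_names)]))
  }), use.names = FALSE)
  pools <- lapply(seq_len(32L), function(cx) which(ctx == cx))
  pool_w <- lapply(pools, function(p) weight[p])
  list(chrom_names = chrom_names, chrom_len = chrom_len,
       offsets_chrom = offsets_chrom, L = L, weight = weight,
       pools = pools, pool_w = pool_w,
       total_weight = sum(weight, na.rm = TRUE))
}

#' Draw one realization of the mutation process
#'
#' Draws SNVs (signature class counts placed at matching trinucleotide
#' positions with core weighting) and indels over a fixed genome and
#' site layout; exposed separately from [simulate_sites_and_mutations()]
#' so replicated draws can reuse a prepared engine.
#'
#' @param config `sim_config`.
#' @param genome `DNAStringSet`.
#' @param sites Site data frame.
#' @param seed Integer seed for this draw.
#' @param engine Optional result of [prepare_mutation_engine()].
#' @return Mutation data frame.
#' @export
simulate_mutation_draw <- function(config, genome, sites, seed, engine = NULL) {
  if (is.null(engine)) engine <- prepare_mutation_engine(config, genome, sites)
  chrom_names <- engine$chrom_names
  offsets_chrom <- engine$offsets_chrom
  L <- engine$L
  with_seed(seed, {
    n_total <- stats::rpois(1L, config$background_rate * engine$total_weight)
    class_counts <- as.integer(stats::rmultinom(1L, n_total, config$signature))
    ctx_of_class <- class_context_index()
    pos_all <- integer(0); class_all <- integer(0)
    for (cx in seq_len(32L)) {
      cnt <- sum(class_counts[ctx_of_class == cx])
      if (cnt == 0L) next
      pool <- engine$pools[[cx]]
      if (length(pool) == 0L) {
        stop("no genomic position matches context ", trinuc_contexts()[cx])
      }
      picked <- pool[sample.int(length(pool), cnt, replace = TRUE,
                                prob = engine$pool_w[[cx]])]
      cls <- rep(which(ctx_of_class == cx), class_counts[ctx_of_class == cx])
      pos_all <- c(pos_all, picked)
      class_all <- c(class_all, cls)
    }
    chrom_idx <- findInterval(pos_all - 0.5, c(offsets_chrom, L))
    chrom <- chrom_names[chrom_idx]
    pos <- as.integer(pos_all - offsets_chrom[chrom_idx])
    labels <- trinuc_classes()[class_all]
    class_ref <- substr(labels, 3L, 3L)
    class_alt <- substr(labels, 5L, 5L)
    center <- get_sequence(genome, chrom, pos, pos)
    flip <- center %in% c("A", "G")
    ref <- ifelse(flip, revcomp(class_ref), class_ref)
    alt <- ifelse(flip, revcomp(class_alt), class_alt)
    donors <- sprintf("D%03d", sample.int(config$n_donors, length(pos), replace = TRUE))
    snv <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      donor_id = donors, mut_type = "SNV",
                      stringsAsFactors = FALSE)
    indels <- simulate_indels(config, genome, engine$weight, offsets_chrom,
                              chrom_names)
    muts <- rbind(snv, indels)
    tissue <- sample(names(config$control_tissue_fracs), config$n_donors,
                     replace = TRUE, prob = config$control_tissue_fracs)
    names(tissue) <- sprintf("D%03d", seq_len(config$n_donors))
    muts$control_tissue <- tissue[muts$donor_id]
    muts <- muts[order(muts$chrom, muts$pos), , drop = FALSE]
    rownames(muts) <- NULL
    build_mutation_table(muts)
  })
}

# uniform-background indels with their own core multiplier (no context model)
simulate_indels <- function(config, genome, weight, offsets_chrom, chrom_names) {
  L <- length(weight)
  w <- ifelse(weight > 1, config$indel_core_mult, 1)
  n_ind <- stats::rpois(1L, config$indel_rate * sum(w))
  if (n_ind == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), donor_id = character(),
                      mut_type = character(), stringsAsFactors = FALSE))
  }
  pos_lin <- sample.int(L - 20L, n_ind, replace = TRUE, prob = w[seq_len(L - 20L)]) + 2L
  chrom_len <- diff(c(offsets_chrom, L))
  chrom_idx <- findInterval(pos_lin - 0.5, c(offsets_chrom, L))
  chrom <- chrom_names[chrom_idx]
  pos <- as.integer(pos_lin - offsets_chrom[chrom_idx])
  len <- pmin(1L + stats::rgeom(n_ind, 0.4), config$indel_max_len)
  is_ins <- stats::runif(n_ind) < 0.5
  anchor <- get_sequence(genome, chrom, pos, pos)
  ref <- ifelse(is_ins, anchor,
                get_sequence(genome, chrom, pos, pmin(pos + len, chrom_len[chrom_idx])))
  ins_seq <- vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1L))
  alt <- ifelse(is_ins, paste0(anchor, ins_seq), anchor)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             donor_id = sprintf("D%03d", sample.int(config$n_donors, n_ind,
                                                    replace = TRUE)),
             mut_type = ifelse(is_ins, "INS", "DEL"),
             stringsAsFactors = FALSE)
}

#' Simulate chromatin topology and gene expression
#'
#' Tiles the site-bearing chromosomes into TADs of `tad_length`, places
#' `genes_per_tad` genes per TAD with log-normal baseline expression,
#' draws per-site contact counts from a negative binomial whose log-mean
#' is linear in standardized log intensity and (optionally) core
#' mutation count, emits that many loops from each site to distal
#' (`> min_loop_distance` bp) same-TAD genes, and multiplies the
#' expression of loop targets of sites with at least `shift_min_mut`
#' core mutations by `exp(expression_shift)`. Genes merely linearly
#' proximal to those sites receive no shift.
#'
#' @param config `sim_config`.
#' @param sites Site data frame with `chrom`, `summit`, `intensity` and
#'   a `mut_count` column (core mutation count per site).
#' @return List with `tads`, `genes`, `loops` data frames and
#'   `shifted_genes` (character vector of planted shifted gene ids).
#' @export
simulate_topology_expression <- function(config, sites) {
  if (is.null(sites$mut_count)) stop("sites must carry a mut_count column")
  with_seed(derive_seed(config$seed, 4L), {
    tad_len <- as.integer(config$tad_length)
    tads_list <- list()
    for (ch in unique(sites$chrom)) {
      span <- max(sites$summit[sites$chrom == ch]) + tad_len
      n_tad <- ceiling(span / tad_len)
      tads_list[[ch]] <- data.frame(chrom = ch,
                                    start = tad_len * (seq_len(n_tad) - 1L),
                                    end = tad_len * seq_len(n_tad),
                                    stringsAsFactors = FALSE)
    }
    tads <- do.call(rbind, tads_list)
    rownames(tads) <- NULL
    gpt <- config$genes_per_tad
    glen <- as.integer(config$gene_length)
    slot <- floor((tad_len - glen) / gpt)
    genes_list <- lapply(seq_len(nrow(tads)), function(ti) {
      starts <- tads$start[ti] + slot * (seq_len(gpt) - 1L) +
        sample.int(max(slot - glen, 1L), gpt, replace = TRUE)
      data.frame(gene_id = sprintf("g_%04d_%02d", ti, seq_len(gpt)),
                 chrom = tads$chrom[ti], start = starts, end = starts + glen,
                 strand = sample(c("+", "-"), gpt, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, genes_list)
    genes$expression <- stats::rlnorm(nrow(genes), config$expr_meanlog,
                                      config$expr_sdlog)
    rownames(genes) <- NULL
    # per-site contact counts
    z_int <- as.numeric(scale(log(sites$intensity)))
    mu <- exp(config$contact_a + config$contact_b * z_int +
                config$contact_c * sites$mut_count)
    contact <- stats::rnbinom(nrow(sites), size = config$contact_theta, mu = mu)
    # loop targets: distal same-TAD genes
    tad_key_gene <- paste(genes$chrom, floor((genes$start + genes$end) / 2) %/% tad_len)
    tad_key_site <- paste(sites$chrom, (sites$summit - 1L) %/% tad_len)
    loop_rows <- vector("list", nrow(sites))
    target_ids <- vector("list", nrow(sites))
    gene_mid <- floor((genes$start + genes$end) / 2)
    for (i in seq_len(nrow(sites))) {
      if (contact[i] == 0L) next
      cand <- which(tad_key_gene == tad_key_site[i] &
                      abs(gene_mid - sites$summit[i]) > config$min_loop_distance)
      if (length(cand) == 0L) next
      k <- min(contact[i], length(cand))
      tg <- cand[sample.int(length(cand), k)]
      target_ids[[i]] <- genes$gene_id[tg]
      loop_rows[[i]] <- data.frame(
        chrom_a = sites$chrom[i], start_a = sites$summit[i] - 250L,
        end_a = sites$summit[i] + 250L, chrom_b = genes$chrom[tg],
        start_b = genes$start[tg], end_b = genes$end[tg], weight = 1,
        stringsAsFactors = FALSE)
    }
    loops <- do.call(rbind, loop_rows)
    if (is.null(loops)) {
      loops <- data.frame(chrom_a = character(), start_a = integer(),
                          end_a = integer(), chrom_b = character(),
                          start_b = integer(), end_b = integer(),
                          weight = numeric(), stringsAsFactors = FALSE)
    }
    rownames(loops) <- NULL
    high <- sites$mut_count >= config$shift_min_mut
    shifted <- unique(unlist(target_ids[high]))
    if (config$expression_shift != 0 && length(shifted) > 0L) {
      sel <- genes$gene_id %in% shifted
      genes$expression[sel] <- genes$expression[sel] * exp(config$expression_shift)
    }
    list(tads = tads, genes = genes, loops = loops,
         contact_count = as.integer(contact),
         shifted_genes = if (length(shifted)) shifted else character(0))
  })
}

#' Simulate read pileups with planted variant alleles
#'
#' For each candidate position and sample group, draws a read depth
#' around `pileup_depth_mean` and, where a variant is planted for that
#' group, a Binomial(`depth`, `pileup_alt_fraction`) number of
#' alternative-allele reads; remaining reads carry the reference base.
#'
#' @param config `sim_config`.
#' @param candidates Data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `site_id`, `outcome` (outcome class of the parent site).
#' @return List of per-group pileup data frames (`good`, `poor_met`) and
#'   `planted` (logical matrix positions x groups).
#' @export
simulate_pileups <- function(config, candidates) {
  with_seed(derive_seed(config$seed, 5L), {
    groups <- names(config$pileup_variant_prob)
    planted <- matrix(FALSE, nrow = nrow(candidates), ncol = length(groups),
                      dimnames = list(NULL, groups))
    pileups <- list()
    for (g in groups) {
      pvar <- config$pileup_variant_prob[[g]]
      has_var <- stats::runif(nrow(candidates)) <
        ifelse(candidates$outcome == g, pvar, pvar / 3)
      planted[, g] <- has_var
      depth <- stats::rpois(nrow(candidates), config$pileup_depth_mean)
      n_alt <- ifelse(has_var,
                      stats::rbinom(nrow(candidates), depth,
                                    config$pileup_alt_fraction), 0L)
      total <- sum(depth)
      base <- rep(candidates$ref, depth)
      first <- cumsum(depth) - depth  # 0-based row offset per position
      alt_rows <- unlist(mapply(function(s, k) if (k > 0L) s + seq_len(k),
                                first, n_alt, SIMPLIFY = FALSE))
      if (length(alt_rows) > 0L) {
        base[alt_rows] <- rep(candidates$alt, n_alt)[seq_along(alt_rows)]
      }
      pileups[[g]] <- data.frame(
        chrom = rep(candidates$chrom, depth), pos = rep(candidates$pos, depth),
        base = base, baseq = 20L + stats::rpois(total, 10L), mapq = 30L,
        sample = g, stringsAsFactors = FALSE)
    }
    list(pileups = pileups, planted = planted)
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator stage under one master seed and writes all
#' pipeline inputs in their standard formats to `outdir`: genome FASTA,
#' sites narrowPeak, summits BED, mutations TSV, loops BEDPE, TADs BED,
#' genes TSV, per-group pileup TSVs, candidate-variant TSV, plus a
#' ground-truth sidecar (per-site TSV and key-value parameter file).
#'
#' @param config `sim_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisible list with the in-memory objects and file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  sm <- simulate_sites_and_mutations(config, genome)
  sites <- sm$sites
  windows <- build_analysis_windows(sites, flank = 1000L,
                                    core_halfwidth = config$core_halfwidth)
  sites$mut_count <- site_core_counts(windows, sm$mutations,
                                      config$core_halfwidth)
  topo <- simulate_topology_expression(config, sites)
  # candidate variant positions: core SNVs mapped back to their site
  hits <- map_mutations_to_windows(windows, sm$mutations)
  hits <- hits[abs(hits$offset) <= config$core_halfwidth, , drop = FALSE]
  snv_idx <- hits$mut_idx[sm$mutations$mut_type[hits$mut_idx] == "SNV"]
  site_of <- hits$site_idx[sm$mutations$mut_type[hits$mut_idx] == "SNV"]
  cand <- data.frame(chrom = sm$mutations$chrom[snv_idx],
                     pos = sm$mutations$pos[snv_idx],
                     ref = sm$mutations$ref[snv_idx],
                     alt = sm$mutations$alt[snv_idx],
                     site_id = sites$site_id[site_of],
                     outcome = sites$outcome[site_of],
                     stringsAsFactors = FALSE)
  cand <- cand[!duplicated(paste(cand$chrom, cand$pos)), , drop = FALSE]
  pile <- simulate_pileups(config, cand)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    peaks = file.path(outdir, "sites.narrowPeak"),
    summits = file.path(outdir, "summits.bed"),
    mutations = file.path(outdir, "mutations.tsv"),
    loops = file.path(outdir, "loops.bedpe"),
    tads = file.path(outdir, "tads.bed"),
    genes = file.path(outdir, "genes.tsv"),
    candidates = file.path(outdir, "candidates.tsv"),
    truth_sites = file.path(outdir, "truth_sites.tsv"),
    truth_params = file.path(outdir, "truth_params.txt"))
  Biostrings::writeXStringSet(genome, paths$genome, width = 80L)
  np <- sites
  np$name <- np$site_id; np$score <- round(np$intensity * 100)
  np$strand <- "."; np$signal <- np$intensity; np$pvalue <- -1; np$qvalue <- -1
  write_interval_file(np, paths$peaks, dialect = "narrowPeak")
  write_interval_file(data.frame(chrom = sites$chrom,
                                 start = sites$summit - 1L,
                                 end = sites$summit), paths$summits,
                      dialect = "bed3")
  write_mutation_table(sm$mutations, paths$mutations)
  write_bedpe(topo$loops, paths$loops)
  write_interval_file(topo$tads, paths$tads, dialect = "bed3")
  utils::write.table(topo$genes[, c("gene_id", "chrom", "start", "end",
                                    "strand", "expression")],
                     paths$genes, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cand, paths$candidates, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (g in names(pile$pileups)) {
    paths[[paste0("pileup_", g)]] <- file.path(outdir, paste0("pileup_", g, ".tsv"))
    utils::write.table(pile$pileups[[g]], paths[[paste0("pileup_", g)]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth_sites <- sites
  truth_sites$contact_count <- topo$contact_count
  utils::write.table(truth_sites, paths$truth_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  par <- sm$truth$params
  writeLines(paste0(names(par), "=", unlist(par)), paths$truth_params)
  invisible(list(config = config, genome = genome, sites = sites,
                 windows = windows, mutations = sm$mutations, topo = topo,
                 candidates = cand, pileups = pile, paths = paths))
}
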