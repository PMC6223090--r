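#' Core-versus-flank mutation enrichment test
#'
#' Contrasts the per-position mutation rate within `core_halfwidth` bp of
#' the summit against the flanking rate (offsets with
#' `core_halfwidth < |offset| <= flank_max`) using a 2x2 Pearson
#' chi-square test (no continuity correction by default) on
#' `[[core_mut, core_pos - core_mut], [flank_mut, flank_pos - flank_mut]]`.
#' The fold change is the ratio of the two rates. Benjamini-Hochberg
#' correction across an analysis family is applied by the caller via
#' [enrichment_family()].
#'
#' @param profile A `rate_profile` (observed counts), or a list/vector
#'   with named elements `core_mut`, `core_pos`, `flank_mut`, `flank_pos`.
#' @param core_halfwidth Core half-width in bp (default 200).
#' @param flank_max Outer flank limit in bp (default 1000).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return Object of class `enrichment_result`: list with `fold_change`,
#'   `chi2_stat`, `p_value`, `q_value` (`NA` until family adjustment) and
#'   the four counts.
#' @export
enrichment_test <- function(profile, core_halfwidth = 200L, flank_max = 1000L,
                            correct = FALSE) {
  if (inherits(profile, "rate_profile")) {
    core <- abs(profile$offsets) <= core_halfwidth
    flank <- abs(profile$offsets) > core_halfwidth &
      abs(profile$offsets) <= flank_max
    counts <- list(core_mut = sum(profile$mut_count[core]),
                   core_pos = sum(profile$n_valid[core]),
                   flank_mut = sum(profile$mut_count[flank]),
                   flank_pos = sum(profile$n_valid[flank]))
  } else {
    counts <- as.list(profile)
  }
  with(counts, {
    if (core_pos < 1L || flank_pos < 1L) {
      stop("core and flank must each contain at least one valid position")
    }
    if (min(core_mut, flank_mut, core_pos - core_mut,
            flank_pos - flank_mut) < 0) {
      stop("negative contingency cell")
    }
    fc <- if (flank_mut > 0) {
      (core_mut / core_pos) / (flank_mut / flank_pos)
    } else NA_real_
    tab <- matrix(c(core_mut, core_pos - core_mut,
                    flank_mut, flank_pos - flank_mut),
                  nrow = 2L, byrow = TRUE)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    structure(list(fold_change = fc,
                   chi2_stat = unname(ct$statistic),
                   p_value = unname(ct$p.value),
                   q_value = NA_real_,
                   core_mut = core_mut, core_pos = core_pos,
                   flank_mut = flank_mut, flank_pos = flank_pos),
              class = "enrichment_result")
  })
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: FC = %.3f, chi2 = %.2f, p = %.3g (q = %.3g)\n",
              x$fold_change, x$chi2_stat, x$p_value, x$q_value))
  invisible(x)
}

#' Collect enrichment results into a BH-adjusted family
#'
#' One family per figure-equivalent analysis run: all group tests are
#' adjusted together with the Benjamini-Hochberg procedure.
#'
#' @param results Named list of `enrichment_result` objects.
#' @return Data frame with one row per result and a `q_value` column.
#' @export
enrichment_family <- function(results) {
  stopifnot(length(results) > 0L)
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(group = nm, fold_change = r$fold_change,
               chi2_stat = r$chi2_stat, p_value = r$p_value,
               core_mut = r$core_mut, core_pos = r$core_pos,
               flank_mut = r$flank_mut, flank_pos = r$flank_pos,
               stringsAsFactors = FALSE)
  }))
  df$q_value <- stats::p.adjust(df$p_value, method = "BH")
  rownames(df) <- NULL
  df
}

#' Six-class substitution spectrum with core/flank enrichment
#'
#' Collapses SNVs to the six pyrimidine-centered substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G) and, for each class, tests core-vs-flank
#' enrichment; q-values are BH-adjusted across the six classes.
#'
#' @param windows `summit_windows` object.
#' @param mutations Mutation data frame (SNVs selected internally).
#' @param core_halfwidth,flank_max Core/flank geometry in bp.
#' @return Data frame with per-class core/flank counts, fold change,
#'   p and q values.
#' @export
substitution_spectrum <- function(windows, mutations, core_halfwidth = 200L,
                                  flank_max = 1000L) {
  snv <- mutations[mutations$mut_type == "SNV", , drop = FALSE]
  hits <- map_mutations_to_windows(windows, snv)
  ref <- snv$ref[hits$mut_idx]
  alt <- snv$alt[hits$mut_idx]
  flip <- ref %in% c("A", "G")
  ref[flip] <- revcomp(ref[flip])
  alt[flip] <- revcomp(alt[flip])
  cls <- paste0(ref, ">", alt)
  levels6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  in_core <- abs(hits$offset) <= core_halfwidth
  in_flank <- abs(hits$offset) > core_halfwidth & abs(hits$offset) <= flank_max
  core_pos <- sum(colSums(windows$valid)[abs(windows$offsets) <= core_halfwidth])
  flank_pos <- sum(colSums(windows$valid)[abs(windows$offsets) > core_halfwidth &
                                            abs(windows$offsets) <= flank_max])
  res <- lapply(levels6, function(l6) {
    enrichment_test(list(core_mut = sum(cls == l6 & in_core),
                         core_pos = core_pos,
                         flank_mut = sum(cls == l6 & in_flank),
                         flank_pos = flank_pos))
  })
  names(res) <- levels6
  enrichment_family(res)
}
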