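#' Pipeline run configuration
#'
#' Collects every stage parameter with its study default: peak significance
#' FDR below 10 percent, normalization to one million reads, detection at
#' ten combined reads and 125 nt, significance at p < 0.05, the one-third
#' fold rule, the 100/300-nt pruning distances, the 100-nt E-box window,
#' the 1.2 read-ratio retention threshold with every-50th selection, and
#' the peak-caller window geometry. Any override is echoed in the run
#' report.
#'
#' @param fdr_max Peak/site significance threshold, percent.
#' @param norm_target Per-sample normalization total.
#' @param min_reads,min_length Detection filter thresholds.
#' @param alpha Differential significance level.
#' @param fold_fraction Fold-change class fraction.
#' @param near,far TSS pruning distances, nt.
#' @param ebox_window E-box scan window, nt.
#' @param ratio_max,step Validation-region selector parameters.
#' @param window,caller_step Peak-caller window width and step, nt.
#' @param gsea_weight,n_perm Enrichment-score weight and permutation count.
#' @param seed Master seed for subsampling and permutations.
#' @param excluded_chroms Chromosomes dropped by the specificity filter.
#' @return List of class `run_config`.
#' @export
run_config <- function(fdr_max = 10, norm_target = 1e6, min_reads = 10L,
                       min_length = 125L, alpha = 0.05, fold_fraction = 1/3,
                       near = 100L, far = 300L, ebox_window = 100L,
                       ratio_max = 1.2, step = 50L, window = 200L,
                       caller_step = 50L, gsea_weight = 1, n_perm = 1000L,
                       seed = 1L, excluded_chroms = character()) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the integrative binding/expression pipeline end to end
#'
#' Stage order follows the analysis design: equal-depth subsampling, peak
#' calling (or ingestion), specificity filtering against the IgG and
#' knockdown controls, consensus-site construction, TSS-distance and E-box
#' profiling, count normalization, detection filtering, differential
#' calling, site-to-gene assignment with pruning, direct-target
#' classification, category tabulation, and gene-set enrichment of the
#' snoRNA set on the ranked expression changes.
#'
#' @param sim Output of [simulate_experiment()], or a list with the same
#'   elements (`annotation`, `genome`, `truth` optional, `tags`, `counts`)
#'   assembled from files.
#' @param config A `run_config`.
#' @param out_dir Optional directory; when given, `report.json` and
#'   `report.md` plus the stage tables are written there.
#' @return List of class `pipeline_report` with the stage outputs
#'   (`peak_sets`, `filtered`, `consensus`, `tss_profile`, `ebox`, `diff`,
#'   `assignment`, `targets`, `category_table`, `enrichment`) and a
#'   `summary` list of the headline numbers plus the full parameter echo.
#' @export
run_pipeline <- function(sim, config = run_config(), out_dir = NULL) {
  ann <- sim$annotation
  chrom_sizes <- ann$chrom_sizes

  # --- binding arm ---
  depth <- min(vapply(sim$tags, nrow, integer(1)))
  tags <- lapply(sim$tags, subsample_tags, k = depth, seed = config$seed)
  peak_sets <- lapply(names(tags), function(cond) {
    call_peaks_naive(tags[[cond]], background = NULL,
                     chrom_sizes = chrom_sizes, window = config$window,
                     step = config$caller_step, fdr_max = config$fdr_max,
                     experiment_id = "exp1", condition = cond)
  })
  names(peak_sets) <- names(tags)
  filtered <- filter_specific_peaks(
    peak_sets$specific_naive,
    control_sets = peak_sets[c("specific_depleted", "igg_naive",
                               "igg_depleted")],
    excluded_chroms = config$excluded_chroms)
  consensus <- build_consensus_sites(list(filtered), fdr_max = config$fdr_max)
  sites <- consensus$sites
  sig_sites <- sites[sites$significant, , drop = FALSE]
  ebox <- if (nrow(sites)) {
    scan_ebox(data.frame(chrom = sites$chrom,
                         summit = sites$representative_summit),
              sim$genome, window = config$ebox_window)
  } else logical(0)
  profile <- if (nrow(sites)) {
    tss_distance_profile(sites, ann, ebox = ebox)
  } else NULL

  # --- expression arm ---
  cm <- normalize_counts(sim$counts, target = config$norm_target)
  detected <- filter_detected(cm, ann, min_reads = config$min_reads,
                              min_length = config$min_length)
  diff <- differential_test(cm, detected, alpha = config$alpha)

  # --- integration ---
  assignment <- assign_sites_to_genes(consensus, ann, diff,
                                      near = config$near, far = config$far,
                                      alpha = config$alpha)
  targets <- classify_direct_targets(assignment, diff, ann = ann,
                                     fold_fraction = config$fold_fraction)
  category_table <- tabulate_categories(targets)

  # --- enrichment of the snoRNA set on the ranked list ---
  det <- diff[diff$regulation != "undetected", , drop = FALSE]
  sno_ids <- ann$genes$gene_id[ann$genes$gene_class == "snoRNA"]
  sno_det <- intersect(sno_ids, det$gene_id)
  enrichment <- if (length(sno_det) >= 3L &&
                    length(sno_det) < nrow(det)) {
    permutation_significance(ranked_list(det$gene_id, det$log2_ratio),
                             sno_det, weight = config$gsea_weight,
                             n_perm = config$n_perm, seed = config$seed)
  } else NULL

  summary <- list(
    n_tags_per_condition = depth,
    n_peaks_per_condition = lapply(peak_sets, nrow),
    n_peaks_specific = nrow(filtered),
    n_consensus_sites = nrow(sites),
    n_significant_sites = nrow(sig_sites),
    pct_sites_ebox = if (length(ebox)) 100 * mean(ebox) else NA_real_,
    pct_sites_within_100nt = if (!is.null(profile))
      profile$cumulative$within_100_all else NA_real_,
    n_genes_detected = length(detected),
    n_down_significant = sum(diff$regulation == "down_significant"),
    n_up_significant = sum(diff$regulation == "up_significant"),
    n_direct_activated = sum(targets$direct_activated),
    n_direct_repressed = sum(targets$direct_repressed),
    category_subtotal = category_table$subtotal,
    category_percent = category_table$percent,
    enrichment = if (is.null(enrichment)) NULL else unclass(enrichment),
    parameters = unclass(config))

  report <- structure(
    list(peak_sets = peak_sets, filtered = filtered, consensus = consensus,
         tss_profile = profile, ebox = ebox, diff = diff,
         assignment = assignment, targets = targets,
         category_table = category_table, enrichment = enrichment,
         summary = summary),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("Integrative binding/expression pipeline report\n")
  cat(sprintf("  specific peaks: %d; consensus sites: %d (%d significant)\n",
              s$n_peaks_specific, s$n_consensus_sites, s$n_significant_sites))
  cat(sprintf("  detected genes: %d; down/up significant: %d/%d\n",
              s$n_genes_detected, s$n_down_significant, s$n_up_significant))
  cat(sprintf("  direct targets: %d activated, %d repressed (%d/%d in RiBi/translation, %d%%)\n",
              s$n_direct_activated, s$n_direct_repressed,
              s$category_subtotal, s$n_direct_activated, s$category_percent))
  if (!is.null(x$enrichment)) {
    cat("  snoRNA set enrichment: "); print(x$enrichment)
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (machine-readable summary), `report.md`
#' (human-readable) and the main stage tables as TSV.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report$summary, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, na = "null",
                       pretty = TRUE)
  utils::write.table(report$diff, file.path(dir, "diff_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$targets, file.path(dir, "target_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$consensus$sites, file.path(dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  s <- report$summary
  md <- c(
    "# Pipeline report", "",
    sprintf("- tags per condition (subsampled): %d", s$n_tags_per_condition),
    sprintf("- specific peaks after control subtraction: %d",
            s$n_peaks_specific),
    sprintf("- consensus sites: %d (%d significant, FDR < %g%%)",
            s$n_consensus_sites, s$n_significant_sites,
            s$parameters$fdr_max),
    sprintf("- sites with canonical E-box near summit: %.1f%%",
            s$pct_sites_ebox),
    sprintf("- sites within 100 nt of a TSS: %.1f%%",
            s$pct_sites_within_100nt),
    sprintf("- detected genes: %d", s$n_genes_detected),
    sprintf("- significantly down / up upon knockdown: %d / %d",
            s$n_down_significant, s$n_up_significant),
    sprintf("- direct targets: %d activated, %d repressed",
            s$n_direct_activated, s$n_direct_repressed),
    sprintf("- RiBi/translation subtotal: %d of %d (%d%%)",
            s$category_subtotal, s$n_direct_activated, s$category_percent),
    "", "## Parameters", "",
    vapply(names(s$parameters), function(p) {
      sprintf("- %s: %s", p, paste(format(s$parameters[[p]]), collapse = ", "))
    }, character(1)))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Evaluate recovery of the planted truth
#'
#' Compares the pipeline's direct-target calls and specific peak list
#' against the simulator's ground truth.
#'
#' @param report A `pipeline_report`.
#' @param truth The simulator truth list.
#' @param detected Optional character vector restricting the truth targets
#'   to detectable genes; defaults to genes not `undetected` in the
#'   report's differential table.
#' @return List with `sensitivity`, `fdr` (of the direct-activated calls),
#'   `sticky_removed_fraction` (fraction of sticky regions free of
#'   specific peaks), and `site_sensitivity`/`site_fdr` for significant
#'   consensus sites against planted true sites.
#' @export
evaluate_recovery <- function(report, truth, detected = NULL) {
  if (is.null(detected)) {
    detected <- report$diff$gene_id[report$diff$regulation != "undetected"]
  }
  truth_targets <- truth$genes$gene_id[truth$genes$is_direct_target]
  truth_targets <- intersect(truth_targets, detected)
  called <- report$targets$gene_id[report$targets$direct_activated]
  sens <- if (length(truth_targets)) {
    mean(truth_targets %in% called)
  } else NA_real_
  fdr <- if (length(called)) mean(!called %in% truth_targets) else 0

  filt <- report$filtered
  sticky_hit <- vapply(seq_len(nrow(truth$sticky)), function(i) {
    any(filt$chrom == truth$sticky$chrom[i] &
          filt$start < truth$sticky$end[i] &
          filt$end > truth$sticky$start[i])
  }, logical(1))

  sites <- report$consensus$sites
  sig <- sites[sites$significant, , drop = FALSE]
  true_hit <- vapply(seq_len(nrow(truth$sites)), function(i) {
    any(sig$chrom == truth$sites$chrom[i] &
          sig$start < truth$sites$end[i] &
          sig$end > truth$sites$start[i])
  }, logical(1))
  site_fp <- if (nrow(sig)) {
    vapply(seq_len(nrow(sig)), function(i) {
      !any(truth$sites$chrom == sig$chrom[i] &
             truth$sites$start < sig$end[i] &
             truth$sites$end > sig$start[i])
    }, logical(1))
  } else logical(0)

  list(sensitivity = sens, fdr = fdr,
       sticky_removed_fraction = mean(!sticky_hit),
       site_sensitivity = mean(true_hit),
       site_fdr = if (nrow(sig)) mean(site_fp) else 0)
}
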