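#' Construct a gene-by-sample count matrix
#'
#' Raw RNA-seq counts for the knockdown design: `myc_kd` vs `ctrl_kd`
#' replicates (the standard design has three of each; other designs are
#' accepted with a warning).
#'
#' @param counts Integer matrix, genes in rows (rownames = gene_id),
#'   samples in columns.
#' @param conditions Character vector (`myc_kd`/`ctrl_kd`), one per column.
#' @return Object of class `count_matrix`: list with `counts`, `samples`
#'   (data.frame: `sample_id`, `condition`, `replicate`) and `normalized`
#'   (NULL until [normalize_counts()] is applied).
#' @export
count_matrix <- function(counts, conditions) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry gene_id rownames")
  if (length(conditions) != ncol(counts)) {
    stop("one condition label per sample column is required")
  }
  if (!all(conditions %in% c("myc_kd", "ctrl_kd"))) {
    stop("conditions must be 'myc_kd' or 'ctrl_kd'")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  tab <- table(factor(conditions, levels = c("myc_kd", "ctrl_kd")))
  if (any(tab != 3L)) {
    warning(sprintf(
      "non-standard design (%d myc_kd vs %d ctrl_kd replicates); the standard design has 3 vs 3",
      tab[["myc_kd"]], tab[["ctrl_kd"]]))
  }
  replicate <- stats::ave(seq_along(conditions), conditions, FUN = seq_along)
  samples <- data.frame(
    sample_id = if (is.null(colnames(counts))) {
      paste0(conditions, "_", replicate)
    } else colnames(counts),
    condition = conditions, replicate = replicate,
    stringsAsFactors = FALSE)
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples, normalized = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)%s\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$samples$condition, collapse = ", "),
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' Read/write a count matrix as TSV
#'
#' First column `gene_id`; remaining column names are `<condition>.<rep>`
#' so the condition labels travel in the header.
#'
#' @param cm A `count_matrix`.
#' @param path File path.
#' @return `write_counts`: `path` invisibly. `read_counts`: a
#'   `count_matrix`.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  names(df)[-1] <- paste0(cm$samples$condition, ".", cm$samples$replicate)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  count_matrix(counts, sub("\\..*$", "", colnames(counts)))
}

#' Normalize each sample to a fixed total read number
#'
#' Scales every sample column so that its total equals `target` reads
#' (default one million), preserving within-sample proportions.
#'
#' @param cm A `count_matrix`.
#' @param target Target column total.
#' @return The `count_matrix` with its `normalized` slot filled.
#' @export
normalize_counts <- function(cm, target = 1e6) {
  cs <- colSums(cm$counts)
  if (any(cs == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(cm$samples$sample_id[cs == 0], collapse = ", "))
  }
  cm$normalized <- sweep(cm$counts, 2L, target / cs, `*`)
  cm
}

#' Detection filter on raw counts and transcript length
#'
#' A gene is detected iff its raw counts summed over all samples reach
#' `min_reads` and its annotated transcript length reaches `min_length`
#' (short transcripts are unreliable in this library preparation, so the
#' study design excludes them).
#'
#' @param cm A `count_matrix`.
#' @param ann A `genome_annotation` covering every gene in `cm`.
#' @param min_reads Combined raw-count threshold (default 10, inclusive).
#' @param min_length Transcript-length threshold in nt (default 125,
#'   inclusive).
#' @return Character vector of detected gene_ids.
#' @export
filter_detected <- function(cm, ann, min_reads = 10L, min_length = 125L) {
  genes <- rownames(cm$counts)
  idx <- match(genes, ann$genes$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) missing from annotation: ",
         paste(genes[is.na(idx)], collapse = ", "))
  }
  total <- rowSums(cm$counts)
  len <- ann$genes$transcript_length[idx]
  genes[total >= min_reads & len >= min_length]
}

#' Differential expression test between knockdown and control
#'
#' For each detected gene, condition means of normalized counts, the log2
#' knockdown/control ratio (pseudocount 1 keeps zero-count conditions
#' finite), and a two-sided Student t test with pooled variance on
#' log2(normalized + 1) replicate values. With three replicates per group
#' the pooled test is exactly calibrated under the null, whereas
#' unequal-variance corrections lose calibration at such small group sizes;
#' the equal-replicate knockdown design justifies pooling. A gene is called
#' significant at unadjusted p < `alpha`; Benjamini-Hochberg adjusted
#' p-values are additionally reported in `p_adjusted` for users who want
#' multiplicity control, without changing the default calls.
#'
#' @param cm A normalized `count_matrix` (see [normalize_counts()]).
#' @param detected Character vector of detected gene_ids (see
#'   [filter_detected()]); genes not listed are reported as `undetected`.
#' @param alpha Significance level on the unadjusted p-value.
#' @param pseudocount Pseudocount for the log2 ratio and the log transform.
#' @return data.frame (`diff_result`) with one row per gene in `cm`:
#'   `gene_id`, `mean_ctrl`, `mean_kd`, `log2_ratio`, `p_value`,
#'   `p_adjusted`, `regulation` in
#'   `{down_significant, up_significant, unchanged, undetected}`.
#'   `log2_ratio` and `p_value` are NA for undetected genes.
#' @export
differential_test <- function(cm, detected, alpha = 0.05, pseudocount = 1) {
  if (is.null(cm$normalized)) {
    stop("count_matrix must be normalized first (see normalize_counts)")
  }
  kd <- cm$samples$condition == "myc_kd"
  ct <- cm$samples$condition == "ctrl_kd"
  n1 <- sum(ct); n2 <- sum(kd)
  if (n1 < 2L || n2 < 2L) stop("at least 2 replicates per condition required")
  norm <- cm$normalized
  lx <- log2(norm + pseudocount)

  mean_ctrl <- rowMeans(norm[, ct, drop = FALSE])
  mean_kd <- rowMeans(norm[, kd, drop = FALSE])
  m1 <- rowMeans(lx[, ct, drop = FALSE])
  m2 <- rowMeans(lx[, kd, drop = FALSE])
  v1 <- apply(lx[, ct, drop = FALSE], 1L, stats::var)
  v2 <- apply(lx[, kd, drop = FALSE], 1L, stats::var)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se2 <- pooled * (1 / n1 + 1 / n2)
  t_stat <- (m2 - m1) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  # degenerate cases: no variance in either group
  zero_var <- se2 == 0
  p[zero_var] <- ifelse(m1[zero_var] == m2[zero_var], 1, 0)

  is_det <- rownames(norm) %in% detected
  log2_ratio <- log2((mean_kd + pseudocount) / (mean_ctrl + pseudocount))
  p[!is_det] <- NA_real_
  log2_ratio[!is_det] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[is_det] <- stats::p.adjust(p[is_det], method = "BH")

  regulation <- rep("unchanged", nrow(norm))
  regulation[!is_det] <- "undetected"
  sig <- is_det & !is.na(p) & p < alpha
  regulation[sig & log2_ratio < 0] <- "down_significant"
  regulation[sig & log2_ratio > 0] <- "up_significant"

  res <- data.frame(gene_id = rownames(norm), mean_ctrl = mean_ctrl,
                    mean_kd = mean_kd, log2_ratio = log2_ratio,
                    p_value = p, p_adjusted = p_adj,
                    regulation = regulation, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Fold-change regulation class on condition means
#'
#' A detected gene is `down_by_third` when its knockdown mean has dropped
#' to at most `1 - fold_fraction` of the control mean (boundary inclusive),
#' and `up_by_third` under the reciprocal rule on the ratio scale
#' (`mean_kd >= mean_ctrl / (1 - fold_fraction)`), so that swapping the
#' condition labels maps the two classes onto each other exactly.
#'
#' @param dr A `diff_result` data.frame (or any data.frame with
#'   `mean_ctrl`, `mean_kd` and optionally `regulation`).
#' @param fold_fraction Fractional change defining the classes (default
#'   1/3).
#' @return Character vector, one of `down_by_third`, `up_by_third`,
#'   `unchanged` per gene (`undetected` passes through for undetected
#'   genes).
#' @export
classify_regulation <- function(dr, fold_fraction = 1/3) {
  .stopifnot_cols(dr, c("mean_ctrl", "mean_kd"), "'dr'")
  keep <- 1 - fold_fraction
  cls <- rep("unchanged", nrow(dr))
  both_zero <- dr$mean_ctrl == 0 & dr$mean_kd == 0
  down <- !both_zero & dr$mean_kd <= keep * dr$mean_ctrl
  up <- !both_zero & dr$mean_kd >= dr$mean_ctrl / keep
  cls[down] <- "down_by_third"
  cls[up] <- "up_by_third"
  if ("regulation" %in% names(dr)) cls[dr$regulation == "undetected"] <- "undetected"
  cls
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR quantification: per sample, the target Ct is referenced to the mean
#' Ct of the reference genes (delta Ct); per condition, the mean delta Ct is
#' then referenced to the calibrator condition (delta-delta Ct) and
#' expressed as `2^(-ddCt) * 100`, so the calibrator condition reads
#' exactly 100%.
#'
#' @param ct data.frame with columns `gene_id`, `sample_id`, `condition`,
#'   `ct`; every (gene, sample) pair must be present.
#' @param reference_genes Character vector (>= 1) of reference gene_ids
#'   whose average anchors the quantification.
#' @param calibrator Condition label used as the 100% baseline.
#' @return data.frame with `gene_id`, `condition`, `percent_expression`
#'   for every non-reference target gene.
#' @export
ddct_relative_expression <- function(ct, reference_genes, calibrator) {
  .stopifnot_cols(ct, c("gene_id", "sample_id", "condition", "ct"), "'ct'")
  if (length(reference_genes) < 1L) stop("at least one reference gene required")
  if (anyNA(ct$ct)) stop("missing Ct value(s)")
  samples <- unique(ct$sample_id)
  genes <- unique(ct$gene_id)
  full <- expand.grid(gene_id = genes, sample_id = samples,
                      stringsAsFactors = FALSE)
  have <- paste(ct$gene_id, ct$sample_id)
  if (!all(paste(full$gene_id, full$sample_id) %in% have)) {
    stop("missing Ct value(s): every (gene, sample) pair must be measured")
  }
  if (!all(reference_genes %in% genes)) {
    stop("reference gene(s) without Ct values: ",
         paste(setdiff(reference_genes, genes), collapse = ", "))
  }
  if (!calibrator %in% ct$condition) {
    stop("calibrator condition not present: ", calibrator)
  }
  ref <- ct[ct$gene_id %in% reference_genes, ]
  ref_mean <- tapply(ref$ct, ref$sample_id, mean)
  ct$dct <- ct$ct - ref_mean[ct$sample_id]
  targets <- setdiff(genes, reference_genes)
  out <- list()
  for (g in targets) {
    sel <- ct[ct$gene_id == g, ]
    dct_cond <- tapply(sel$dct, sel$condition, mean)
    ddct <- dct_cond - dct_cond[[calibrator]]
    out[[g]] <- data.frame(gene_id = g, condition = names(ddct),
                           percent_expression = 2^(-as.numeric(ddct)) * 100,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
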