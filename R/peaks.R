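#' Construct a peak set
#'
#' One ChIP experiment's called peaks: interval, summit, enrichment score
#' and the caller's per-peak FDR estimate in percent (the significance rule
#' downstream is FDR < 10).
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `summit` (absolute position, `start <= summit < end`),
#'   `score` and `fdr_percent` (in \[0, 100\]).
#' @param experiment_id Experiment label carried by every peak.
#' @param condition One of the four ChIP conditions.
#' @param chrom_sizes Optional named vector used to validate intervals.
#' @return Object of class `peak_set` (a data.frame with attributes
#'   `experiment_id` and `condition`).
#' @export
peak_set <- function(peaks, experiment_id,
                     condition = c("specific_naive", "specific_depleted",
                                   "igg_naive", "igg_depleted"),
                     chrom_sizes = NULL) {
  condition <- match.arg(condition)
  .stopifnot_cols(peaks, c("chrom", "start", "end", "summit", "score",
                           "fdr_percent"), "'peaks'")
  peaks <- data.frame(chrom = as.character(peaks$chrom),
                      start = as.integer(peaks$start),
                      end = as.integer(peaks$end),
                      summit = as.integer(peaks$summit),
                      score = as.numeric(peaks$score),
                      fdr_percent = as.numeric(peaks$fdr_percent),
                      stringsAsFactors = FALSE)
  peaks$experiment_id <- rep_len(as.character(experiment_id), nrow(peaks))
  if (nrow(peaks)) {
    if (any(peaks$start > peaks$summit | peaks$summit >= peaks$end)) {
      stop("summit must satisfy start <= summit < end")
    }
    if (any(peaks$fdr_percent < 0 | peaks$fdr_percent > 100)) {
      stop("fdr_percent must lie in [0, 100]")
    }
    if (!is.null(chrom_sizes)) {
      sz <- chrom_sizes[peaks$chrom]
      if (anyNA(sz) || any(peaks$start < 0L) || any(peaks$end > sz)) {
        stop("peak interval(s) outside chrom_sizes")
      }
    }
  }
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_set", "data.frame"),
            experiment_id = experiment_id, condition = condition)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set [%s, %s]: %d peaks (%d with FDR < 10%%)\n",
              attr(x, "experiment_id"), attr(x, "condition"), nrow(x),
              sum(x$fdr_percent < 10)))
  invisible(x)
}

#' Read/write peak sets as BED6+3
#'
#' Columns 1-6 are standard BED (name = experiment_id, score = enrichment
#' statistic); columns 7-9 carry the summit offset from `start`, the
#' per-peak FDR in percent, and the ChIP condition.
#'
#' @param peaks A `peak_set`.
#' @param path File path.
#' @return `write_peaks`: `path` invisibly. `read_peaks`: a `peak_set`.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(
    data.frame(peaks$chrom, peaks$start, peaks$end, peaks$experiment_id,
               peaks$score, ".", peaks$summit - peaks$start,
               peaks$fdr_percent, attr(peaks, "condition")),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 9L) stop("expected BED6+3 with 9 columns")
  peak_set(data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                      summit = bed[[2]] + bed[[7]], score = bed[[5]],
                      fdr_percent = bed[[8]]),
           experiment_id = bed[[4]][1], condition = bed[[9]][1])
}

#' Naive sliding-window peak caller
#'
#' A deliberately simple caller used as plumbing for synthetic end-to-end
#' runs (real caller output can be ingested with [read_peaks()] instead).
#' Fixed windows are scored by a Poisson upper-tail p-value of the treatment
#' tag count against a background rate taken as the maximum of the
#' genome-wide rate and a +/- 5 kb local estimate; Benjamini-Hochberg across
#' all windows yields a per-window FDR; windows must additionally clear a
#' minimum fold enrichment over the background rate (the usual guard
#' against the adaptive-threshold cascade admitting barely elevated
#' windows); overlapping significant windows are merged and the summit is
#' placed at the position of maximal treatment coverage (tags extended by
#' `tag_extend` nt in their strand direction), leftmost on ties.
#'
#' @param treatment,background `tag_set`s at equal depth. `background =
#'   NULL` estimates local rates from the treatment itself.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window Window width in nt.
#' @param step Window step in nt.
#' @param fdr_max Per-window FDR threshold in percent.
#' @param min_fold Minimum fold enrichment of the window count over its
#'   background expectation.
#' @param local_halfwidth Half-width of the local background window (nt).
#' @param tag_extend Tag extension used for summit coverage (nt).
#' @param experiment_id,condition Labels for the returned `peak_set`.
#' @return A `peak_set`; the peak `fdr_percent` is the minimum over merged
#'   windows and `score` the maximal fold enrichment over the background
#'   rate.
#' @export
call_peaks_naive <- function(treatment, background = NULL, chrom_sizes,
                             window = 200L, step = 50L, fdr_max = 10,
                             min_fold = 2, local_halfwidth = 5000L,
                             tag_extend = 50L,
                             experiment_id = "exp1",
                             condition = attr(treatment, "condition")) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(), score = numeric(),
                      fdr_percent = numeric())
  if (nrow(treatment) == 0L) {
    return(peak_set(empty, experiment_id, condition))
  }
  bg <- if (is.null(background)) treatment else background
  genome_len <- sum(as.numeric(chrom_sizes))
  rate_global <- nrow(bg) / genome_len  # tags per nt

  win <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    if (len < window) next
    ws <- seq.int(0L, len - window, by = step)
    tpos <- sort(treatment$pos[treatment$chrom == ch])
    bpos <- sort(bg$pos[bg$chrom == ch])
    cnt <- .count_in_intervals(tpos, ws, ws + window)
    centre <- ws + window %/% 2L
    lo <- pmax(0L, centre - local_halfwidth)
    hi <- pmin(len, centre + local_halfwidth)
    bcnt <- .count_in_intervals(bpos, lo, hi)
    rate_local <- bcnt / (hi - lo)
    lambda <- pmax(rate_global, rate_local) * window
    p <- stats::ppois(cnt - 1L, lambda, lower.tail = FALSE)
    win[[ch]] <- data.frame(chrom = ch, start = ws, end = ws + window,
                            cnt = cnt, lambda = lambda, p = p)
  }
  win <- do.call(rbind, win)
  win$fdr_percent <- stats::p.adjust(win$p, method = "BH") * 100
  sig <- win[win$fdr_percent < fdr_max & win$cnt > 0L &
               win$cnt >= min_fold * win$lambda, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(peak_set(empty, experiment_id, condition))
  }

  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    ir <- .as_iranges(s$start, s$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    tsel <- treatment[treatment$chrom == ch, , drop = FALSE]
    ext <- ifelse(tsel$strand == "-",
                  pmax(0L, tsel$pos - tag_extend + 1L), tsel$pos)
    cov <- IRanges::coverage(
      .as_iranges(ext, pmin(ext + tag_extend, chrom_sizes[[ch]])),
      width = chrom_sizes[[ch]])
    for (k in seq_along(red)) {
      members <- s[grp == k, , drop = FALSE]
      p_start <- IRanges::start(red)[k] - 1L
      p_end <- IRanges::end(red)[k]
      seg <- S4Vectors::window(cov, start = p_start + 1L, end = p_end)
      summit <- p_start + which.max(as.integer(seg)) - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = p_start, end = p_end, summit = summit,
        score = max(members$cnt / pmax(members$lambda, 1e-9)),
        fdr_percent = min(members$fdr_percent))
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  peak_set(out, experiment_id, condition)
}
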