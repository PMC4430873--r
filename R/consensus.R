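#' Specificity filtering of ChIP peaks against negative controls
#'
#' Removes from a specific-antibody peak list every peak that (a) lies on an
#' excluded chromosome (unmappable contigs), or (b) overlaps, by at least
#' one base, any peak called in a negative-control ChIP (non-immune IgG, or
#' the specific antibody in knockdown cells). The operation is idempotent
#' and returns a subset of its input.
#'
#' @param myc_peaks A `peak_set` from the specific antibody.
#' @param control_sets List of control `peak_set`s (may be empty, in which
#'   case only the chromosome filter applies).
#' @param excluded_chroms Character vector of chromosome names to drop.
#' @return A filtered `peak_set`.
#' @export
filter_specific_peaks <- function(myc_peaks, control_sets = list(),
                                  excluded_chroms = character()) {
  keep <- !(myc_peaks$chrom %in% excluded_chroms)
  if (length(control_sets) && nrow(myc_peaks)) {
    ctrl <- do.call(rbind, lapply(control_sets, function(s) {
      data.frame(chrom = s$chrom, start = s$start, end = s$end)
    }))
    if (nrow(ctrl)) {
      for (ch in unique(myc_peaks$chrom)) {
        sel <- which(myc_peaks$chrom == ch)
        csel <- ctrl[ctrl$chrom == ch, , drop = FALSE]
        if (!nrow(csel)) next
        ov <- IRanges::overlapsAny(
          .as_iranges(myc_peaks$start[sel], myc_peaks$end[sel]),
          .as_iranges(csel$start, csel$end), minoverlap = 1L)
        keep[sel] <- keep[sel] & !ov
      }
    }
  }
  out <- myc_peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(myc_peaks),
            experiment_id = attr(myc_peaks, "experiment_id"),
            condition = attr(myc_peaks, "condition"))
}

#' Build consensus binding sites across experiments
#'
#' Pools specificity-filtered peaks from several experiments and clusters
#' them by single-linkage interval overlap (>= 1 shared base). Each cluster
#' becomes one consensus site spanning the union of its members. A site is
#' significant iff any member peak has FDR < `fdr_max`; this implements the
#' rescue rule under which a non-significant peak is kept when it overlaps a
#' significant one. The representative summit is taken from the member with
#' the smallest FDR (ties: highest score, then leftmost).
#'
#' @param peak_sets List of `peak_set`s (already specificity-filtered).
#' @param fdr_max Significance threshold in percent (default 10).
#' @return Object of class `consensus_sites`: a list with `sites` (one row
#'   per site: `site_id`, `chrom`, `start`, `end`, `n_members`,
#'   `experiments`, `significant`, `representative_summit`, `min_fdr`,
#'   sorted by chrom then start) and `members` (the pooled peaks with their
#'   `site_id`).
#' @export
build_consensus_sites <- function(peak_sets, fdr_max = 10) {
  pooled <- do.call(rbind, lapply(peak_sets, function(s) {
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               summit = s$summit, score = s$score,
               fdr_percent = s$fdr_percent, experiment_id = s$experiment_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    sites <- data.frame(site_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        n_members = integer(), experiments = character(),
                        significant = logical(),
                        representative_summit = integer(), min_fdr = numeric())
    return(structure(list(sites = sites,
                          members = cbind(pooled, site_id = character())),
                     class = "consensus_sites"))
  }
  pooled$site_id <- NA_character_
  site_rows <- list()
  for (ch in sort(unique(pooled$chrom))) {
    sel <- which(pooled$chrom == ch)
    ir <- .as_iranges(pooled$start[sel], pooled$end[sel])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (k in seq_along(red)) {
      m <- sel[grp == k]
      mem <- pooled[m, , drop = FALSE]
      rep_idx <- m[order(mem$fdr_percent, -mem$score, mem$start)[1]]
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        chrom = ch,
        start = IRanges::start(red)[k] - 1L,
        end = IRanges::end(red)[k],
        n_members = length(m),
        experiments = paste(sort(unique(mem$experiment_id)), collapse = ","),
        significant = min(mem$fdr_percent) < fdr_max,
        representative_summit = pooled$summit[rep_idx],
        min_fdr = min(mem$fdr_percent),
        stringsAsFactors = FALSE)
      pooled$site_id[m] <- paste(ch, IRanges::start(red)[k] - 1L, sep = ":")
    }
  }
  sites <- do.call(rbind, site_rows)
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  sites$site_id <- sprintf("site_%05d", seq_len(nrow(sites)))
  key <- paste(sites$chrom, sites$start, sep = ":")
  pooled$site_id <- sites$site_id[match(pooled$site_id, key)]
  sites <- sites[, c("site_id", "chrom", "start", "end", "n_members",
                     "experiments", "significant", "representative_summit",
                     "min_fdr")]
  rownames(sites) <- NULL
  rownames(pooled) <- NULL
  structure(list(sites = sites, members = pooled),
            class = "consensus_sites")
}

#' @export
print.consensus_sites <- function(x, ...) {
  cat(sprintf("consensus_sites: %d sites (%d significant) from %d peaks\n",
              nrow(x$sites), sum(x$sites$significant), nrow(x$members)))
  invisible(x)
}

#' Venn-style overlap counts across 2 or 3 experiments
#'
#' Counts, for every region of the Venn diagram, the consensus sites whose
#' member peaks come from exactly that subset of experiments.
#'
#' @param peak_sets List of 2 or 3 `peak_set`s.
#' @param fdr_max Passed to [build_consensus_sites()].
#' @return Named integer vector over all non-empty experiment subsets
#'   (names like `"A"`, `"A&B"`); the cells sum to the number of consensus
#'   sites.
#' @export
overlap_counts <- function(peak_sets, fdr_max = 10) {
  if (length(peak_sets) < 2L || length(peak_sets) > 3L) {
    stop("overlap_counts supports 2 or 3 peak sets")
  }
  ids <- vapply(peak_sets, attr, character(1), "experiment_id")
  if (anyDuplicated(ids)) stop("experiment_ids must be distinct")
  cons <- build_consensus_sites(peak_sets, fdr_max = fdr_max)
  subsets <- unlist(lapply(seq_along(ids), function(k) {
    utils::combn(sort(ids), k, paste, collapse = "&", simplify = FALSE)
  }))
  counts <- stats::setNames(integer(length(subsets)), subsets)
  if (nrow(cons$sites)) {
    obs <- vapply(strsplit(cons$sites$experiments, ","), function(e) {
      paste(sort(e), collapse = "&")
    }, character(1))
    tab <- table(obs)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' TSS-distance profile of binding sites
#'
#' Bins the distance from each site to its closest TSS: 100-nt bins up to
#' 1,000 nt, 1,000-nt bins up to 10,000 nt, and an overflow bin. Fractions
#' are percent of all sites; cumulative shares within 100 nt and 1,000 nt of
#' the TSS are reported as well, and everything is computed separately for
#' the E-box-positive subset when flags are supplied.
#'
#' @param sites data.frame with `chrom`, `start`, `end` (and `summit` when
#'   `distance_from = "summit"`), e.g. the `sites` element of a
#'   `consensus_sites`.
#' @param ann A `genome_annotation`.
#' @param ebox Optional logical vector, one flag per site, marking sites
#'   with a canonical E-box (see [scan_ebox()]).
#' @param distance_from `"edge"` or `"summit"`, passed to [closest_tss()].
#' @return List with `bins` (data.frame: `bin`, `pct_all`, `pct_ebox`),
#'   `cumulative` (shares within 100/1,000 nt), `n_sites`, `n_ebox` and
#'   `n_na` (sites with no annotated chromosome, excluded from fractions).
#' @export
tss_distance_profile <- function(sites, ann, ebox = NULL,
                                 distance_from = c("edge", "summit")) {
  distance_from <- match.arg(distance_from)
  ct <- closest_tss(sites, ann, from = distance_from)
  d <- tapply(ct$distance, ct$peak, function(x) x[1])
  d <- as.integer(d[order(as.integer(names(d)))])
  na <- is.na(d)
  breaks <- c(seq(0L, 1000L, by = 100L), seq(2000L, 10000L, by = 1000L), Inf)
  nb <- length(breaks) - 1L  # number of bins, last one is the overflow
  labels <- c(sprintf("[%d,%d)", breaks[seq_len(nb - 1L)],
                      breaks[seq_len(nb - 1L) + 1L]), ">=10000")
  cut_of <- function(x) {
    findInterval(x, breaks, rightmost.closed = FALSE)
  }
  pct <- function(sel) {
    n <- sum(sel & !na)
    if (n == 0L) return(rep(0, length(labels)))
    idx <- cut_of(d[sel & !na])
    100 * tabulate(idx, nbins = length(labels)) / n
  }
  bins <- data.frame(bin = labels, pct_all = pct(rep(TRUE, length(d))))
  cum <- list(within_100_all = if (sum(!na)) 100 * mean(d[!na] <= 100) else 0,
              within_1000_all = if (sum(!na)) 100 * mean(d[!na] <= 1000) else 0)
  if (!is.null(ebox)) {
    stopifnot(length(ebox) == nrow(sites))
    bins$pct_ebox <- pct(ebox)
    ne <- ebox & !na
    cum$within_100_ebox <- if (sum(ne)) 100 * mean(d[ne] <= 100) else 0
    cum$within_1000_ebox <- if (sum(ne)) 100 * mean(d[ne] <= 1000) else 0
  }
  list(bins = bins, cumulative = cum, n_sites = sum(!na),
       n_ebox = if (is.null(ebox)) NA_integer_ else sum(ebox & !na),
       n_na = sum(na))
}

#' Scan for a canonical E-box around binding summits
#'
#' Tests whether the hexamer CACGTG starts at any position within the
#' 100-nt window straddling the summit, i.e. with start in
#' `[summit - window/2, summit + window/2)`. The motif is its own reverse
#' complement, so scanning the forward strand suffices; the window is
#' clipped at chromosome ends.
#'
#' @param sites data.frame with `chrom` and a summit column (`summit` or
#'   `representative_summit`).
#' @param genome A named [Biostrings::DNAStringSet] covering the sites'
#'   chromosomes.
#' @param window Window width in nt (default 100).
#' @param motif Motif hexamer (default `"CACGTG"`).
#' @return Logical vector, one flag per site.
#' @export
scan_ebox <- function(sites, genome, window = 100L, motif = "CACGTG") {
  summit <- if ("summit" %in% names(sites)) sites$summit else
    sites$representative_summit
  if (is.null(summit)) stop("sites must carry a summit column")
  half <- window %/% 2L
  mlen <- nchar(motif)
  vapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]
    if (!ch %in% names(genome)) stop("chromosome absent from genome: ", ch)
    len <- length(genome[[ch]])
    s <- summit[i]
    if (s < 0L || s >= len) {
      stop(sprintf("summit %d outside sequence of %s", s, ch))
    }
    w_lo <- max(0L, s - half)          # first allowed motif start (0-based)
    w_hi <- min(s + half - 1L, len - mlen)  # last allowed motif start
    if (w_hi < w_lo) return(FALSE)
    seg <- Biostrings::subseq(genome[[ch]], start = w_lo + 1L,
                              end = min(len, w_hi + mlen))
    m <- Biostrings::matchPattern(motif, seg)
    any(IRanges::start(m) - 1L + w_lo <= w_hi)
  }, logical(1))
}

#' Tag-count ratio between naive and depleted conditions per region
#'
#' Counts tags whose 5' position falls inside each half-open region, in the
#' naive and depleted tag sets (subsample to equal depth first), and forms
#' the ratio naive/depleted with a pseudocount guard of 1 on the
#' denominator for regions with no depleted tags.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param naive,depleted `tag_set`s at equal depth.
#' @return `regions` with added columns `n_naive`, `n_depleted`, `ratio`.
#' @export
region_read_ratio <- function(regions, naive, depleted) {
  .stopifnot_cols(regions, c("chrom", "start", "end"), "'regions'")
  out <- regions
  out$n_naive <- .count_tags(naive, regions$chrom, regions$start, regions$end)
  out$n_depleted <- .count_tags(depleted, regions$chrom, regions$start,
                                regions$end)
  out$ratio <- out$n_naive / pmax(out$n_depleted, 1L)
  out
}

#' Select validation regions from an external peak list
#'
#' Implements the comparative re-analysis selector: retain regions whose
#' naive/depleted read ratio is at most `ratio_max` and that do not overlap
#' any of the package user's own binding sites, sort them by read count
#' descending (ties broken by chrom then start ascending), and pick every
#' `step`-th region starting from the highest-count one.
#'
#' @param regions Output of [region_read_ratio()].
#' @param own_sites data.frame with `chrom`, `start`, `end` of the user's
#'   own sites.
#' @param ratio_max Retention threshold on the ratio (inclusive).
#' @param step Selection stride along the sorted list.
#' @return The selected rows, with columns `rank` (position in the sorted
#'   retained list) added; `ceiling(n_retained / step)` rows.
#' @export
select_validation_regions <- function(regions, own_sites, ratio_max = 1.2,
                                      step = 50L) {
  .stopifnot_cols(regions, c("chrom", "start", "end", "n_naive", "ratio"),
                  "'regions'")
  keep <- regions$ratio <= ratio_max
  if (!is.null(own_sites) && nrow(own_sites)) {
    for (ch in unique(regions$chrom)) {
      sel <- which(regions$chrom == ch)
      osel <- own_sites[own_sites$chrom == ch, , drop = FALSE]
      if (!nrow(osel)) next
      ov <- IRanges::overlapsAny(
        .as_iranges(regions$start[sel], regions$end[sel]),
        .as_iranges(osel$start, osel$end), minoverlap = 1L)
      keep[sel] <- keep[sel] & !ov
    }
  }
  retained <- regions[keep, , drop = FALSE]
  if (nrow(retained) == 0L) {
    retained$rank <- integer()
    return(retained)
  }
  ord <- order(-retained$n_naive, retained$chrom, retained$start)
  retained <- retained[ord, , drop = FALSE]
  retained$rank <- seq_len(nrow(retained))
  sel <- seq.int(1L, nrow(retained), by = step)
  out <- retained[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
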