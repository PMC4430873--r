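# Small fixtures and independent brute-force oracles used across the suite.

tiny_annotation <- function(genes = NULL, chrom_len = 100000L) {
  if (is.null(genes)) {
    genes <- data.frame(
      gene_id = c("gA", "gB", "snoC", "gD"),
      chrom = c("chr1", "chr1", "chr1", "chr2"),
      start = c(1000L, 5000L, 5200L, 100L),
      end = c(2000L, 8000L, 5330L, 700L),
      strand = c("+", "-", "-", "+"),
      gene_class = c("protein_coding", "uhg", "snoRNA", "other"),
      transcript_length = c(1000L, 400L, 130L, 600L),
      host_gene_id = c(NA, NA, "gB", NA),
      stringsAsFactors = FALSE)
  }
  genome_annotation(genes, c(chr1 = chrom_len, chr2 = chrom_len))
}

random_annotation <- function(n_genes, chrom_len = 100000L,
                              chroms = c("chr1", "chr2")) {
  start <- sample.int(chrom_len - 2000L, n_genes)
  width <- sample(100:1500, n_genes, replace = TRUE)
  genome_annotation(
    data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
               chrom = sample(chroms, n_genes, replace = TRUE),
               start = start, end = start + width,
               strand = sample(c("+", "-"), n_genes, replace = TRUE),
               gene_class = "other", transcript_length = width,
               stringsAsFactors = FALSE),
    stats::setNames(rep(chrom_len, length(chroms)), chroms))
}

random_peaks <- function(n, chrom_len = 100000L, chroms = c("chr1", "chr2"),
                         experiment_id = "e1",
                         condition = "specific_naive", width_max = 800L) {
  start <- sample.int(chrom_len - 1000L, n, replace = TRUE)
  width <- sample(50:width_max, n, replace = TRUE)
  peak_set(data.frame(chrom = sample(chroms, n, replace = TRUE),
                      start = start, end = start + width,
                      summit = start + width %/% 2L,
                      score = runif(n, 1, 50),
                      fdr_percent = runif(n, 0, 100)),
           experiment_id = experiment_id, condition = condition)
}

# exhaustive all-pairs closest-TSS
bf_closest_tss <- function(peaks, ann) {
  g <- ann$genes
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    d <- rep(NA_integer_, nrow(g))
    for (j in seq_len(nrow(g))) {
      if (g$chrom[j] != peaks$chrom[i]) next
      d[j] <- max(peaks$start[i] - tss[j], tss[j] - peaks$end[i], 0L)
    }
    if (all(is.na(d))) {
      out[[i]] <- data.frame(peak = i, gene_id = NA_character_,
                             distance = NA_integer_)
    } else {
      dmin <- min(d, na.rm = TRUE)
      hit <- which(!is.na(d) & d == dmin)
      out[[i]] <- data.frame(peak = i, gene_id = g$gene_id[hit],
                             distance = dmin)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# all-pairs overlap filter
bf_filter <- function(myc, controls, excluded = character()) {
  keep <- logical(nrow(myc))
  ctrl <- do.call(rbind, lapply(controls, function(s) {
    data.frame(chrom = s$chrom, start = s$start, end = s$end)
  }))
  for (i in seq_len(nrow(myc))) {
    if (myc$chrom[i] %in% excluded) { keep[i] <- FALSE; next }
    ov <- FALSE
    if (!is.null(ctrl)) {
      for (j in seq_len(nrow(ctrl))) {
        if (myc$chrom[i] == ctrl$chrom[j] && myc$start[i] < ctrl$end[j] &&
            myc$end[i] > ctrl$start[j]) { ov <- TRUE; break }
      }
    }
    keep[i] <- !ov
  }
  which(keep)
}

# single-linkage components over peak overlap, as index sets
bf_consensus_partition <- function(pooled) {
  n <- nrow(pooled)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- pooled$chrom[i] == pooled$chrom[j] &&
      pooled$start[i] < pooled$end[j] && pooled$end[i] > pooled$start[j]
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(seq_len(n), comp), sort))
}

# 6-mer enumeration over the summit window
bf_ebox <- function(seq_chr, summit, window = 100L, motif = "CACGTG") {
  len <- nchar(seq_chr)
  half <- window %/% 2L
  for (s0 in max(0L, summit - half):(summit + half - 1L)) {
    if (s0 + 6L > len) next
    if (substr(seq_chr, s0 + 1L, s0 + 6L) == motif) return(TRUE)
  }
  FALSE
}

# plain-loop running-sum enrichment score
bf_enrichment_score <- function(gene_ids, metric, gene_set, weight) {
  ord <- order(-metric, gene_ids)
  gene_ids <- gene_ids[ord]; metric <- metric[ord]
  hit <- gene_ids %in% gene_set
  nr <- sum(abs(metric[hit])^weight)
  n <- length(gene_ids); nh <- sum(hit)
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) {
      if (nr > 0) abs(metric[i])^weight / nr else 1 / nh
    } else -1 / (n - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# brute-force region tag counting
bf_region_counts <- function(regions, tags) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(tags$chrom == regions$chrom[i] & tags$pos >= regions$start[i] &
          tags$pos < regions$end[i])
  }, integer(1))
}
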