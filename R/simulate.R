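#' Configuration for the synthetic experiment generator
#'
#' Defines the study conditions the generator emulates: a toy genome with
#' snoRNA/host-gene architecture (dedicated non-coding host genes carrying
#' 2-16 intronic snoRNAs each, plus snoRNAs hosted in protein-coding
#' genes), four ChIP tag sets (specific antibody and non-immune IgG, in
#' naive and knockdown cells) with true binding sites enriched only in the
#' specific/naive condition and "sticky" background regions enriched in all
#' four, and negative-binomial RNA-seq counts in 3 + 3 replicates where the
#' designated target genes drop upon knockdown.
#'
#' @param seed Integer master seed. Annotation, tags and counts consume the
#'   streams `seed`, `seed + 1` and `seed + 2` respectively, so each layer
#'   is individually reproducible.
#' @param n_chroms,chrom_length Genome shape (default one 2-Mb chromosome).
#' @param n_genes Number of top-level genes (intronic snoRNAs are extra
#'   records).
#' @param class_mix Named fractions over `protein_coding`,
#'   `snorna_in_host` (a protein-coding host carrying one intronic snoRNA),
#'   `uhg` (dedicated snoRNA host gene) and `other`.
#' @param length_meanlog,length_sdlog Log-normal gene-length parameters.
#' @param snorna_length_range snoRNA length range in nt; straddles the
#'   125-nt detection cutoff so that only part of the snoRNAs are
#'   detectable, as in real annotations.
#' @param uhg_introns_range Number of intronic snoRNAs per dedicated host.
#' @param n_true_sites,frac_promoter,frac_ebox,n_sticky Binding-site
#'   layout: number of true sites, fraction placed at promoters of
#'   designated target genes, fraction with a CACGTG planted at the summit,
#'   and number of sticky regions bound in all conditions.
#' @param tags_per_condition,enrichment_fold,sticky_fold,tag_spread ChIP
#'   tag totals, fold enrichment of true sites over the background rate,
#'   fold enrichment of sticky regions, and the nt spread of site tags.
#' @param expr_meanlog,expr_sdlog,target_meanlog,target_sdlog Log-normal
#'   base-expression parameters for background and affected genes.
#'   Background genes span a wide dynamic range; affected genes are drawn
#'   from a narrower moderate-expression distribution so that the affected
#'   fraction of the library mass stays small, as in the emulated design —
#'   fixed-total normalization is only composition-safe when the changing
#'   genes carry a minor share of the reads.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param effect_mean,effect_sd,effect_max Knockdown log2-effect
#'   distribution for target genes: normal(`effect_mean`, `effect_sd`)
#'   truncated to at most `effect_max`, so that every designated target is
#'   genuinely repressed past the one-third boundary (target status is
#'   response-defined).
#' @param sno_coupling Factor coupling a snoRNA's effect to its host's.
#' @param n_replicates Replicates per condition.
#' @param libsize_jitter Relative library-size jitter (uniform +/- 20% by
#'   default).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L, chrom_length = 2e6,
                       n_genes = 300L,
                       class_mix = c(protein_coding = 0.70,
                                     snorna_in_host = 0.05,
                                     uhg = 0.05,
                                     other = 0.20),
                       length_meanlog = log(1500), length_sdlog = 0.6,
                       snorna_length_range = c(46L, 316L),
                       uhg_introns_range = c(2L, 16L),
                       n_true_sites = 40L, frac_promoter = 0.9,
                       frac_ebox = 0.9, n_sticky = 10L,
                       tags_per_condition = 200000L,
                       enrichment_fold = 20, sticky_fold = 15,
                       tag_spread = 200L,
                       expr_meanlog = log(2000), expr_sdlog = 1,
                       target_meanlog = log(500), target_sdlog = 0.3,
                       dispersion = 0.01,
                       effect_mean = -1, effect_sd = 0.3, effect_max = -0.8,
                       sno_coupling = 1,
                       n_replicates = 3L, libsize_jitter = 0.2) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_chroms >= 1L, cfg$chrom_length > 0, cfg$n_genes > 0L,
    abs(sum(class_mix) - 1) < 1e-8, all(class_mix >= 0),
    setequal(names(class_mix),
             c("protein_coding", "snorna_in_host", "uhg", "other")),
    cfg$snorna_length_range[1] < 125L, cfg$snorna_length_range[2] >= 125L,
    cfg$uhg_introns_range[1] >= 1L,
    cfg$n_true_sites > 0L, cfg$n_sticky >= 0L,
    cfg$frac_promoter >= 0, cfg$frac_promoter <= 1,
    cfg$frac_ebox >= 0, cfg$frac_ebox <= 1,
    cfg$tags_per_condition > 0L, cfg$enrichment_fold > 0,
    cfg$tag_spread > 0L, cfg$dispersion > 0,
    cfg$effect_max < 0, cfg$n_replicates >= 2L,
    cfg$libsize_jitter >= 0, cfg$libsize_jitter < 1)
  class(cfg) <- "sim_config"
  cfg
}

# integer partition of `total` over n cells proportional to `prob`
.partition_counts <- function(total, prob) {
  diff(c(0L, round(cumsum(prob / sum(prob)) * total)))
}

#' Simulate a genome, annotation and binding-site truth
#'
#' Places non-overlapping genes on random strands, gives dedicated host
#' genes their intronic snoRNA records (host-linked), designates target
#' genes and plants true binding sites at their promoters (plus distal
#' sites away from any TSS), plants the CACGTG hexamer at flagged site
#' summits of an otherwise random genome sequence, and draws the knockdown
#' effect sizes that [simulate_counts()] will apply.
#'
#' @param cfg A `sim_config`.
#' @return List with `annotation` (a `genome_annotation`), `genome` (named
#'   [Biostrings::DNAStringSet]) and `truth` (see [write_truth()]): `sites`
#'   (chrom, start, end, summit, ebox, target_gene_id), `sticky`
#'   (chrom, start, end) and `genes` (gene_id, is_direct_target,
#'   planted_effect, is_snorna, host_gene_id).
#' @export
simulate_genome_annotation <- function(cfg) {
  with_seed(cfg$seed, .simulate_genome_annotation(cfg))
}

.simulate_genome_annotation <- function(cfg) {
  chroms <- paste0("chrS", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(as.integer(cfg$chrom_length),
                                     cfg$n_chroms), chroms)
  n_per_chrom <- .partition_counts(cfg$n_genes, rep(1, cfg$n_chroms))

  exon_unit <- 100L
  gene_rows <- list()
  gid <- 0L
  sid <- 0L
  next_gid <- function() { gid <<- gid + 1L; sprintf("gene_%04d", gid) }
  next_sid <- function() { sid <<- sid + 1L; sprintf("sno_%04d", sid) }

  for (ci in seq_len(cfg$n_chroms)) {
    n <- n_per_chrom[ci]
    if (n == 0L) next
    cls_counts <- .partition_counts(n, cfg$class_mix)
    classes <- sample(rep(names(cfg$class_mix), cls_counts))
    # spans and per-gene internal structure
    plan <- lapply(classes, function(cl) {
      if (cl == "uhg") {
        n_inr <- sample(seq(cfg$uhg_introns_range[1],
                            cfg$uhg_introns_range[2]), 1L)
        sno_len <- sample(seq(cfg$snorna_length_range[1],
                              cfg$snorna_length_range[2]),
                          n_inr, replace = TRUE)
        span <- (n_inr + 1L) * exon_unit + sum(sno_len + exon_unit)
        list(class = cl, span = as.integer(span), sno_len = sno_len,
             transcript_length = (n_inr + 1L) * exon_unit)
      } else if (cl == "snorna_in_host") {
        sno_len <- sample(seq(cfg$snorna_length_range[1],
                              cfg$snorna_length_range[2]), 1L)
        span <- max(800L, sno_len + 400L,
                    as.integer(round(stats::rlnorm(1, cfg$length_meanlog,
                                                   cfg$length_sdlog))))
        list(class = cl, span = span, sno_len = sno_len,
             transcript_length = span)
      } else {
        lo <- if (cl == "protein_coding") 150L else 60L
        span <- min(20000L, max(lo, as.integer(
          round(stats::rlnorm(1, cfg$length_meanlog, cfg$length_sdlog)))))
        list(class = cl, span = span, transcript_length = span)
      }
    })
    spans <- vapply(plan, `[[`, numeric(1), "span")
    leftover <- cfg$chrom_length - sum(spans)
    if (leftover < length(spans) + 1L) {
      stop("genome too small to place genes without overlap")
    }
    gaps <- as.vector(stats::rmultinom(1L, leftover - length(spans) - 1L,
                                       rep(1, length(spans) + 1L))) + 1L
    starts <- cumsum(gaps[-length(gaps)]) + cumsum(c(0L, spans[-length(spans)]))
    strands <- sample(c("+", "-"), length(spans), replace = TRUE)

    for (i in seq_along(plan)) {
      p <- plan[[i]]
      id <- next_gid()
      g_start <- as.integer(starts[i])
      g_end <- g_start + p$span
      host_class <- switch(p$class,
                           uhg = "uhg",
                           snorna_in_host = "protein_coding",
                           p$class)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = id, chrom = chroms[ci], start = g_start, end = g_end,
        strand = strands[i], gene_class = host_class,
        transcript_length = p$transcript_length,
        host_gene_id = NA_character_, category = NA_character_,
        stringsAsFactors = FALSE)
      if (p$class == "uhg") {
        # exon(100) [ pad(50) sno pad(50) ]* exon(100)
        off <- exon_unit
        for (k in seq_along(p$sno_len)) {
          s_start <- g_start + off + exon_unit %/% 2L
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene_id = next_sid(), chrom = chroms[ci], start = s_start,
            end = s_start + p$sno_len[k], strand = strands[i],
            gene_class = "snoRNA", transcript_length = p$sno_len[k],
            host_gene_id = id, category = NA_character_,
            stringsAsFactors = FALSE)
          off <- off + p$sno_len[k] + 2L * (exon_unit %/% 2L) + exon_unit
        }
      } else if (p$class == "snorna_in_host") {
        s_start <- g_start + sample.int(p$span - p$sno_len - 200L, 1L) + 100L
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = next_sid(), chrom = chroms[ci], start = s_start,
          end = s_start + p$sno_len, strand = strands[i],
          gene_class = "snoRNA", transcript_length = p$sno_len,
          host_gene_id = id, category = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, gene_rows)

  # --- designate target genes and plant binding sites ---
  n_prom <- round(cfg$frac_promoter * cfg$n_true_sites)
  uhg_ids <- genes$gene_id[genes$gene_class == "uhg"]
  pc_ids <- genes$gene_id[genes$gene_class == "protein_coding"]
  extra_needed <- max(0L, n_prom - length(uhg_ids))
  target_ids <- c(uhg_ids[seq_len(min(n_prom, length(uhg_ids)))],
                  if (extra_needed > 0L) sample(pc_ids, extra_needed))
  half <- cfg$tag_spread %/% 2L
  tss_all <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)

  site_rows <- list()
  for (id in target_ids) {
    gi <- match(id, genes$gene_id)
    ch <- genes$chrom[gi]
    len <- chrom_sizes[[ch]]
    summit <- min(max(half, tss_all[gi] + sample(-20:20, 1L)),
                  len - half - 1L)
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      chrom = ch, start = summit - half, end = summit + half,
      summit = summit, target_gene_id = id, stringsAsFactors = FALSE)
  }
  n_distal <- cfg$n_true_sites - length(target_ids)
  tries <- 0L
  while (n_distal > 0L && tries < 10000L) {
    tries <- tries + 1L
    ci <- sample.int(cfg$n_chroms, 1L)
    ch <- chroms[ci]
    len <- chrom_sizes[[ch]]
    summit <- sample.int(len - 2L * half, 1L) + half
    on_chr <- genes$chrom == ch
    if (any(abs(tss_all[on_chr] - summit) < 1500L)) next
    if (any(genes$start[on_chr] < summit + half &
            genes$end[on_chr] > summit - half)) next
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      chrom = ch, start = summit - half, end = summit + half,
      summit = summit, target_gene_id = NA_character_,
      stringsAsFactors = FALSE)
    n_distal <- n_distal - 1L
  }
  if (n_distal > 0L) stop("could not place distal sites; genome too crowded")
  sites <- do.call(rbind, site_rows)
  sites$ebox <- FALSE
  sites$ebox[sample.int(nrow(sites),
                        round(cfg$frac_ebox * nrow(sites)))] <- TRUE

  sticky_rows <- list()
  n_left <- cfg$n_sticky
  tries <- 0L
  while (n_left > 0L && tries < 10000L) {
    tries <- tries + 1L
    ci <- sample.int(cfg$n_chroms, 1L)
    ch <- chroms[ci]
    len <- chrom_sizes[[ch]]
    summit <- sample.int(len - 2L * half, 1L) + half
    on_ch <- sites$chrom == ch
    if (any(sites$start[on_ch] - 1000L < summit + half &
            sites$end[on_ch] + 1000L > summit - half)) next
    sticky_rows[[length(sticky_rows) + 1L]] <- data.frame(
      chrom = ch, start = summit - half, end = summit + half,
      summit = summit, stringsAsFactors = FALSE)
    n_left <- n_left - 1L
  }
  if (n_left > 0L) stop("could not place sticky regions")
  sticky <- do.call(rbind, sticky_rows)

  # --- knockdown effects: truncated normal, every target repressed ---
  is_target <- genes$gene_id %in% target_ids
  n_t <- sum(is_target)
  u <- stats::runif(n_t, 0, stats::pnorm(cfg$effect_max, cfg$effect_mean,
                                         cfg$effect_sd))
  eff <- numeric(nrow(genes))
  eff[is_target] <- stats::qnorm(u, cfg$effect_mean, cfg$effect_sd)
  is_sno <- genes$gene_class == "snoRNA"
  host_idx <- match(genes$host_gene_id, genes$gene_id)
  eff[is_sno] <- ifelse(is.na(host_idx[is_sno]), 0,
                        eff[host_idx[is_sno]] * cfg$sno_coupling)

  # functional categories for designated targets (background NA)
  ribi <- ribi_translation_categories()
  others <- c("Metabolism", "Transcription, RNA processing",
              "Mitochondrial function", "Other, unknown")
  genes$category[is_target] <- ifelse(
    stats::runif(n_t) < 0.82, sample(ribi, n_t, replace = TRUE),
    sample(others, n_t, replace = TRUE))

  # --- genome sequence with planted E-boxes ---
  genome <- lapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrom_sizes[[ch]], replace = TRUE),
          collapse = "")
  })
  names(genome) <- chroms
  for (i in which(sites$ebox)) {
    ch <- sites$chrom[i]
    s <- sites$summit[i]
    substr(genome[[ch]], s + 1L, s + 6L) <- "CACGTG"
  }
  genome <- Biostrings::DNAStringSet(unlist(genome))

  truth_genes <- data.frame(
    gene_id = genes$gene_id,
    is_direct_target = is_target,
    planted_effect = eff,
    is_snorna = is_sno,
    host_gene_id = genes$host_gene_id,
    stringsAsFactors = FALSE)

  list(annotation = genome_annotation(genes, chrom_sizes),
       genome = genome,
       truth = list(sites = sites, sticky = sticky, genes = truth_genes))
}

#' Simulate the four ChIP tag sets
#'
#' Background tags are uniform over the genome in all four conditions; true
#' binding sites receive `enrichment_fold` times the background rate (over
#' the `tag_spread` window, normally spread around the summit) only in the
#' specific/naive condition; sticky regions receive `sticky_fold` extra
#' tags in all four conditions. Each condition holds exactly
#' `tags_per_condition` tags.
#'
#' @param cfg A `sim_config`.
#' @param truth Truth list from [simulate_genome_annotation()].
#' @return Named list of four `tag_set`s (`specific_naive`,
#'   `specific_depleted`, `igg_naive`, `igg_depleted`).
#' @export
simulate_chip_tags <- function(cfg, truth) {
  with_seed(cfg$seed + 1L, .simulate_chip_tags(cfg, truth))
}

.simulate_chip_tags <- function(cfg, truth) {
  chroms <- paste0("chrS", seq_len(cfg$n_chroms))
  len <- as.integer(cfg$chrom_length)
  genome_len <- cfg$n_chroms * cfg$chrom_length
  bg_rate <- cfg$tags_per_condition / genome_len
  n_site_extra <- as.integer(round(cfg$enrichment_fold * bg_rate *
                                     cfg$tag_spread))
  n_sticky_extra <- as.integer(round(cfg$sticky_fold * bg_rate *
                                       cfg$tag_spread))
  conditions <- c("specific_naive", "specific_depleted", "igg_naive",
                  "igg_depleted")
  draw_region_tags <- function(regions, n_each) {
    if (is.null(regions) || nrow(regions) == 0L || n_each == 0L) {
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character()))
    }
    do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      pos <- as.integer(round(stats::rnorm(n_each, regions$summit[i],
                                           cfg$tag_spread / 4)))
      pos <- pmin(pmax(pos, 0L), len - 1L)
      data.frame(chrom = regions$chrom[i], pos = pos,
                 strand = sample(c("+", "-"), n_each, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list()
  for (cond in conditions) {
    site_tags <- draw_region_tags(
      if (cond == "specific_naive") truth$sites else NULL, n_site_extra)
    sticky_tags <- draw_region_tags(truth$sticky, n_sticky_extra)
    n_bg <- cfg$tags_per_condition - nrow(site_tags) - nrow(sticky_tags)
    if (n_bg < 0L) stop("tags_per_condition too small for planted signal")
    flat <- sample.int(genome_len, n_bg, replace = TRUE) - 1L
    bg <- data.frame(chrom = chroms[flat %/% len + 1L],
                     pos = as.integer(flat %% len),
                     strand = sample(c("+", "-"), n_bg, replace = TRUE),
                     stringsAsFactors = FALSE)
    tags <- rbind(bg, site_tags, sticky_tags)
    tags <- tags[order(tags$chrom, tags$pos), , drop = FALSE]
    out[[cond]] <- tag_set(tags, condition = cond)
  }
  out
}

#' Simulate the replicated knockdown count matrix
#'
#' Per gene, negative-binomial counts around a log-normal base mean; in the
#' knockdown condition the mean of every gene with a planted effect is
#' scaled by `2^effect` (snoRNAs inherit their host's effect scaled by
#' `sno_coupling`, fixed already in the truth); library sizes are jittered
#' by `libsize_jitter`.
#'
#' @param cfg A `sim_config`.
#' @param truth Truth list from [simulate_genome_annotation()].
#' @return A `count_matrix` over all annotated genes, `n_replicates` myc_kd
#'   then ctrl_kd samples.
#' @export
simulate_counts <- function(cfg, truth) {
  with_seed(cfg$seed + 2L, .simulate_counts(cfg, truth))
}

.simulate_counts <- function(cfg, truth) {
  tg <- truth$genes
  n <- nrow(tg)
  affected <- tg$planted_effect != 0
  base <- stats::rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
  base[affected] <- stats::rlnorm(sum(affected), cfg$target_meanlog,
                                  cfg$target_sdlog)
  n_rep <- cfg$n_replicates
  conditions <- rep(c("myc_kd", "ctrl_kd"), each = n_rep)
  lib <- stats::runif(2L * n_rep, 1 - cfg$libsize_jitter,
                      1 + cfg$libsize_jitter)
  counts <- matrix(0L, nrow = n, ncol = 2L * n_rep,
                   dimnames = list(tg$gene_id,
                                   paste0(conditions, "_",
                                          rep(seq_len(n_rep), 2L))))
  for (s in seq_len(2L * n_rep)) {
    mu <- base * lib[s]
    if (conditions[s] == "myc_kd") mu <- mu * 2^tg$planted_effect
    counts[, s] <- stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
  }
  suppressWarnings(count_matrix(counts, conditions))
}

#' Run the full generator
#'
#' @param cfg A `sim_config`.
#' @return List with `annotation`, `genome`, `truth`, `tags` (list of four
#'   `tag_set`s) and `counts` (a `count_matrix`).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  sim <- simulate_genome_annotation(cfg)
  sim$tags <- simulate_chip_tags(cfg, sim$truth)
  sim$counts <- simulate_counts(cfg, sim$truth)
  sim$config <- cfg
  sim
}

#' Write/read the simulator ground truth as JSON
#'
#' @param truth Truth list (`sites`, `sticky`, `genes`).
#' @param path JSON path.
#' @return `write_truth`: `path` invisibly. `read_truth`: the truth list,
#'   round-tripped without loss.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$genes$host_gene_id <- as.character(truth$genes$host_gene_id)
  truth$sites$target_gene_id <- as.character(truth$sites$target_gene_id)
  truth
}

#' Write all simulated artifacts to a directory
#'
#' Emits the genome FASTA, annotation GTF plus host-link TSV, one BED per
#' ChIP condition, the raw count TSV, the truth JSON and the configuration
#' (JSON echo of the `sim_config`).
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_annotation(sim$annotation, file.path(dir, "annotation.gtf"),
                   file.path(dir, "host_links.tsv"))
  for (cond in names(sim$tags)) {
    write_tags(sim$tags[[cond]], file.path(dir, paste0("tags_", cond, ".bed")))
  }
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_truth(sim$truth, file.path(dir, "truth.json"))
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
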