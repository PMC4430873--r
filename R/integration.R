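#' Assign consensus binding sites to genes with expression-aware pruning
#'
#' Candidate genes for each site are the genes whose interval the site
#' overlaps plus the gene(s) with the closest TSS (all ties kept); with
#' `candidates = "overlap"` the closest-TSS genes are omitted. The
#' candidate list is then pruned, in order:
#'
#' 1. intron-hosted snoRNAs are replaced by their host genes
#'    (deduplicated) — the ChIP signal at an intronic snoRNA belongs to the
#'    transcription unit of the host;
#' 2. if at least one candidate is significantly changed upon knockdown
#'    (p < `alpha`), all unchanged candidates are dropped;
#' 3. otherwise, if some unchanged candidate's TSS lies within `near` nt of
#'    the site, unchanged candidates whose TSS is farther than `far` nt are
#'    dropped.
#'
#' The result is deterministic and independent of input order, and pruning
#' never removes a significantly changed candidate.
#'
#' @param sites A `consensus_sites` object or its `sites` data.frame.
#' @param ann A `genome_annotation` (host links resolved).
#' @param diff A `diff_result` data.frame from [differential_test()].
#' @param near,far TSS-distance pruning thresholds in nt (defaults 100 and
#'   300; distances use the same peak-interval definition as
#'   [closest_tss()]).
#' @param alpha Significance threshold on `diff$p_value`.
#' @param candidates `"overlap_closest"` (default) or `"overlap"`.
#' @return Object of class `site_assignment`: list with `assignments`
#'   (data.frame `site_id`, `gene_id`; sites with no candidate contribute
#'   no rows but are listed in `empty_sites`), `empty_sites`, and the
#'   `sites` table carried through.
#' @export
assign_sites_to_genes <- function(sites, ann, diff, near = 100L, far = 300L,
                                  alpha = 0.05,
                                  candidates = c("overlap_closest",
                                                 "overlap")) {
  candidates <- match.arg(candidates)
  st <- if (inherits(sites, "consensus_sites")) sites$sites else sites
  .stopifnot_cols(st, c("site_id", "chrom", "start", "end"), "'sites'")
  g <- ann$genes
  sig_genes <- diff$gene_id[!is.na(diff$p_value) & diff$p_value < alpha]

  # distance of every candidate gene's TSS to the site interval
  tss <- gene_tss(ann)
  site_gene_dist <- function(i, gidx) {
    t <- tss[g$gene_id[gidx]]
    pmax(st$start[i] - t, t - st$end[i], 0L)
  }

  rows <- list()
  empty <- character()
  for (i in seq_len(nrow(st))) {
    on_chr <- which(g$chrom == st$chrom[i])
    ov <- on_chr[g$start[on_chr] < st$end[i] & g$end[on_chr] > st$start[i]]
    cand <- g$gene_id[ov]
    if (candidates == "overlap_closest" && length(on_chr)) {
      d <- site_gene_dist(i, on_chr)
      cand <- union(cand, g$gene_id[on_chr[d == min(d)]])
    }
    if (!length(cand)) {
      empty <- c(empty, st$site_id[i])
      next
    }
    # (1) intronic snoRNA -> host substitution
    host <- g$host_gene_id[match(cand, g$gene_id)]
    cand <- unique(ifelse(is.na(host), cand, host))
    # (2) expression-aware pruning
    is_sig <- cand %in% sig_genes
    if (any(is_sig)) {
      cand <- cand[is_sig]
    } else {
      # (3) proximity pruning among unchanged candidates
      d <- site_gene_dist(i, match(cand, g$gene_id))
      if (any(d <= near) && any(d > far)) cand <- cand[d <= far]
    }
    cand <- sort(cand)
    rows[[length(rows) + 1L]] <- data.frame(site_id = st$site_id[i],
                                            gene_id = cand,
                                            stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), gene_id = character())
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, empty_sites = empty,
                 sites = st),
            class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("site_assignment: %d assignments over %d sites (%d empty)\n",
              nrow(x$assignments), nrow(x$sites), length(x$empty_sites)))
  invisible(x)
}

#' Classify direct Myc targets
#'
#' A gene is *bound* when it is assigned to at least one significant
#' consensus site. The core direct-target call combines binding with the
#' fold-change class: `direct_activated` = bound and downregulated by at
#' least one third upon knockdown; `direct_repressed` = bound and
#' upregulated by at least one third. Bound genes with weaker responses are
#' `bound_only`; unbound but significantly changed genes are `indirect`;
#' the rest are `none`.
#'
#' @param assignment A `site_assignment`.
#' @param diff A `diff_result` data.frame.
#' @param ann Optional `genome_annotation` supplying `category` labels.
#' @param fold_fraction Passed to [classify_regulation()].
#' @return data.frame (`target_calls`): `gene_id`, `bound`, `n_sites`,
#'   `regulation`, `fold_class`, `direct_activated`, `direct_repressed`,
#'   `status`, `category`. Ordered by `gene_id`.
#' @export
classify_direct_targets <- function(assignment, diff, ann = NULL,
                                    fold_fraction = 1/3) {
  sig_sites <- assignment$sites$site_id[assignment$sites$significant]
  asg <- assignment$assignments
  asg_sig <- asg[asg$site_id %in% sig_sites, , drop = FALSE]
  n_sites <- table(asg_sig$gene_id)

  res <- diff[order(diff$gene_id), , drop = FALSE]
  extra <- setdiff(unique(asg_sig$gene_id), res$gene_id)
  if (length(extra)) {
    pad <- data.frame(gene_id = extra, mean_ctrl = NA_real_,
                      mean_kd = NA_real_, log2_ratio = NA_real_,
                      p_value = NA_real_, p_adjusted = NA_real_,
                      regulation = "undetected", stringsAsFactors = FALSE)
    res <- rbind(res[, names(pad)], pad)
    res <- res[order(res$gene_id), , drop = FALSE]
  }
  out <- data.frame(gene_id = res$gene_id, stringsAsFactors = FALSE)
  out$bound <- out$gene_id %in% names(n_sites)
  out$n_sites <- ifelse(out$bound, as.integer(n_sites[out$gene_id]), 0L)
  out$regulation <- res$regulation
  fc <- rep("undetected", nrow(res))
  det <- res$regulation != "undetected"
  if (any(det)) fc[det] <- classify_regulation(res[det, , drop = FALSE],
                                               fold_fraction = fold_fraction)
  out$fold_class <- fc
  out$direct_activated <- out$bound & out$fold_class == "down_by_third"
  out$direct_repressed <- out$bound & out$fold_class == "up_by_third"
  out$status <- ifelse(out$direct_activated, "direct_activated",
                ifelse(out$direct_repressed, "direct_repressed",
                ifelse(out$bound, "bound_only",
                ifelse(out$regulation %in% c("down_significant",
                                             "up_significant"),
                       "indirect", "none"))))
  out$category <- if (!is.null(ann)) {
    ann$genes$category[match(out$gene_id, ann$genes$gene_id)]
  } else NA_character_
  rownames(out) <- NULL
  class(out) <- c("target_calls", "data.frame")
  out
}

#' The functional-category labels making up ribosome biogenesis and
#' translation
#'
#' The named label group over which [tabulate_categories()] computes its
#' subtotal: RNA polymerase I activity, snoRNP function, maturation of the
#' two ribosomal subunits, ribosomal proteins, the mitochondrial ribosome,
#' translation factors and tRNA processing.
#'
#' @return Character vector of ten category labels.
#' @export
ribi_translation_categories <- function() {
  c("RNA Pol I activity",
    "snoRNP function",
    "40S subunit assembly, processing, maturation",
    "60S subunit assembly, processing, maturation",
    "processing of both subunits",
    "40S ribosomal subunit",
    "60S ribosomal subunit",
    "Mitochondrial ribosome",
    "Translation factors",
    "tRNA processing, maturation")
}

#' Tabulate functional categories of directly activated target genes
#'
#' Counts genes per functional-category label, computes the subtotal over a
#' named label group (by default the ten ribosome-biogenesis/translation
#' labels), the total, and the rounded percentage the group represents.
#'
#' @param categories Character vector of per-gene category labels (one
#'   entry per directly activated gene; NA or unknown labels count as
#'   `"Other, unknown"`), or a `target_calls` data.frame, in which case the
#'   `category` column of its `direct_activated` rows is used.
#' @param group Label group for the subtotal.
#' @return List with `counts` (data.frame `category`, `n`), `subtotal`,
#'   `total` and `percent` (= `round(100 * subtotal / total)`; 0 when the
#'   target set is empty).
#' @export
tabulate_categories <- function(categories,
                                group = ribi_translation_categories()) {
  if (is.data.frame(categories)) {
    .stopifnot_cols(categories, c("direct_activated", "category"),
                    "'categories'")
    categories <- categories$category[categories$direct_activated]
  }
  categories <- as.character(categories)
  categories[is.na(categories) | !nzchar(categories)] <- "Other, unknown"
  total <- length(categories)
  if (total == 0L) {
    return(list(counts = data.frame(category = character(), n = integer()),
                subtotal = 0L, total = 0L, percent = 0))
  }
  tab <- table(categories)
  order_ref <- c(group, setdiff(sort(names(tab)), group))
  counts <- data.frame(category = order_ref[order_ref %in% names(tab)],
                       stringsAsFactors = FALSE)
  counts$n <- as.integer(tab[counts$category])
  subtotal <- sum(counts$n[counts$category %in% group])
  list(counts = counts, subtotal = subtotal, total = total,
       percent = round(100 * subtotal / total))
}
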