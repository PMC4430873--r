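# shared fixture: two-gene locus with an intron-hosted snoRNA
integration_ann <- function() {
  tiny_annotation(genes = data.frame(
    gene_id = c("sig", "flat", "host", "sno1", "farflat"),
    chrom = "chr1",
    start = c(1000L, 1100L, 9000L, 9400L, 20000L),
    end = c(2000L, 2100L, 12000L, 9550L, 21000L),
    strand = c("+", "+", "+", "+", "+"),
    gene_class = c("protein_coding", "protein_coding", "uhg", "snoRNA",
                   "protein_coding"),
    transcript_length = c(1000L, 1000L, 400L, 150L, 1000L),
    host_gene_id = c(NA, NA, NA, "host", NA),
    stringsAsFactors = FALSE))
}

mk_diff <- function(ids, p, mean_ctrl = 300, mean_kd = 200) {
  data.frame(gene_id = ids, mean_ctrl = mean_ctrl, mean_kd = mean_kd,
             log2_ratio = log2((mean_kd + 1) / (mean_ctrl + 1)),
             p_value = p, p_adjusted = p,
             regulation = ifelse(is.na(p), "undetected",
                                 ifelse(p < 0.05, "down_significant",
                                        "unchanged")),
             stringsAsFactors = FALSE)
}

mk_sites <- function(df) {
  df$site_id <- sprintf("site_%05d", seq_len(nrow(df)))
  df$significant <- if ("significant" %in% names(df)) df$significant else TRUE
  df
}

test_that("significant candidates displace unaffected ones", {
  ann <- integration_ann()
  sites <- mk_sites(data.frame(chrom = "chr1", start = 1050L, end = 1300L))
  diff <- mk_diff(c("sig", "flat"), p = c(0.01, 0.5))
  asg <- assign_sites_to_genes(sites, ann, diff)
  expect_equal(asg$assignments$gene_id, "sig")
})

test_that("the 100/300-nt proximity rule prunes distant unaffected genes", {
  # all three genes overlap the site; TSS distances to site [1000,1200):
  # anchorA 0 (TSS inside), edgeB exactly 300, farC 400
  ann <- tiny_annotation(genes = data.frame(
    gene_id = c("anchorA", "edgeB", "farC"), chrom = "chr1",
    start = c(1050L, 900L, 900L), end = c(1500L, 1501L, 1601L),
    strand = c("+", "-", "-"),
    gene_class = "protein_coding", transcript_length = 400L,
    stringsAsFactors = FALSE))
  sites <- mk_sites(data.frame(chrom = "chr1", start = 1000L, end = 1200L))
  diff <- mk_diff(c("anchorA", "edgeB", "farC"), p = c(0.5, 0.6, 0.7))
  asg <- assign_sites_to_genes(sites, ann, diff)
  # farC (d = 400 > 300) pruned; edgeB at the inclusive 300 boundary kept
  expect_setequal(asg$assignments$gene_id, c("anchorA", "edgeB"))
  # without an unaffected candidate within 100 nt the rule does not fire
  sites3 <- mk_sites(data.frame(chrom = "chr1", start = 1250L, end = 1300L))
  asg3 <- assign_sites_to_genes(sites3, ann, diff)
  expect_setequal(asg3$assignments$gene_id, c("anchorA", "edgeB", "farC"))
})

test_that("intron-hosted snoRNAs are replaced by their host genes", {
  ann <- integration_ann()
  sites <- mk_sites(data.frame(chrom = "chr1", start = 9420L, end = 9500L))
  diff <- mk_diff(c("host", "sno1"), p = c(0.01, 0.01))
  asg <- assign_sites_to_genes(sites, ann, diff)
  expect_equal(asg$assignments$gene_id, "host")
  # idempotent: re-assigning the produced gene set changes nothing
  expect_false("sno1" %in% asg$assignments$gene_id)
})

test_that("pruning never removes a significantly changed candidate", {
  withr::with_seed(83, {
    for (rep in 1:5) {
      ann <- random_annotation(80, chroms = "chr1")
      st <- sample.int(90000L, 25)
      sites <- mk_sites(data.frame(chrom = "chr1", start = st,
                                   end = st + 400L))
      diff <- mk_diff(ann$genes$gene_id, p = runif(80))
      asg <- assign_sites_to_genes(sites, ann, diff)
      sig <- diff$gene_id[diff$p_value < 0.05]
      # every significant candidate (overlap or closest) must survive
      for (i in seq_len(nrow(sites))) {
        ct <- closest_tss(sites[i, , drop = FALSE], ann)
        g <- ann$genes
        ov <- g$gene_id[g$start < sites$end[i] & g$end > sites$start[i]]
        cand_sig <- intersect(union(ov, ct$gene_id), sig)
        kept <- asg$assignments$gene_id[asg$assignments$site_id ==
                                          sites$site_id[i]]
        expect_true(all(cand_sig %in% kept))
      }
    }
  })
})

test_that("assignment is order-independent", {
  ann <- integration_ann()
  sites <- mk_sites(data.frame(chrom = "chr1",
                               start = c(1050L, 9420L), end = c(1300L, 9500L)))
  diff <- mk_diff(c("sig", "flat", "host", "sno1", "farflat"),
                  p = c(0.01, 0.5, 0.01, 0.01, 0.9))
  a1 <- assign_sites_to_genes(sites, ann, diff)
  perm_genes <- ann$genes[c(3, 5, 1, 4, 2), ]
  ann2 <- genome_annotation(perm_genes, ann$chrom_sizes)
  a2 <- assign_sites_to_genes(sites, ann2, diff[c(4, 2, 5, 1, 3), ])
  norm <- function(a) a$assignments[order(a$assignments$site_id,
                                          a$assignments$gene_id), ]
  expect_equal(norm(a1), norm(a2), ignore_attr = TRUE)
})

test_that("direct-target classes combine binding with the fold rule", {
  ann <- integration_ann()
  sites <- mk_sites(data.frame(chrom = "chr1",
                               start = c(1050L, 20100L),
                               end = c(1300L, 20200L),
                               significant = c(TRUE, FALSE)))
  diff <- mk_diff(c("sig", "flat", "host", "sno1", "farflat"),
                  p = c(0.01, 0.5, 0.01, NA, 0.01),
                  mean_ctrl = c(300, 300, 300, 300, 200),
                  mean_kd = c(150, 290, 270, 300, 300))
  diff$regulation[4] <- "undetected"
  asg <- assign_sites_to_genes(sites, ann, diff)
  tc <- classify_direct_targets(asg, diff)
  row <- function(g) tc[tc$gene_id == g, ]
  expect_true(row("sig")$direct_activated)     # bound + halved
  expect_equal(row("sig")$status, "direct_activated")
  # farflat's only site is non-significant -> not bound, but changed
  expect_false(row("farflat")$bound)
  expect_equal(row("farflat")$status, "indirect")
  expect_equal(row("flat")$status, "none")
  # bound gene with a mild drop stays bound_only
  diff2 <- diff; diff2$mean_kd[1] <- 270
  tc2 <- classify_direct_targets(assign_sites_to_genes(sites, ann, diff2),
                                 diff2)
  expect_equal(tc2[tc2$gene_id == "sig", ]$status, "bound_only")
})

test_that("category tabulation reproduces subtotal, total and percent arithmetic", {
  tab_file <- system.file("extdata", "myc_direct_target_categories.tsv",
                          package = "dmycTargets")
  cat_counts <- read.delim(tab_file, stringsAsFactors = FALSE)
  labels <- rep(cat_counts$category, cat_counts$n_genes)
  res <- tabulate_categories(labels)
  expect_equal(res$total, 139L)
  expect_equal(res$subtotal, 114L)
  expect_equal(res$percent, 82)
  # order invariance
  res2 <- tabulate_categories(sample(labels))
  expect_equal(res2$counts, res$counts)
  # degenerate cases
  expect_equal(tabulate_categories(character())$percent, 0)
  one <- tabulate_categories("snoRNP function")
  expect_equal(one$subtotal, 1L)
  expect_equal(one$percent, 100)
  expect_equal(tabulate_categories("Metabolism")$percent, 0)
  expect_equal(tabulate_categories(NA_character_)$counts$category,
               "Other, unknown")
})
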