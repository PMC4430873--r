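mk_cm <- function(counts, conditions = rep(c("myc_kd", "ctrl_kd"), each = 3)) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  suppressWarnings(count_matrix(counts, conditions))
}

test_that("normalization scales every sample to the target and keeps proportions", {
  counts <- matrix(c(50, 150, 1999800, 10, 90, 999900), nrow = 3,
                   dimnames = list(c("a", "b", "c"), NULL))
  cm <- normalize_counts(mk_cm(counts, c("myc_kd", "ctrl_kd")))
  expect_equal(cm$normalized["a", 1], 25)   # column sum 2e6 -> factor 1/2
  expect_equal(cm$normalized[, 2], counts[, 2], ignore_attr = TRUE)
  withr::with_seed(5, {
    m <- matrix(rpois(600, 80), nrow = 100)
    cm2 <- normalize_counts(mk_cm(m))
    expect_equal(unname(colSums(cm2$normalized)), rep(1e6, 6),
                 tolerance = 1e-9)
    # within-sample proportions preserved
    expect_equal(cm2$normalized[1, ] / cm2$normalized[2, ],
                 m[1, ] / m[2, ], ignore_attr = TRUE)
  })
  zero <- mk_cm(matrix(0, 2, 6))
  expect_error(normalize_counts(zero), "zero total")
})

test_that("detection filter applies both thresholds inclusively", {
  counts <- cbind(c(9L, 10L, 1000L, 1000L), matrix(1L, 4, 5))
  counts[, 1] <- counts[, 1] - 5L   # totals exactly 9, 10, 1000, 1000
  rownames(counts) <- c("lowreads", "justreads", "shortlen", "ok")
  cm <- mk_cm(counts)
  ann <- tiny_annotation(genes = data.frame(
    gene_id = rownames(counts), chrom = "chr1",
    start = c(0L, 1000L, 2000L, 3000L) + 1L,
    end = c(900L, 1900L, 2900L, 3900L),
    strand = "+", gene_class = "other",
    transcript_length = c(500L, 500L, 124L, 125L),
    stringsAsFactors = FALSE))
  det <- filter_detected(cm, ann)
  expect_setequal(det, c("justreads", "ok"))
  # monotone in both thresholds
  expect_true(all(filter_detected(cm, ann, min_reads = 20) %in% det))
  expect_true(all(filter_detected(cm, ann, min_length = 200) %in% det))
  cm2 <- mk_cm(matrix(5, 1, 6, dimnames = list("mystery", NULL)))
  expect_error(filter_detected(cm2, ann), "mystery")
})

test_that("differential test handles identical replicates and planted effects", {
  flat <- mk_cm(matrix(100, 3, 6, dimnames = list(c("a", "b", "c"), NULL)))
  flat <- normalize_counts(flat)
  dr <- differential_test(flat, detected = c("a", "b"))
  expect_equal(dr$log2_ratio[1:2], c(0, 0))
  expect_equal(dr$p_value[1:2], c(1, 1))
  expect_equal(dr$regulation, c("unchanged", "unchanged", "undetected"))
  expect_true(is.na(dr$p_value[3]))

  withr::with_seed(17, {
    # 50 of 300 genes planted at 2-fold knockdown, moderate dispersion;
    # the affected minority keeps fixed-total normalization composition-safe
    n <- 300
    mu_kd <- rep(400, n); mu_kd[1:50] <- 200
    counts <- cbind(
      matrix(rnbinom(3 * n, mu = mu_kd, size = 50), n, byrow = FALSE),
      matrix(rnbinom(3 * n, mu = 400, size = 50), n))
    cm <- normalize_counts(mk_cm(counts))
    dr2 <- differential_test(cm, rownames(cm$counts))
    expect_lt(abs(mean(dr2$log2_ratio[1:50]) + 1), 0.2)
    expect_gt(mean(dr2$regulation[1:50] == "down_significant"), 0.9)
    expect_lt(mean(dr2$regulation[51:300] != "unchanged"), 0.2)
  })
})

test_that("type-I error of the differential test is near nominal under the null", {
  withr::with_seed(29, {
    n <- 2000
    counts <- matrix(rnbinom(6 * n, mu = 300, size = 100), n)
    rownames(counts) <- sprintf("g%04d", seq_len(n))
    cm <- normalize_counts(mk_cm(counts))
    dr <- differential_test(cm, rownames(counts))
    rate <- mean(dr$p_value < 0.05)
    se <- sqrt(0.05 * 0.95 / n)
    expect_lt(abs(rate - 0.05), 3 * se)
  })
})

test_that("fold classes honour the inclusive one-third boundary and label symmetry", {
  dr <- data.frame(mean_ctrl = c(300, 300, 200, 0, 0),
                   mean_kd = c(200, 201, 300, 0, 10))
  cls <- classify_regulation(dr)
  expect_equal(cls, c("down_by_third", "unchanged", "up_by_third",
                      "unchanged", "up_by_third"))
  # swapping condition labels maps the classes onto each other exactly
  withr::with_seed(37, {
    rnd <- data.frame(mean_ctrl = runif(500, 0, 1000),
                      mean_kd = runif(500, 0, 1000))
    fwd <- classify_regulation(rnd)
    rev <- classify_regulation(data.frame(mean_ctrl = rnd$mean_kd,
                                          mean_kd = rnd$mean_ctrl))
    map <- c(down_by_third = "up_by_third", up_by_third = "down_by_third",
             unchanged = "unchanged")
    expect_equal(unname(map[fwd]), rev)
  })
})

test_that("delta-delta-Ct quantification anchors the calibrator at 100%", {
  ct <- expand.grid(gene_id = c("target", "ref1", "ref2"),
                    sample_id = c("c1", "c2", "k1", "k2"),
                    stringsAsFactors = FALSE)
  ct$condition <- ifelse(grepl("^c", ct$sample_id), "ctrl", "kd")
  ct$ct <- 20
  ct$ct[ct$gene_id == "ref2"] <- 22
  # references unchanged; target one cycle later in kd -> 50%
  ct$ct[ct$gene_id == "target" & ct$condition == "kd"] <- 21
  res <- ddct_relative_expression(ct, c("ref1", "ref2"), "ctrl")
  expect_equal(res$percent_expression[res$condition == "ctrl"], 100)
  expect_equal(res$percent_expression[res$condition == "kd"], 50)

  # equal shift of target and references cancels out
  ct2 <- ct
  ct2$ct[ct2$condition == "kd"] <- ct2$ct[ct2$condition == "kd"] + 3
  ct2$ct[ct2$gene_id == "target" & ct2$condition == "kd"] <- 23
  res2 <- ddct_relative_expression(ct2, c("ref1", "ref2"), "ctrl")
  expect_equal(res2$percent_expression, c(100, 100))

  # a third reference equal to the mean of the others changes nothing
  ref3 <- ct[ct$gene_id == "ref1", ]
  ref3$gene_id <- "ref3"
  ref3$ct <- 21  # mean of ref1 (20) and ref2 (22)
  ct3 <- rbind(ct, ref3)
  res3 <- ddct_relative_expression(ct3, c("ref1", "ref2", "ref3"), "ctrl")
  expect_equal(res3[res3$gene_id == "target", "percent_expression"],
               res[res$gene_id == "target", "percent_expression"])

  expect_error(ddct_relative_expression(ct[-1, ], c("ref1", "ref2"), "ctrl"),
               "missing Ct")
})
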