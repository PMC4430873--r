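mk_peaks <- function(df, id = "e1", condition = "specific_naive") {
  if (!"summit" %in% names(df)) df$summit <- df$start + 1L
  if (!"score" %in% names(df)) df$score <- 1
  if (!"fdr_percent" %in% names(df)) df$fdr_percent <- 1
  peak_set(df, experiment_id = id, condition = condition)
}

test_that("control overlap and excluded chromosomes remove peaks", {
  myc <- mk_peaks(data.frame(chrom = c("chr1", "chr1", "chrU"),
                             start = c(100L, 500L, 10L),
                             end = c(200L, 600L, 90L)))
  igg <- mk_peaks(data.frame(chrom = "chr1", start = 150L, end = 250L),
                  id = "igg", condition = "igg_naive")
  out <- filter_specific_peaks(myc, list(igg))
  expect_equal(out$start, c(500L, 10L))
  out2 <- filter_specific_peaks(myc, list(igg), excluded_chroms = "chrU")
  expect_equal(out2$start, 500L)
  # idempotent and, with empty controls, only the chromosome rule applies
  expect_equal(as.data.frame(filter_specific_peaks(out2, list(igg),
                                                   excluded_chroms = "chrU")),
               as.data.frame(out2))
  expect_equal(nrow(filter_specific_peaks(myc, list())), 3L)
})

test_that("specificity filter matches the all-pairs oracle on random sets", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      myc <- random_peaks(200)
      ctrl <- list(random_peaks(80, experiment_id = "c1",
                                condition = "igg_naive"),
                   random_peaks(60, experiment_id = "c2",
                                condition = "specific_depleted"))
      got <- filter_specific_peaks(myc, ctrl)
      want <- bf_filter(myc, ctrl)
      expect_equal(got$start, myc$start[want])
      expect_equal(got$chrom, myc$chrom[want])
    }
  })
})

test_that("consensus sites implement the FDR rescue rule", {
  a <- mk_peaks(data.frame(chrom = "chr1", start = 100L, end = 300L,
                           summit = 200L, score = 5, fdr_percent = 5),
                id = "mouse")
  b <- mk_peaks(data.frame(chrom = "chr1", start = 250L, end = 450L,
                           summit = 350L, score = 9, fdr_percent = 20),
                id = "rabbit")
  lone <- mk_peaks(data.frame(chrom = "chr2", start = 10L, end = 60L,
                              summit = 30L, score = 2, fdr_percent = 20),
                   id = "mouse")
  cons <- build_consensus_sites(list(a, b, lone))
  expect_equal(nrow(cons$sites), 2L)
  rescued <- cons$sites[cons$sites$chrom == "chr1", ]
  expect_true(rescued$significant)       # FDR 20% member rescued by 5% member
  expect_equal(rescued$n_members, 2L)
  expect_equal(rescued$start, 100L)
  expect_equal(rescued$end, 450L)
  expect_equal(rescued$representative_summit, 200L)  # min-FDR member
  expect_false(cons$sites$significant[cons$sites$chrom == "chr2"])
})

test_that("overlap chains merge by single linkage", {
  a <- mk_peaks(data.frame(chrom = "chr1", start = 0L, end = 100L), id = "A")
  b <- mk_peaks(data.frame(chrom = "chr1", start = 90L, end = 200L), id = "B")
  c3 <- mk_peaks(data.frame(chrom = "chr1", start = 190L, end = 300L), id = "C")
  cons <- build_consensus_sites(list(a, b, c3))
  expect_equal(nrow(cons$sites), 1L)     # A-B and B-C overlap; A-C do not
  expect_equal(cons$sites$n_members, 3L)
  # book-ended intervals (zero shared bases) must NOT merge
  d <- mk_peaks(data.frame(chrom = "chr1", start = 0L, end = 100L), id = "A")
  e <- mk_peaks(data.frame(chrom = "chr1", start = 100L, end = 200L), id = "B")
  expect_equal(nrow(build_consensus_sites(list(d, e))$sites), 2L)
})

test_that("consensus clustering matches the brute-force partition and covers all peaks", {
  withr::with_seed(31, {
    for (rep in 1:8) {
      sets <- list(random_peaks(60, experiment_id = "A"),
                   random_peaks(60, experiment_id = "B"),
                   random_peaks(60, experiment_id = "C"))
      cons <- build_consensus_sites(sets)
      pooled <- cons$members
      # every peak in exactly one site
      expect_equal(nrow(pooled), 180L)
      expect_false(anyNA(pooled$site_id))
      got <- unname(lapply(split(seq_len(nrow(pooled)), pooled$site_id),
                           sort))
      want <- bf_consensus_partition(pooled)
      key <- function(p) sort(vapply(p, paste, character(1), collapse = ","))
      expect_equal(key(got), key(want))
      # site intervals span their members
      for (k in seq_len(nrow(cons$sites))) {
        m <- pooled[pooled$site_id == cons$sites$site_id[k], ]
        expect_equal(cons$sites$start[k], min(m$start))
        expect_equal(cons$sites$end[k], max(m$end))
        expect_equal(cons$sites$significant[k], min(m$fdr_percent) < 10)
      }
    }
  })
})

test_that("Venn cells reflect exact experiment membership and sum to the site count", {
  a <- mk_peaks(data.frame(chrom = "chr1", start = 0L, end = 100L), id = "A")
  b <- mk_peaks(data.frame(chrom = "chr1", start = 500L, end = 600L), id = "B")
  oc <- overlap_counts(list(a, b))
  expect_equal(unname(oc[c("A", "B", "A&B")]), c(1L, 1L, 0L))
  same <- mk_peaks(data.frame(chrom = "chr1", start = 0L, end = 100L), id = "B")
  oc2 <- overlap_counts(list(a, same))
  expect_equal(unname(oc2[c("A", "B", "A&B")]), c(0L, 0L, 1L))
  withr::with_seed(41, {
    sets <- list(random_peaks(100, experiment_id = "A"),
                 random_peaks(100, experiment_id = "B"),
                 random_peaks(100, experiment_id = "C"))
    oc3 <- overlap_counts(sets)
    expect_equal(sum(oc3), nrow(build_consensus_sites(sets)$sites))
  })
  expect_error(overlap_counts(list(a)), "2 or 3")
})

test_that("TSS-distance bins, cumulative shares and bin closure behave", {
  ann <- tiny_annotation(genes = data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(1000L, 20000L), end = c(2000L, 21000L), strand = "+",
    gene_class = "other", transcript_length = 500L,
    stringsAsFactors = FALSE))
  sites <- data.frame(chrom = "chr1",
                      start = c(990L, 14450L), end = c(1100L, 14500L))
  prof <- tss_distance_profile(sites, ann)
  expect_equal(prof$bins$pct_all[prof$bins$bin == "[0,100)"], 50)
  expect_equal(prof$bins$pct_all[prof$bins$bin == "[5000,6000)"], 50)
  expect_equal(sum(prof$bins$pct_all), 100, tolerance = 1e-9)
  expect_equal(prof$cumulative$within_100_all, 50)
  withr::with_seed(51, {
    ann2 <- random_annotation(100)
    st <- sample.int(90000L, 60)
    sites2 <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                         start = st, end = st + 200L)
    prof2 <- tss_distance_profile(sites2, ann2,
                                  ebox = runif(60) < 0.5)
    expect_equal(sum(prof2$bins$pct_all), 100, tolerance = 1e-9)
    expect_equal(sum(prof2$bins$pct_ebox), 100, tolerance = 1e-9)
  })
})

test_that("E-box scan honours the 100-nt summit window boundaries", {
  base <- paste(rep("A", 400), collapse = "")
  put <- function(pos0) {  # plant CACGTG with 0-based start pos0
    s <- base
    substr(s, pos0 + 1, pos0 + 6) <- "CACGTG"
    Biostrings::DNAStringSet(c(chr1 = s))
  }
  site <- data.frame(chrom = "chr1", summit = 200L)
  expect_true(scan_ebox(site, put(200L)))       # at the summit
  expect_true(scan_ebox(site, put(249L)))       # last start inside window
  expect_false(scan_ebox(site, put(250L)))      # first start outside
  expect_true(scan_ebox(site, put(150L)))       # left edge inside
  expect_false(scan_ebox(site, put(149L)))
  expect_error(scan_ebox(data.frame(chrom = "chr1", summit = 500L),
                         put(200L)), "outside")
})

test_that("E-box scan equals 6-mer enumeration and is reverse-complement invariant", {
  withr::with_seed(61, {
    for (rep in 1:4) {
      s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
      genome <- Biostrings::DNAStringSet(c(chr1 = s))
      summits <- sample(100:9900, 50)
      sites <- data.frame(chrom = "chr1", summit = summits)
      got <- scan_ebox(sites, genome)
      want <- vapply(summits, function(x) bf_ebox(s, x), logical(1))
      expect_equal(got, want)
      # palindromic motif: reverse-complementing the genome mirrors hits
      # (a 6-mer starting at s maps to start L - 6 - s, so the mirrored
      # summit is L - summit - 5 for the start-in-window rule to align)
      rc <- Biostrings::reverseComplement(genome)
      names(rc) <- "chr1"
      sites_rc <- data.frame(chrom = "chr1", summit = 10000L - summits - 5L)
      expect_equal(scan_ebox(sites_rc, rc), got)
    }
  })
})

test_that("region read ratios use half-open membership and the denominator guard", {
  naive <- tag_set(data.frame(chrom = "chr1",
                              pos = c(rep(150L, 120), rep(900L, 5)),
                              strand = "+"), condition = "specific_naive")
  depl <- tag_set(data.frame(chrom = "chr1", pos = rep(160L, 100),
                             strand = "+"), condition = "specific_depleted")
  regions <- data.frame(chrom = "chr1", start = c(100L, 880L),
                        end = c(200L, 950L))
  rr <- region_read_ratio(regions, naive, depl)
  expect_equal(rr$ratio[1], 1.2)         # 120 / 100
  expect_equal(rr$n_depleted[2], 0L)
  expect_equal(rr$ratio[2], 5)           # guard: 5 / max(0, 1)
  withr::with_seed(71, {
    tags1 <- tag_set(data.frame(chrom = sample(c("chr1", "chr2"), 3000, TRUE),
                                pos = sample.int(50000L, 3000, TRUE),
                                strand = "+"), condition = "specific_naive")
    tags2 <- tag_set(data.frame(chrom = sample(c("chr1", "chr2"), 3000, TRUE),
                                pos = sample.int(50000L, 3000, TRUE),
                                strand = "+"), condition = "specific_depleted")
    st <- sample.int(49000L, 40)
    reg <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                      start = st, end = st + sample(100:800, 40, TRUE))
    rr2 <- region_read_ratio(reg, tags1, tags2)
    expect_equal(rr2$n_naive, bf_region_counts(reg, tags1))
    expect_equal(rr2$n_depleted, bf_region_counts(reg, tags2))
  })
})

test_that("validation-region selection enforces the ratio boundary and the stride", {
  n <- 120
  regions <- data.frame(chrom = "chr1",
                        start = seq(0L, by = 1000L, length.out = n))
  regions$end <- regions$start + 500L
  regions$n_naive <- rev(seq_len(n)) * 10L
  regions$n_depleted <- 10L
  regions$ratio <- 1.0
  regions$ratio[1] <- 1.21    # excluded: just above the threshold
  regions$ratio[2] <- 1.20    # retained: boundary inclusive
  own <- data.frame(chrom = "chr1", start = 2000L, end = 2600L)  # hits row 3
  sel <- select_validation_regions(regions, own)
  retained_n <- n - 2  # one ratio exclusion, one own-site overlap
  expect_equal(nrow(sel), ceiling(retained_n / 50))
  expect_equal(sel$rank, c(1L, 51L, 101L))
  # top-ranked region is the highest-count retained one
  expect_equal(sel$n_naive[1], max(regions$n_naive[regions$ratio <= 1.2][-2]))
})
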