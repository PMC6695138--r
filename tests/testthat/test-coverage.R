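# Depth-of-coverage summaries: parsing contracts, hand-computed summaries,
# binning, pooling, and the brute-force recount oracle.

test_that("depth tables parse and enforce their contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\ttotal_depth",
               "chr1\t1\t10", "chr1\t2\t20", "chr1\t3\t30"), f)
  d <- read_depth_table(f)
  expect_equal(nrow(d), 3L)
  expect_equal(d$total_depth, c(10L, 20L, 30L))

  writeLines(c("chrom\tpos\ttotal_depth",
               "chr1\t1\t10", "chr1\t1\t20"), f)
  expect_error(read_depth_table(f), "duplicated locus",
               class = "panelval_data_error")

  writeLines(c("chrom\tpos\ttotal_depth",
               "chr1\t1\t10", "chr1\t2\t12.5"), f)
  expect_error(read_depth_table(f), "line 3",
               class = "panelval_parse_error")
})

test_that("region summaries match hand-computed values", {
  r <- target_regions("G1", "chr1", 0L, 100L)
  d <- depth_table_from(rep(250L, 100))
  s <- summarize_region(r, d)
  expect_equal(s$mean_depth, 250)
  expect_equal(s$pct_ge_250, 100)
  expect_equal(s$pct_ge_500, 0)

  r5 <- target_regions("G1", "chr1", 0L, 5L, exon_start = 1L, exon_end = 4L)
  d5 <- depth_table_from(c(0L, 10L, 20L, 50L, 100L))
  s5 <- summarize_region(r5, d5)
  expect_equal(s5$mean_depth, 36)
  expect_equal(unlist(s5[paste0("pct_ge_", c(1, 10, 20, 50, 100))]),
               c(pct_ge_1 = 80, pct_ge_10 = 80, pct_ge_20 = 60,
                 pct_ge_50 = 40, pct_ge_100 = 20))

  # bases absent from the table count as uncovered
  d3 <- depth_table_from(c(10L, 10L))
  s3 <- summarize_region(target_regions("G1", "chr1", 0L, 4L), d3)
  expect_equal(s3$mean_depth, 5)
  expect_equal(s3$pct_ge_1, 50)

  expect_error(summarize_region(r[0, ], d), class = "panelval_config_error")
})

test_that("threshold fractions are non-increasing in the threshold", {
  set.seed(5)
  for (i in 1:20) {
    len <- sample(10:60, 1)
    d <- depth_table_from(rpois(len, lambda = sample(c(2, 50, 400), 1)))
    s <- summarize_region(target_regions("G", "chr1", 0L, len), d)
    pct <- unlist(s[paste0("pct_ge_", coverage_thresholds())])
    expect_true(all(diff(pct) <= 1e-12))
    expect_true(s$q1 <= s$median && s$median <= s$q3)
  }
})

test_that("summaries agree with a brute-force per-base recount", {
  set.seed(9)
  for (i in 1:10) {
    len <- sample(5:50, 1)
    start <- sample(0:100, 1)
    depths <- rpois(len, 120)
    d <- depth_table_from(depths, start_pos = start + 1L)
    # punch holes: drop some loci entirely
    d <- d[runif(len) > 0.2, , drop = FALSE]
    attr(d, "samples") <- character()
    r <- target_regions("G", "chr1", start, start + len)
    s <- summarize_region(r, d)
    b <- brute_region_summary(r, d, coverage_thresholds())
    expect_equal(s$mean_depth, b$mean)
    expect_equal(unname(unlist(s[paste0("pct_ge_", coverage_thresholds())])),
                 unname(b$pct))
  }
})

test_that("regions land in the expected depth bins", {
  mk <- function(mean_depth) {
    len <- 10L
    d <- depth_table_from(rep(as.integer(mean_depth), len))
    summarize_region(target_regions("G", "chr1", 0L, len), d)
  }
  s <- rbind(mk(1502), mk(68), mk(82), mk(100), mk(1499))
  bins <- bin_regions(s)
  expect_equal(sum(bins$n_regions), 5L)
  expect_equal(bins$n_regions[bins$bin == "<100"], 2L)
  expect_equal(bins$n_regions[bins$bin == ">1500"], 1L)
  expect_equal(bins$n_regions[bins$bin == "100-199"], 1L)
  expect_equal(bins$n_regions[bins$bin == "1400-1499"], 1L)
  expect_error(bin_regions(s[0, ]), class = "panelval_config_error")
})

test_that("panel pooling is the per-base multiset, not a mean of means", {
  t2 <- target_regions(c("G1", "G2"), "chr1", c(0L, 100L), c(100L, 200L))
  d <- depth_table_from(c(rep(100L, 100), rep(300L, 100)))
  p <- panel_summary(t2, d)
  expect_equal(p$mean_depth, 200)
  expect_equal(p$pct_ge_250, 50)
  expect_equal(p$pct_ge_100, 100)

  # single region: panel summary is that region's summary
  t1 <- target_regions("G1", "chr1", 0L, 100L)
  s1 <- summarize_region(t1, d)
  p1 <- panel_summary(t1, d)
  expect_equal(p1$mean_depth, s1$mean_depth)
  expect_equal(p1$q3, s1$q3)

  # all-zero panel
  dz <- depth_table_from(rep(0L, 200))
  pz <- panel_summary(t2, dz)
  expect_true(all(unlist(pz[paste0("pct_ge_", coverage_thresholds())]) == 0))
})

test_that("pooled panel mean equals the length-weighted mean of region means", {
  set.seed(21)
  lens <- sample(10:40, 5)
  starts <- cumsum(c(0L, head(lens, -1) + 10L))
  tg <- target_regions(paste0("G", 1:5), "chr1", starts, starts + lens)
  d <- depth_table_from(rpois(max(starts + lens), 300))
  s <- summarize_regions(tg, d)
  p <- panel_summary(tg, d)
  expect_equal(p$mean_depth, weighted.mean(s$mean_depth, s$length))
})

test_that("synthetic region binning covers all regions with sensible gradients", {
  b <- simulate_panel(small_sim_config(seed = 5L))
  s <- summarize_regions(b$targets, b$depth)
  bins <- bin_regions(s)
  expect_equal(sum(bins$n_regions), nrow(b$targets))
})
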