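# Concordance: labeling against Sanger truth, FN/TN derivation from
# clinical screening, metric identities, and class summaries.

test_that("calls are labeled TP/FP by Sanger outcome, unresolved otherwise", {
  fx <- fixture()
  labeled <- label_calls(fx$calls, fx$sanger)
  expect_equal(sum(labeled$label == "TP"), 61L)
  expect_equal(sum(labeled$label == "FP"), 13L)
  key <- labeled$dna_change == "c.5611_5615delAGTAA"
  expect_equal(labeled$label[key], "TP")
  pten <- labeled[labeled$dna_change == "c.802-2A>T", ]
  expect_equal(nrow(pten), 4L)
  expect_true(all(pten$label == "FP"))

  orphan <- make_calls(1, chrom = "chrX", pos = 1L)
  expect_message(l2 <- label_calls(rbind2_calls(fx$calls, orphan), fx$sanger),
                 "unresolved")
  expect_equal(sum(l2$label == "unresolved"), 1L)

  bad <- fx$sanger[c(1, 1), ]
  bad$outcome[2] <- "not_confirmed"
  expect_error(label_calls(fx$calls, bad), "contradictory",
               class = "panelval_data_error")

  expect_equal(nrow(label_calls(fx$calls[0, ], fx$sanger)), 0L)
})

test_that("indel aliases match through key normalization", {
  # the same deletion in ANNOVAR style and VCF anchored style
  k1 <- variant_key("chr13", 32339966, "AGTAA", "-")
  k2 <- variant_key("chr13", 32339965, "AAGTAA", "A")
  expect_equal(k1, k2)
  expect_equal(variant_key("chr1", 100, "A", "G"), "chr1:100:A:G")
})

test_that("false negatives are clinically known variants the panel missed", {
  fx <- fixture()
  fn <- derive_fn(fx$clinical, fx$calls)
  expect_equal(fn$fn[fn$gene == "BRCA1"], 0L)
  expect_equal(fn$fn[fn$gene == "BRCA2"], 0L)

  # remove the known pathogenic deletion from the call set: one FN appears
  dropped <- fx$calls[fx$calls$dna_change != "c.5611_5615delAGTAA", ]
  fn2 <- derive_fn(fx$clinical, dropped)
  expect_equal(fn2$fn[fn2$gene == "BRCA2"], 1L)

  expect_equal(nrow(derive_fn(fx$clinical[0, ], fx$calls)), 0L)
})

test_that("true negatives need a negative full screen and no pathogenic call", {
  fx <- fixture()
  tn <- derive_tn(fx$clinical, fx$calls)
  # six negative-screened samples; their VUS/benign calls do not break TN
  expect_equal(tn$tn[tn$gene == "BRCA1"], 6L)
  expect_equal(tn$tn[tn$gene == "BRCA2"], 6L)

  # a targeted (single-variant) negative never becomes a TN
  cl <- fx$clinical
  cl <- rbind(cl, data.frame(sample = "1CAD-f", gene = "BRCA1",
                             scope = "targeted",
                             outcome = "negative_full_screen",
                             chrom = ".", pos = ".", ref = ".", alt = "."))
  expect_equal(derive_tn(cl, fx$calls)$tn, tn$tn)

  # a pathogenic call in a screened-negative sample removes that TN
  calls2 <- fx$calls
  calls2$clinvar[calls2$sample == "1EA-a" & calls2$gene == "BRCA1"][1] <- "Pathogenic"
  tn2 <- derive_tn(fx$clinical, calls2)
  expect_equal(tn2$tn[tn2$gene == "BRCA1"], 5L)
})

test_that("per-gene metrics reproduce the validation table", {
  res <- fixture_result()
  m <- res$metrics
  row <- function(g) m[m$gene == g, ]
  expect_equal(row("BRCA1")$tp, 11L)
  expect_equal(row("BRCA1")$fp, 1L)
  expect_equal(row("BRCA1")$fdr_all, 1 / 12, tolerance = 1e-12)
  expect_equal(row("BRCA1")$fdr_filtered, 0)
  expect_equal(row("PTEN")$fdr_all, 11 / 12, tolerance = 1e-12)
  expect_equal(row("PTEN")$fdr_filtered, 11 / 12, tolerance = 1e-12)
  expect_equal(row("CDH1")$fdr_all, 0.25)
  expect_equal(row("CDH1")$fdr_filtered, 0)
  zero <- c("ATM", "BRCA2", "CHEK2", "NBN", "PALB2", "STK11", "TP53")
  expect_true(all(m$fdr_all[m$gene %in% zero] == 0))
  # genes without clinical truth have undefined sensitivity/specificity
  expect_true(is.na(row("PTEN")$sensitivity))
  # conservation: TP + FP across genes equals resolved calls
  expect_equal(sum(m$tp[m$gene != "pooled"]) + sum(m$fp[m$gene != "pooled"]), 74L)
  # the filtered mode can only shrink the FDR when excluded calls are FPs
  expect_true(all(m$fdr_filtered <= m$fdr_all + 1e-12, na.rm = TRUE))
})

test_that("undefined denominators give NA, and empty genes all-NA metrics", {
  labeled <- make_calls(0)
  labeled$label <- character(0)
  fn <- data.frame(gene = "G9", fn = 0L)
  tn <- data.frame(gene = "G9", tn = 0L)
  m <- concordance_metrics(labeled, fn, tn)
  g9 <- m[m$gene == "G9", ]
  expect_true(is.na(g9$sensitivity) && is.na(g9$specificity) &&
                is.na(g9$fdr_all))
})

test_that("class summaries are exact recounts of the labeled table", {
  res <- fixture_result()
  cs <- res$class_summaries
  calls <- res$calls
  pick <- function(cl) cs[cs$class == cl, ]
  # brute-force recount of the TP class
  tp <- calls[calls$label == "TP", ]
  expect_equal(pick("TP")$n, nrow(tp))
  expect_equal(pick("TP")$mean_dp, mean(tp$dp))
  expect_equal(pick("TP")$mean_ab, mean(tp$ab))
  # single-call classes degrade gracefully
  one <- calls[5, ]
  cs1 <- class_summaries(one, triage_thresholds())
  got <- cs1[cs1$class == "TP", ]
  expect_equal(got$mean_dp, one$dp)
  expect_equal(got$min_ab, got$max_ab)
  # empty class rows carry NA
  fps <- class_summaries(tp, triage_thresholds())
  expect_true(is.na(fps$mean_dp[fps$class == "FP"]))
})
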