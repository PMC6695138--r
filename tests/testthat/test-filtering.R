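# Filtering cascade: MAF annotation, rarity and positional predicates,
# and the algebraic properties (idempotence, order independence).

test_that("MAF annotation joins by variant key and flags conflicts", {
  fx <- fixture()
  calls <- annotate_maf(fx$calls, fx$maf)
  atm <- calls[calls$dna_change == "c.146C>G", ]
  expect_equal(atm$maf_EA, 0.0136)
  expect_equal(atm$maf_AA, 0.0027)

  novel <- make_calls(1, chrom = "chr9", pos = 1L)
  novel <- annotate_maf(novel, fx$maf)
  expect_true(is.na(novel$maf_EA) && is.na(novel$maf_AA))

  dup <- fx$maf[c(1, 1), ]
  dup$EA[2] <- 0.3  # same key, different value
  dup$EA[1] <- 0.1
  attr(dup, "groups") <- c("EA", "AA")
  expect_error(annotate_maf(fx$calls, dup), "conflicting",
               class = "panelval_data_error")
})

test_that("the rarity filter keeps a call only if rare in every group", {
  calls <- make_calls(4)
  calls$maf_EA <- c(0.0136, 0.021, 0.02, NA)
  calls$maf_AA <- c(0.0027, 0.001, NA, NA)
  kept <- filter_rare(calls, cutoff = 0.02)
  # 2% boundary is inclusive; absent MAF counts as rare
  expect_equal(kept$sample, c("S1", "S3", "S4"))
})

test_that("the positional filter keeps coding and near-boundary intronic calls", {
  calls <- make_calls(5)
  calls$func <- c("nonsynonymous", "synonymous", "intronic", "intronic", "other")
  calls$boundary_dist <- c(NA, NA, 7L, 12L, NA)
  kept <- filter_positional(calls, window = 10)
  expect_equal(kept$sample, c("S1", "S2", "S3"))

  # distance parsed from the cDNA annotation when no explicit column
  calls2 <- make_calls(2)
  calls2$func <- "intronic"
  calls2$boundary_dist <- NULL
  calls2$dna_change <- c("c.186-7C>T", "c.4000+11G>A")
  kept2 <- filter_positional(calls2, window = 10)
  expect_equal(kept2$dna_change, "c.186-7C>T")

  # distance computed from the exon model as a fallback
  tg <- tiny_targets()  # region chr1:[100,200), exon core [110,190)
  calls3 <- make_calls(2, chrom = "chr1")
  calls3$func <- "intronic"
  calls3$boundary_dist <- NA_integer_
  calls3$pos <- c(105L, 199L)   # 6 bp before the core, 9 bp after
  expect_equal(boundary_distance(calls3$pos, calls3$chrom, tg), c(6L, 9L))
  kept3 <- filter_positional(calls3, targets = tg, window = 8)
  expect_equal(kept3$pos, 105L)

  # unlocatable intronic calls are dropped with a warning
  calls4 <- make_calls(1)
  calls4$func <- "intronic"
  calls4$boundary_dist <- NA_integer_
  expect_warning(out <- filter_positional(calls4), "no locatable boundary")
  expect_equal(nrow(out), 0L)
})

test_that("gene restriction behaves as a plain subset", {
  fx <- fixture()
  expect_equal(nrow(restrict_genes(fx$calls, character())), 0L)
  expect_identical(restrict_genes(fx$calls, unique(fx$calls$gene)), fx$calls)
  expect_equal(nrow(restrict_genes(fx$calls, c("BRCA1", "BRCA2"))), 26L)
})

test_that("the full cascade retains all 74 fixture calls", {
  fx <- fixture()
  out <- filter_calls(fx$calls, maf = fx$maf, genes = unique(fx$calls$gene))
  expect_equal(nrow(out$calls), 74L)
  expect_equal(out$audit$n_dropped, c(0L, 0L, 0L))
})

test_that("filters are conjunctive: idempotent, order-independent, subset-preserving", {
  fx <- fixture()
  calls <- annotate_maf(fx$calls, fx$maf)
  # add calls that each stage must remove
  extra <- calls[1:3, ]
  extra$sample <- "XX-a"
  extra$maf_EA <- c(0.3, NA, NA)
  extra$func <- c("nonsynonymous", "intronic", "nonsynonymous")
  extra$boundary_dist <- c(NA, 25L, NA)
  extra$dna_change <- c("c.1A>G", "c.100-25A>G", "c.2A>G")
  extra$gene <- c("ATM", "ATM", "NOTAGENE")
  calls <- rbind(calls, extra)
  genes <- unique(fx$calls$gene)

  ord1 <- restrict_genes(filter_positional(filter_rare(calls), window = 10), genes)
  ord2 <- filter_rare(filter_positional(restrict_genes(calls, genes), window = 10))
  expect_identical(ord1[order(ord1$sample, ord1$pos), ],
                   ord2[order(ord2$sample, ord2$pos), ])
  expect_identical(filter_rare(ord1), ord1)                       # idempotent
  expect_identical(filter_positional(ord1, window = 10), ord1)
  expect_true(all(rownames(ord1) %in% rownames(calls)))           # pure subset

  # brute-force predicate over every call matches the cascade
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    c0 <- calls[i, ]
    rare <- all(is.na(c(c0$maf_EA, c0$maf_AA)) |
                  c(c0$maf_EA, c0$maf_AA) <= 0.02, na.rm = TRUE)
    d <- if (!is.na(c0$boundary_dist)) c0$boundary_dist else
      parse_intronic_offset(c0$dna_change)
    posn <- c0$func %in% c("nonsynonymous", "synonymous", "frameshift") ||
      (c0$func == "intronic" && !is.na(d) && d <= 10)
    rare && posn && c0$gene %in% genes
  }, logical(1))
  expect_identical(sort(rownames(calls)[keep]), sort(rownames(ord1)))
})
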