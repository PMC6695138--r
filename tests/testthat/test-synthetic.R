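# Synthetic panel-screening data: determinism, conservation, and the
# statistical laws the generator promises.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_samples = c(5, 5)), "named",
               class = "panelval_config_error")
  expect_error(simulation_config(n_samples = c(AA = 0L)), "n_samples",
               class = "panelval_config_error")
  expect_error(simulation_config(genes = data.frame()), "genes",
               class = "panelval_config_error")
  expect_error(depth_model(dropout = 1.5), "dropout",
               class = "panelval_config_error")
  expect_error(artifact_model(rate = -0.1), "rate",
               class = "panelval_config_error")
  expect_error(triage_thresholds(min_depth = 0), "min_depth",
               class = "panelval_config_error")
})

test_that("identical config and seed give identical output, including bytes", {
  cfg <- small_sim_config(seed = 42L, artifact_rate = 0.02, pseudogene = TRUE)
  b1 <- simulate_panel(cfg)
  b2 <- simulate_panel(cfg)
  for (el in c("targets", "depth", "calls", "maf", "sanger", "clinical",
               "cohort", "ledger"))
    expect_identical(b1[[el]], b2[[el]], label = el)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in dir(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  b3 <- simulate_panel(small_sim_config(seed = 43L, artifact_rate = 0.02,
                                        pseudogene = TRUE))
  expect_false(identical(b1$depth, b3$depth))
})

test_that("every emitted call maps to exactly one planted-truth entry", {
  b <- simulate_panel(small_sim_config(seed = 7L, artifact_rate = 0.05,
                                       pseudogene = TRUE))
  expect_equal(nrow(b$calls), nrow(b$ledger))
  ck <- paste(b$calls$sample, variant_key(b$calls$chrom, b$calls$pos,
                                          b$calls$ref, b$calls$alt))
  lk <- paste(b$ledger$sample, variant_key(b$ledger$chrom, b$ledger$pos,
                                           b$ledger$ref, b$ledger$alt))
  expect_identical(ck, lk)
  expect_true(all(b$ledger$true_genotype[b$ledger$is_artifact] == "absent"))
})

test_that("zero artifact rate forces a ledger with no artifacts and all-confirmable calls", {
  b <- simulate_panel(small_sim_config(seed = 7L, artifact_rate = 0))
  expect_equal(sum(b$ledger$is_artifact), 0L)
  expect_true(all(b$sanger$outcome == "confirmed"))
})

test_that("homozygous-alternate calls have allele balance exactly 1", {
  cfg <- small_sim_config(seed = 3L)
  cfg$variants$zygosity <- "all_hom"
  b <- simulate_panel(cfg)
  expect_gt(nrow(b$calls), 0)
  expect_true(all(b$calls$ad_alt == b$calls$dp))
  expect_true(all(allele_balance(b$calls$ad_alt, b$calls$dp) == 1))
})

test_that("heterozygote allele balance is binomial around one half", {
  # one all-het variant, depth pinned at 10,000, 1,000 carriers: the mean
  # allele balance must sit within 0.01 of 0.5 (LLN on Binomial(1e4, .5))
  genes <- data.frame(gene = "G1", n_regions = 1L, region_length = 60L)
  variants <- data.frame(
    gene = "G1", region = 1L, offset = 10L, func = "nonsynonymous",
    clinvar = "VUS", zygosity = "all_het",
    maf_pop_AA = 0.01, maf_cohort_AA = 1, stringsAsFactors = FALSE)
  cfg <- simulation_config(
    n_samples = c(AA = 1000L), genes = genes,
    depth = depth_model(meanlog = log(10000), sdlog = 0, noise_sd = 0,
                        noise_rho = 0, dropout = 0, sample_sdlog = 0),
    variants = variants, artifacts = artifact_model(rate = 0),
    screened_fraction = 0, seed = 11L)
  b <- simulate_panel(cfg)
  expect_equal(nrow(b$calls), 1000L)
  expect_true(all(b$calls$dp == 10000L))
  ab <- b$calls$ad_alt / b$calls$dp
  expect_lt(abs(mean(ab) - 0.5), 0.01)
})

test_that("depth profiles honor the degenerate corners of the model", {
  m0 <- depth_model(meanlog = log(250), sdlog = 0, noise_sd = 0,
                    noise_rho = 0, dropout = 0, sample_sdlog = 0)
  expect_identical(simulate_depth_profile(50L, m0), rep(250L, 50L))
  m1 <- depth_model(meanlog = log(250), sdlog = 0, noise_sd = 0,
                    noise_rho = 0, dropout = 1, sample_sdlog = 0)
  expect_identical(simulate_depth_profile(50L, m1), rep(0L, 50L))
  expect_error(simulate_depth_profile(0L, m0), class = "panelval_config_error")
})

test_that("region means recover the configured log-normal spread", {
  model <- depth_model(meanlog = log(700), sdlog = 0.5, noise_sd = 0.2,
                       noise_rho = 0.9, dropout = 0, sample_sdlog = 0)
  set.seed(11)
  means <- replicate(10000, mean(simulate_depth_profile(80L, model)))
  expect_lt(abs(sd(log(means)) - 0.5) / 0.5, 0.05)
})
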