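# Shared builders for tests: tiny in-code datasets and brute-force oracles.

# A two-gene, few-region target table with known exon cores.
tiny_targets <- function() {
  target_regions(
    gene = c("G1", "G1", "G2"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 400L, 1000L),
    end = c(200L, 500L, 1150L),
    flank = 10L)
}

# Minimal call table; every column the filters and triage touch.
make_calls <- function(n = 0, ...) {
  base <- data.frame(
    sample = character(), group = character(), gene = character(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), func = character(), boundary_dist = integer(),
    clinvar = character(), gt = character(), gq = integer(),
    dp = integer(), ad_alt = integer(), stringsAsFactors = FALSE)
  if (n == 0) return(base)
  out <- data.frame(
    sample = paste0("S", seq_len(n)), group = "AA", gene = "G1",
    chrom = "chr1", pos = 150L + seq_len(n), ref = "A", alt = "G",
    func = "nonsynonymous", boundary_dist = NA_integer_, clinvar = "VUS",
    gt = "het", gq = 99L, dp = 200L, ad_alt = 100L,
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# Depth table from a named per-base vector laid on chr1 starting at pos 1.
depth_table_from <- function(depths, chrom = "chr1", start_pos = 1L) {
  structure(
    data.frame(chrom = chrom, pos = seq_along(depths) + start_pos - 1L,
               total_depth = as.integer(depths), stringsAsFactors = FALSE),
    samples = character())
}

# Brute-force coverage recount: loops base by base, no vectorized path.
brute_region_summary <- function(region, depth, thresholds) {
  vals <- numeric(0)
  for (p in seq.int(region$start + 1L, region$end)) {
    hit <- which(depth$chrom == region$chrom & depth$pos == p)
    vals <- c(vals, if (length(hit)) depth$total_depth[hit] else 0)
  }
  pct <- sapply(thresholds, function(t) {
    k <- 0
    for (v in vals) if (v >= t) k <- k + 1
    100 * k / length(vals)
  })
  list(mean = sum(vals) / length(vals), pct = pct)
}

# Scaled-down simulation config for fast tests.
small_sim_config <- function(seed = 1L, artifact_rate = 0,
                             pseudogene = FALSE, n = c(AA = 8L, EA = 6L),
                             dropout = 0) {
  genes <- data.frame(gene = c("G1", "G2"),
                      n_regions = c(3L, 2L),
                      region_length = c(120L, 90L),
                      stringsAsFactors = FALSE)
  variants <- data.frame(
    gene = c("G1", "G2", "G1"),
    region = c(1L, 2L, 3L),
    offset = c(20L, 30L, 6L),
    func = c("nonsynonymous", "synonymous", "intronic"),
    clinvar = c("Pathogenic", "Likely Benign", "VUS"),
    zygosity = c("hwe", "hwe", "hwe"),
    maf_pop_AA = c(NA, 0.01, 0.002),
    maf_pop_EA = c(NA, 0.004, NA),
    maf_cohort_AA = c(0.15, 0.2, 0.1),
    maf_cohort_EA = c(0.1, 0.15, 0.1),
    stringsAsFactors = FALSE)
  simulation_config(
    n_samples = n, genes = genes,
    depth = depth_model(meanlog = log(500), sdlog = 0.4, noise_sd = 0.2,
                        noise_rho = 0.8, dropout = dropout,
                        sample_sdlog = 0.1),
    variants = variants,
    artifacts = artifact_model(
      rate = artifact_rate,
      pseudogene_region = if (pseudogene) "G2.1" else NULL,
      pseudogene_rate = if (pseudogene) 0.3 else 0),
    screened_fraction = 0.5, screened_genes = c("G1", "G2"),
    seed = seed)
}

# rbind call tables with different column sets (missing columns become NA).
rbind2_calls <- function(a, b) {
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  rbind(a, b[names(a)])
}

# Random 2x2 tables with margins bounded by `max_margin`.
random_tables <- function(n, max_margin = 30L) {
  lapply(seq_len(n), function(i) {
    repeat {
      x <- sample.int(max_margin + 1L, 4L, replace = TRUE) - 1L
      if (sum(x) > 0) return(two_by_two(x[1], x[2], x[3], x[4]))
    }
  })
}

fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_panel_fixture()
    cache
  }
})

# Fixture pushed through the full pipeline, cached per test run.
fixture_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture()
      cfg <- pipeline_config(calls = fx$calls, maf = fx$maf,
                             sanger = fx$sanger, clinical = fx$clinical,
                             cohort = fx$cohort,
                             genes = unique(fx$calls$gene))
      cache <<- suppressMessages(run_pipeline(cfg))
    }
    cache
  }
})
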