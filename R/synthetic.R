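# Seeded synthetic panel-screening datasets: targets, per-base depth,
# calls, population MAF table, orthogonal-truth tables, and a planted-truth
# ledger, with the statistical structure the downstream analysis assumes.

#' Depth model for synthetic capture data
#'
#' Region mean depth is log-normal — hybridization-capture panels show a
#' long right tail of region depths, with per-gene averages in the
#' several-hundred-X range and individual regions spanning well over an
#' order of magnitude. Per-base depth multiplies the region mean by a
#' sample-level log-normal capture factor and stationary AR(1) noise on the
#' log scale (capture efficiency is locally correlated along a probe), with
#' independent per-base dropout producing entirely uncovered bases even
#' inside deep regions.
#'
#' @param meanlog,sdlog Log-mean and log-sd of the region mean depth. The
#'   defaults give an expected panel depth of 809X with region means mostly
#'   between roughly 300X and 1700X.
#' @param noise_sd Stationary sd of the per-base AR(1) log-noise.
#' @param noise_rho AR(1) autocorrelation of the per-base noise.
#' @param dropout Per-base probability of zero coverage.
#' @param sample_sdlog Log-sd of the per-sample capture factor.
#' @return A list of class `depth_model`.
#' @export
depth_model <- function(meanlog = log(809) - 0.5^2 / 2, sdlog = 0.5,
                        noise_sd = 0.3, noise_rho = 0.9,
                        dropout = 0.018, sample_sdlog = 0.2) {
  if (!is.finite(meanlog)) config_error("depth_model: meanlog must be finite")
  for (f in c("sdlog", "noise_sd", "sample_sdlog"))
    if (get(f) < 0) config_error(sprintf("depth_model: %s must be >= 0", f))
  if (!is_proportion(dropout)) config_error("depth_model: dropout must be in [0,1]")
  if (noise_rho < 0 || noise_rho >= 1)
    config_error("depth_model: noise_rho must be in [0,1)")
  structure(list(meanlog = meanlog, sdlog = sdlog, noise_sd = noise_sd,
                 noise_rho = noise_rho, dropout = dropout,
                 sample_sdlog = sample_sdlog), class = "depth_model")
}

#' Artifact model for synthetic false-positive calls
#'
#' Artifacts are spurious calls arising at poorly supported bases: they
#' carry shallow depths (drawn uniformly over `depth_range`, by default
#' 12-63 reads, the band where misalignment artifacts concentrate) and a
#' skewed allele balance drawn from a Beta(2, 4) truncated to (0.05, 0.70).
#' Optionally one region behaves like a locus with a processed pseudogene:
#' mis-mapped paralogous reads produce clustered artifact calls at a few
#' recurrent sites across many samples.
#'
#' @param rate Per-sample, per-region artifact probability.
#' @param depth_range Integer depth range of artifact calls.
#' @param ab_shape Beta shape parameters of the artifact allele balance.
#' @param ab_trunc Truncation interval of the allele-balance distribution.
#' @param pseudogene_region `region_id` of the region receiving clustered
#'   artifacts, or `NULL`.
#' @param pseudogene_rate Per-sample artifact probability in that region.
#' @param pseudogene_sites Number of recurrent artifact sites there.
#' @return A list of class `artifact_model`.
#' @export
artifact_model <- function(rate = 0.001, depth_range = c(12, 63),
                           ab_shape = c(2, 4), ab_trunc = c(0.05, 0.70),
                           pseudogene_region = NULL, pseudogene_rate = 0.25,
                           pseudogene_sites = 4L) {
  if (!is_proportion(rate)) config_error("artifact_model: rate must be in [0,1]")
  if (!is_proportion(pseudogene_rate))
    config_error("artifact_model: pseudogene_rate must be in [0,1]")
  if (length(depth_range) != 2L || any(depth_range < 1) ||
      depth_range[1] > depth_range[2])
    config_error("artifact_model: bad depth_range")
  if (any(ab_shape <= 0)) config_error("artifact_model: ab_shape must be positive")
  structure(list(rate = rate, depth_range = as.integer(depth_range),
                 ab_shape = ab_shape, ab_trunc = ab_trunc,
                 pseudogene_region = pseudogene_region,
                 pseudogene_rate = pseudogene_rate,
                 pseudogene_sites = as.integer(pseudogene_sites)),
            class = "artifact_model")
}

#' Default gene layout of the simulated panel
#'
#' Ten clinically actionable breast/ovarian-cancer susceptibility genes
#' with the region counts and per-region sizes of a 225-region, ~74 kb
#' assessment set.
#'
#' @return `data.frame` with `gene`, `n_regions`, `region_length`.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("ATM", "BRCA1", "BRCA2", "CDH1", "CHEK2",
             "NBN", "PALB2", "PTEN", "STK11", "TP53"),
    n_regions = c(65L, 24L, 28L, 16L, 23L, 22L, 13L, 10L, 10L, 14L),
    region_length = c(239L, 323L, 431L, 329L, 200L,
                      304L, 332L, 1025L, 348L, 301L),
    stringsAsFactors = FALSE)
}

#' Default planted-variant model
#'
#' A small catalogue of germline variants to plant: population MAFs per
#' ancestry group (all rare enough to survive a 2% filter), cohort carrier
#' frequencies used for genotype sampling (a cohort enriched for family
#' history can carry a variant far above its population frequency),
#' zygosity scheme, functional class, and clinical-significance label.
#' Positions are expressed as a region index plus an offset: exonic
#' variants sit `offset` bp into the exon core, intronic ones `offset` bp
#' outside it.
#'
#' @return `data.frame`, one row per planted variant.
#' @export
default_variant_model <- function() {
  data.frame(
    gene = c("BRCA2", "BRCA1", "ATM", "ATM", "STK11", "PALB2", "NBN", "CHEK2"),
    region = c(11L, 20L, 3L, 8L, 2L, 4L, 1L, 13L),
    offset = c(25L, 40L, 12L, 6L, 30L, 18L, 5L, 50L),
    func = c("frameshift", "nonsynonymous", "nonsynonymous", "intronic",
             "synonymous", "nonsynonymous", "intronic", "nonsynonymous"),
    clinvar = c("Pathogenic", "Pathogenic", "Likely Benign", "VUS",
                "Likely Benign", "VUS", "Likely Benign", "VUS"),
    zygosity = c("hwe", "hwe", "hwe", "hwe", "hwe", "hwe", "hwe", "hwe"),
    maf_pop_AA = c(NA, NA, 0.0027, 0.0002, 0.0154, 0.0155, 0.0182, NA),
    maf_pop_EA = c(NA, NA, 0.0136, 0.0026, 0.0002, NA, 0.001, 0.0003),
    maf_cohort_AA = c(0.02, 0.02, 0.05, 0.03, 0.11, 0.05, 0.05, 0.02),
    maf_cohort_EA = c(0.01, 0.01, 0.08, 0.05, 0.01, 0.03, 0.03, 0.05),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every parameter of a synthetic panel-screening dataset. Two
#' runs with an equal configuration (including `seed`) produce identical
#' output, byte for byte; each output component draws from its own RNG
#' substream derived from the master seed, so enlarging one group does not
#' perturb draws made for another.
#'
#' @param n_samples Named integer vector: samples per ancestry group. The
#'   default (23 AA, 20 EA) is a cohort of the size typically enrolled for
#'   an initial panel validation.
#' @param genes Gene layout, as [default_gene_panel()].
#' @param depth A [depth_model()].
#' @param variants Planted variants, as [default_variant_model()].
#' @param artifacts An [artifact_model()]. By default the last PTEN region
#'   acts as the pseudogene-shadowed region.
#' @param screened_fraction Fraction of samples with prior full-gene
#'   clinical screening of the `screened_genes`.
#' @param screened_genes Genes covered by clinical screening records.
#' @param seed Master seed (integer).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = c(AA = 23L, EA = 20L),
                              genes = default_gene_panel(),
                              depth = depth_model(),
                              variants = default_variant_model(),
                              artifacts = artifact_model(
                                pseudogene_region = "PTEN.8"),
                              screened_fraction = 7 / 43,
                              screened_genes = c("BRCA1", "BRCA2"),
                              seed = 1L) {
  if (is.null(names(n_samples)) || any(!nzchar(names(n_samples))))
    config_error("simulation_config: n_samples must be a named vector")
  if (any(n_samples < 1) || any(n_samples != floor(n_samples)))
    config_error("simulation_config: n_samples must be positive counts")
  if (!nrow(genes)) config_error("simulation_config: genes must be non-empty")
  if (any(genes$n_regions < 1) || any(genes$region_length < 22))
    config_error("simulation_config: each gene needs >= 1 region of >= 22 bp")
  stopifnot(inherits(depth, "depth_model"), inherits(artifacts, "artifact_model"))
  if (!is_proportion(screened_fraction))
    config_error("simulation_config: screened_fraction must be in [0,1]")
  if (!is.null(variants) && nrow(variants)) {
    if (!all(variants$gene %in% genes$gene))
      config_error("simulation_config: variants reference unknown genes")
    bad <- variants$region > genes$n_regions[match(variants$gene, genes$gene)]
    if (any(bad)) config_error("simulation_config: variants reference unknown regions")
    mafs <- unlist(variants[, grep("^maf_pop_", names(variants))])
    if (any(!is.na(mafs) & (mafs < 0 | mafs > 0.5)))
      config_error("simulation_config: population MAFs must lie in [0, 0.5]")
    cfreq <- unlist(variants[, grep("^maf_cohort_", names(variants))])
    if (any(!is.na(cfreq) & (cfreq < 0 | cfreq > 1)))
      config_error("simulation_config: cohort carrier frequencies must lie in [0, 1]")
  }
  if (!is_count(seed) && !(is.numeric(seed) && seed == floor(seed)))
    config_error("simulation_config: seed must be an integer")
  structure(list(n_samples = n_samples, genes = genes, depth = depth,
                 variants = variants, artifacts = artifacts,
                 screened_fraction = screened_fraction,
                 screened_genes = screened_genes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Independent RNG substreams derived from the master seed.
.substream <- function(seed, stream, unit = 0L) {
  s <- (as.double(seed) * 2654435761 + stream * 97003 + unit * 101) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a per-base depth profile for one region
#'
#' Draws per-base depths under a [depth_model()] using the current RNG
#' state: `round(region_mean * exp(z_b - noise_sd^2/2))` with `z_b`
#' stationary AR(1) log-noise (the correction keeps the expected
#' multiplier at 1), then per-base dropout zeros. With all noise terms at
#' zero the profile is the rounded region mean at every base.
#'
#' @param length Region length in bp (>= 1).
#' @param model A [depth_model()].
#' @param region_mean Region mean depth; drawn from the model's log-normal
#'   law when `NULL`.
#' @return Integer vector of non-negative depths.
#' @export
simulate_depth_profile <- function(length, model = depth_model(),
                                   region_mean = NULL) {
  if (!is_count(length) || length < 1)
    config_error("simulate_depth_profile: length must be >= 1")
  stopifnot(inherits(model, "depth_model"))
  m <- region_mean %||% stats::rlnorm(1, model$meanlog, model$sdlog)
  z <- numeric(length)
  if (model$noise_sd > 0) {
    # stationary AR(1): draw the innovations, run the recursion vectorized
    innov_sd <- model$noise_sd * sqrt(1 - model$noise_rho^2)
    z0 <- stats::rnorm(1, 0, model$noise_sd)
    e <- stats::rnorm(length, 0, innov_sd)
    z <- as.numeric(stats::filter(e, model$noise_rho, method = "recursive",
                                  init = z0))
  }
  d <- as.integer(round(m * exp(z - model$noise_sd^2 / 2)))
  if (model$dropout > 0)
    d <- d * (stats::runif(length) >= model$dropout)
  as.integer(d)
}

# Lay the configured genes out as target regions on per-gene contigs,
# 1000 bp apart, each region an exon core with 10 bp intronic flanks.
.build_targets <- function(genes, flank = 10L) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    starts <- 10000L + (seq_len(g$n_regions) - 1L) * (g$region_length + 1000L)
    data.frame(gene = g$gene, chrom = paste0("chr_", g$gene),
               start = starts, end = starts + g$region_length,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  target_regions(d$gene, d$chrom, d$start, d$end, flank = flank)
}

.rbeta_trunc <- function(n, shape, trunc) {
  lo <- stats::pbeta(trunc[1], shape[1], shape[2])
  hi <- stats::pbeta(trunc[2], shape[1], shape[2])
  stats::qbeta(lo + stats::runif(n) * (hi - lo), shape[1], shape[2])
}

#' Simulate a complete panel-screening dataset
#'
#' Generates every interchange artifact the analysis pipeline consumes:
#' target regions, a per-base depth table (`total_depth` plus one column
#' per sample), sample-level variant calls, a population MAF table, Sanger
#' and clinical truth tables, a cohort table, and the planted-truth ledger
#' recording, for every emitted call, the true genotype and whether it is
#' an artifact.
#'
#' Heterozygous planted calls draw their alternate-allele depth from
#' `Binomial(DP, 0.5)`; homozygous-alternate calls carry `AD = DP` (allele
#' balance exactly 1). Artifact calls draw shallow depths and skewed
#' allele balance from the [artifact_model()] and always have true
#' genotype `absent`; Sanger truth confirms exactly the non-artifact
#' calls. A call is emitted when at least one alternate read is observed
#' at non-zero depth.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, all components are also
#'   written as interchange files (BED, VCF, TSV) via [write_bundle()].
#' @return A list of class `panel_bundle` with elements `targets`,
#'   `depth`, `calls`, `maf`, `sanger`, `clinical`, `cohort`, `ledger`,
#'   and `config`.
#' @export
simulate_panel <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  targets <- .build_targets(config$genes)
  groups <- names(config$n_samples)
  cohort <- data.frame(
    sample = unlist(lapply(groups, function(g)
      sprintf("%s-%03d", g, seq_len(config$n_samples[[g]])))),
    group = rep(groups, config$n_samples), stringsAsFactors = FALSE)
  n_samp <- nrow(cohort)

  # region mean depths: one stream, independent of sample count
  region_means <- with_seed(.substream(seed, 1L), {
    stats::rlnorm(nrow(targets), config$depth$meanlog, config$depth$sdlog)
  })
  sample_factor <- vapply(seq_len(n_samp), function(i)
    with_seed(.substream(seed, 2L, i),
              stats::rlnorm(1, 0, config$depth$sample_sdlog)), numeric(1))

  # per-base depth, one substream per sample
  n_bases <- sum(targets$end - targets$start)
  pos <- unlist(lapply(seq_len(nrow(targets)), function(r)
    seq.int(targets$start[r] + 1L, targets$end[r])))
  chrom <- rep(targets$chrom, targets$end - targets$start)
  depth_mat <- matrix(0L, n_bases, n_samp)
  for (i in seq_len(n_samp)) {
    depth_mat[, i] <- with_seed(.substream(seed, 3L, i), {
      unlist(lapply(seq_len(nrow(targets)), function(r)
        simulate_depth_profile(targets$end[r] - targets$start[r], config$depth,
                               region_mean = region_means[r] * sample_factor[i])))
    })
  }
  depth <- data.frame(chrom = chrom, pos = pos,
                      total_depth = as.integer(rowSums(depth_mat)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_samp)) depth[[cohort$sample[i]]] <- depth_mat[, i]
  attr(depth, "samples") <- cohort$sample

  # planted variants: genomic position and per-sample genotypes
  variants <- config$variants
  calls <- list(); ledger <- list(); maf_rows <- list(); carriers <- list()
  bases <- c("A", "C", "G", "T")
  if (!is.null(variants) && nrow(variants)) {
    vinfo <- lapply(seq_len(nrow(variants)), function(v) {
      sp <- variants[v, ]
      rid <- paste(sp$gene, sp$region, sep = ".")
      reg <- targets[targets$region_id == rid, ]
      if (sp$func == "intronic") {
        vpos <- reg$exon_start + 1L - sp$offset   # upstream intronic flank
        bdist <- sp$offset
      } else {
        vpos <- reg$exon_start + sp$offset
        bdist <- 0L
      }
      ra <- with_seed(.substream(seed, 4L, v), sample(bases, 2L))
      list(spec = sp, chrom = reg$chrom, pos = as.integer(vpos),
           ref = ra[1], alt = ra[2], boundary_dist = bdist)
    })
    maf_rows <- lapply(vinfo, function(vi) {
      row <- data.frame(chrom = vi$chrom, pos = vi$pos, ref = vi$ref,
                        alt = vi$alt, stringsAsFactors = FALSE)
      for (g in groups) row[[g]] <- vi$spec[[paste0("maf_pop_", g)]]
      row
    })
    depth_key <- paste(depth$chrom, depth$pos)
    for (v in seq_along(vinfo)) {
      vi <- vinfo[[v]]
      sp <- vi$spec
      gts <- with_seed(.substream(seed, 5L, v), {
        vapply(seq_len(n_samp), function(i) {
          if (sp$zygosity == "all_het") return("het")
          if (sp$zygosity == "all_hom") return("hom")
          p <- sp[[paste0("maf_cohort_", cohort$group[i])]]
          if (is.na(p)) p <- 0
          u <- stats::runif(1)
          if (u < p^2) "hom" else if (u < p^2 + 2 * p * (1 - p)) "het" else "absent"
        }, character(1))
      })
      drow <- match(paste(vi$chrom, vi$pos), depth_key)
      for (i in seq_len(n_samp)) {
        if (gts[i] == "absent") next
        carriers[[length(carriers) + 1L]] <- data.frame(
          sample = cohort$sample[i], gene = sp$gene, chrom = vi$chrom,
          pos = vi$pos, ref = vi$ref, alt = vi$alt, gt = gts[i],
          clinvar = sp$clinvar, stringsAsFactors = FALSE)
        dp <- depth_mat[drow, i]
        if (dp < 1L) next
        ad <- if (gts[i] == "hom") dp else
          with_seed(.substream(seed, 6L, v * 100000L + i),
                    stats::rbinom(1, dp, 0.5))
        if (ad < 1L) next
        calls[[length(calls) + 1L]] <- data.frame(
          sample = cohort$sample[i], group = cohort$group[i], gene = sp$gene,
          chrom = vi$chrom, pos = vi$pos, ref = vi$ref, alt = vi$alt,
          func = sp$func, boundary_dist = vi$boundary_dist,
          clinvar = sp$clinvar, gt = gts[i], gq = 99L,
          dp = as.integer(dp), ad_alt = as.integer(ad),
          stringsAsFactors = FALSE)
        ledger[[length(ledger) + 1L]] <- data.frame(
          sample = cohort$sample[i], chrom = vi$chrom, pos = vi$pos,
          ref = vi$ref, alt = vi$alt, true_genotype = gts[i],
          is_artifact = FALSE, stringsAsFactors = FALSE)
      }
    }
  }

  # artifact calls
  am <- config$artifacts
  art <- with_seed(.substream(seed, 7L), {
    rows <- list()
    pg_id <- am$pseudogene_region
    pg_pos <- NULL
    if (!is.null(pg_id)) {
      reg <- targets[targets$region_id == pg_id, ]
      if (!nrow(reg)) config_error(sprintf(
        "artifact_model: pseudogene region %s not in target set", pg_id))
      pg_pos <- sort(sample(seq.int(reg$start + 1L, reg$end), am$pseudogene_sites))
    }
    for (r in seq_len(nrow(targets))) {
      rate <- if (!is.null(pg_id) && targets$region_id[r] == pg_id)
        am$pseudogene_rate else am$rate
      if (rate <= 0) next
      hit <- which(stats::runif(n_samp) < rate)
      for (i in hit) {
        p <- if (!is.null(pg_id) && targets$region_id[r] == pg_id)
          sample(pg_pos, 1L)
        else sample(seq.int(targets$start[r] + 1L, targets$end[r]), 1L)
        dp <- sample(seq.int(am$depth_range[1], am$depth_range[2]), 1L)
        ab <- .rbeta_trunc(1, am$ab_shape, am$ab_trunc)
        ad <- max(1L, min(dp - 1L, as.integer(round(ab * dp))))
        ra <- sample(bases, 2L)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = cohort$sample[i], group = cohort$group[i],
          gene = targets$gene[r], chrom = targets$chrom[r], pos = p,
          ref = ra[1], alt = ra[2], func = "nonsynonymous",
          boundary_dist = NA_integer_, clinvar = ".", gt = "het",
          gq = as.integer(round(stats::runif(1, 40, 99))),
          dp = as.integer(dp), ad_alt = ad, stringsAsFactors = FALSE)
      }
    }
    rows
  })
  for (a in art) {
    calls[[length(calls) + 1L]] <- a
    ledger[[length(ledger) + 1L]] <- data.frame(
      sample = a$sample, chrom = a$chrom, pos = a$pos, ref = a$ref,
      alt = a$alt, true_genotype = "absent", is_artifact = TRUE,
      stringsAsFactors = FALSE)
  }

  empty_calls <- data.frame(
    sample = character(), group = character(), gene = character(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), func = character(), boundary_dist = integer(),
    clinvar = character(), gt = character(), gq = integer(),
    dp = integer(), ad_alt = integer(), stringsAsFactors = FALSE)
  calls <- if (length(calls)) do.call(rbind, calls) else empty_calls
  empty_ledger <- data.frame(
    sample = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), true_genotype = character(),
    is_artifact = logical(), stringsAsFactors = FALSE)
  ledger <- if (length(ledger)) do.call(rbind, ledger) else empty_ledger
  carriers <- if (length(carriers)) do.call(rbind, carriers) else
    data.frame(sample = character(), gene = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               gt = character(), clinvar = character(), stringsAsFactors = FALSE)
  ord <- order(calls$chrom, calls$pos, calls$sample)
  calls <- calls[ord, , drop = FALSE]
  ledger <- ledger[ord, , drop = FALSE]
  rownames(calls) <- rownames(ledger) <- NULL

  maf <- if (length(maf_rows)) do.call(rbind, maf_rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  attr(maf, "groups") <- intersect(groups, names(maf))

  # Sanger truth: ground truth decides validation
  sanger <- data.frame(sample = calls$sample, chrom = calls$chrom,
                       pos = calls$pos, ref = calls$ref, alt = calls$alt,
                       outcome = ifelse(ledger$is_artifact,
                                        "not_confirmed", "confirmed"),
                       stringsAsFactors = FALSE)

  # clinical truth for a fraction of samples (deterministic choice: the
  # first samples of each group, so the screened set is seed-independent)
  clinical <- local({
    rows <- list()
    for (g in groups) {
      s <- cohort$sample[cohort$group == g]
      ns <- round(config$screened_fraction * length(s))
      for (smp in utils::head(s, ns)) {
        for (gene in config$screened_genes) {
          hit <- which(carriers$sample == smp & carriers$gene == gene &
                         tolower(carriers$clinvar) == "pathogenic")
          if (length(hit)) {
            h <- hit[1L]
            rows[[length(rows) + 1L]] <- data.frame(
              sample = smp, gene = gene, scope = "full_screen",
              outcome = "positive", chrom = carriers$chrom[h],
              pos = as.character(carriers$pos[h]), ref = carriers$ref[h],
              alt = carriers$alt[h], stringsAsFactors = FALSE)
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              sample = smp, gene = gene, scope = "full_screen",
              outcome = "negative_full_screen", chrom = ".", pos = ".",
              ref = ".", alt = ".", stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(sample = character(), gene = character(),
                 scope = character(), outcome = character(),
                 chrom = character(), pos = character(),
                 ref = character(), alt = character(),
                 stringsAsFactors = FALSE)
  })

  bundle <- structure(list(targets = targets, depth = depth, calls = calls,
                           maf = maf, sanger = sanger, clinical = clinical,
                           cohort = cohort, ledger = ledger, config = config),
                      class = "panel_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}
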