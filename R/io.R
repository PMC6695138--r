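# Interchange formats: VCF v4.2 call tables, BED6 targets, bundle and
# report writers, and the packaged example dataset.

#' Read variant calls from a VCF
#'
#' Parses a VCF v4.2 whose FORMAT contains at least `GT`, `DP` and `AD`
#' (`GQ` optional) into a sample-level call table: one row per sample and
#' alternate allele with a non-missing genotype. `AD` is read as
#' (ref, alt, ...) allele depths; multi-allelic records are split into
#' bi-allelic calls, each keeping its own alternate depth. The INFO keys
#' `GENE`, `FUNC`, `CLNSIG` and `BDIST` (boundary distance), when present,
#' populate the corresponding columns.
#'
#' @param path Path to a VCF file.
#' @return A call table: `sample`, `gene`, `chrom`, `pos`, `ref`, `alt`,
#'   `func`, `boundary_dist`, `clinvar`, `gt` (`"het"`/`"hom"`), `gq`,
#'   `dp`, `ad_alt`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) config_error(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, , drop = FALSE], stringsAsFactors = FALSE)
  if (!nrow(fix)) return(.empty_call_table())
  fix$INFO <- fix$INFO %||% rep(".", nrow(fix))
  fmt <- v@gt[, "FORMAT", drop = TRUE]
  if (!all(grepl("GT", fmt) & grepl("DP", fmt) & grepl("AD", fmt)))
    parse_error(sprintf("VCF %s: FORMAT must contain GT, DP and AD", path))
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    has <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    out[has] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  gene <- info_field("GENE"); func <- info_field("FUNC")
  clnsig <- info_field("CLNSIG"); bdist <- info_field("BDIST")
  as_mat <- function(x) if (is.null(dim(x)))
    matrix(x, nrow = nrow(fix), dimnames = list(NULL, names(x))) else x
  gt_m <- as_mat(vcfR::extract.gt(v, "GT"))
  dp_m <- as_mat(vcfR::extract.gt(v, "DP"))
  ad_m <- as_mat(vcfR::extract.gt(v, "AD"))
  gq_m <- tryCatch(as_mat(vcfR::extract.gt(v, "GQ")), error = function(e) NULL)
  samples <- colnames(gt_m)
  rows <- list(); skipped <- 0L
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1L]]
    for (s in seq_along(samples)) {
      g <- gt_m[r, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) { skipped <- skipped + 1L; next }
      alleles <- as.integer(strsplit(g, "[/|]")[[1L]])
      if (all(alleles == 0L)) next
      if (is.na(dp_m[r, s]) || is.na(ad_m[r, s]))
        data_error(sprintf("VCF %s: missing DP or AD at %s:%s for %s",
                           path, fix$CHROM[r], fix$POS[r], samples[s]))
      ad <- as.integer(strsplit(ad_m[r, s], ",", fixed = TRUE)[[1L]])
      for (ai in unique(alleles[alleles > 0L])) {
        zyg <- if (sum(alleles == ai) == 2L) "hom" else "het"
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[s], gene = gene[r], chrom = fix$CHROM[r],
          pos = as.integer(fix$POS[r]), ref = fix$REF[r], alt = alts[ai],
          func = func[r],
          boundary_dist = as.integer(bdist[r]),
          clinvar = clnsig[r], gt = zyg,
          gq = if (is.null(gq_m)) NA_integer_ else as.integer(gq_m[r, s]),
          dp = as.integer(dp_m[r, s]), ad_alt = ad[ai + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped) message(sprintf("read_vcf: skipped %d missing genotype(s)", skipped))
  if (!length(rows)) return(.empty_call_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_call_table <- function() {
  data.frame(sample = character(), gene = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             func = character(), boundary_dist = integer(),
             clinvar = character(), gt = character(), gq = integer(),
             dp = integer(), ad_alt = integer(), stringsAsFactors = FALSE)
}

#' Write a call table as VCF v4.2
#'
#' Emits a multi-sample VCF with FORMAT `GT:GQ:DP:AD`; `GENE`, `FUNC`,
#' `CLNSIG` and `BDIST` go to INFO. Reruns on identical input are
#' byte-identical; [read_vcf()] on the result restores every consumed
#' column.
#'
#' @param calls A call table (see [read_vcf()] for the columns).
#' @param path Output path.
#' @export
write_vcf <- function(calls, path) {
  samples <- sort(unique(calls$sample))
  vk <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  uv <- !duplicated(vk)
  v <- calls[uv, , drop = FALSE]
  v <- v[order(v$chrom, v$pos, v$alt), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=BDIST,Number=1,Type=Integer,Description=\"Distance to nearest intron-exon boundary (bp)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  ck <- paste(vk, calls$sample)
  body <- vapply(seq_len(nrow(v)), function(r) {
    info <- c(
      if (!is.na(v$gene[r])) paste0("GENE=", v$gene[r]),
      if (!is.na(v$func[r])) paste0("FUNC=", v$func[r]),
      if (!is.null(v$clinvar) && !is.na(v$clinvar[r]))
        paste0("CLNSIG=", gsub("[;= ]", "_", v$clinvar[r])),
      if (!is.null(v$boundary_dist) && !is.na(v$boundary_dist[r]))
        paste0("BDIST=", v$boundary_dist[r]))
    gts <- vapply(samples, function(s) {
      i <- match(paste(variant_key(v$chrom[r], v$pos[r], v$ref[r], v$alt[r]), s), ck)
      if (is.na(i)) return("./.")
      gt <- if (calls$gt[i] == "hom") "1/1" else "0/1"
      gq <- if (is.na(calls$gq[i])) "." else calls$gq[i]
      sprintf("%s:%s:%d:%d,%d", gt, gq, calls$dp[i],
              calls$dp[i] - calls$ad_alt[i], calls$ad_alt[i])
    }, character(1))
    paste(c(v$chrom[r], v$pos[r], ".", v$ref[r], v$alt[r], ".", "PASS",
            if (length(info)) paste(info, collapse = ";") else ".",
            "GT:GQ:DP:AD", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read target regions from a BED6 file
#'
#' Columns: chrom, start, end (0-based half-open), name (gene symbol),
#' score (region index within the gene), strand. The exonic core is
#' reconstructed as the region minus `flank` bp on either side, the layout
#' used by capture designs that retain a fixed intronic flank.
#'
#' @param path Path to the BED file.
#' @param flank Intronic flank width (bp).
#' @return A target-region table (see [target_regions()]).
#' @export
read_targets_bed <- function(path, flank = 10L) {
  if (!file.exists(path)) config_error(sprintf("BED not found: %s", path))
  b <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(b) < 6L) parse_error(sprintf("BED %s: expected 6 columns", path))
  target_regions(gene = b[[4]], chrom = b[[1]],
                 start = as.integer(b[[2]]), end = as.integer(b[[3]]),
                 region_id = paste(b[[4]], b[[5]], sep = "."), flank = flank)
}

#' Write target regions as BED6
#'
#' @param targets A target-region table.
#' @param path Output path.
#' @export
write_targets_bed <- function(targets, path) {
  idx <- sub("^.*\\.", "", targets$region_id)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t+", targets$chrom, targets$start,
                   targets$end, targets$gene, idx)
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated dataset bundle as interchange files
#'
#' Writes `targets.bed`, `depth.tsv`, `calls.vcf`, `maf.tsv`,
#' `sanger_truth.tsv`, `clinical_truth.tsv`, `cohort.tsv`, and
#' `planted_truth.tsv` into `dir`. Output is deterministic given the
#' bundle.
#'
#' @param bundle A `panel_bundle` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "panel_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_targets_bed(bundle$targets, file.path(dir, "targets.bed"))
  write_depth_table(bundle$depth, file.path(dir, "depth.tsv"))
  write_vcf(bundle$calls, file.path(dir, "calls.vcf"))
  m <- bundle$maf
  for (g in attr(m, "groups") %||% character())
    m[[g]] <- ifelse(is.na(m[[g]]), ".", format(m[[g]], scientific = FALSE, trim = TRUE))
  tsv(m, "maf.tsv")
  tsv(bundle$sanger, "sanger_truth.tsv")
  tsv(bundle$clinical, "clinical_truth.tsv")
  tsv(bundle$cohort, "cohort.tsv")
  tsv(bundle$ledger, "planted_truth.tsv")
  invisible(dir)
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata`, or `NULL` to list
#'   available files.
#' @return A file path (or a vector of file names).
#' @export
panelval_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "panelval")))
  path <- system.file("extdata", file, package = "panelval")
  if (!nzchar(path)) config_error(sprintf("no packaged file '%s'", file))
  path
}

#' Load the packaged panel-validation example dataset
#'
#' A desk-scale validation dataset for a 10-gene hereditary-cancer panel
#' screened in 43 individuals (23 African American, 20 European American):
#' the 74 sample-level calls that survive rarity and positional filtering,
#' with per-call genotype, quality, depth and allele balance; the
#' per-ancestry population MAF table for the 56 unique variants; Sanger
#' validation outcomes for every call; clinical screening truth for the
#' two fully screened genes; and the cohort table. Alternate allele depths
#' are reconstructed as `round(ab * dp)` (total depth for homozygotes),
#' which reproduces the tabulated two-decimal allele balances exactly.
#' The clinical-truth and cohort files are partly synthetic: the
#' identities of the negative-screened samples and of cohort members
#' without any retained call are constructed, not observed.
#'
#' @return A list with `calls`, `maf`, `sanger`, `clinical`, `cohort`.
#' @export
load_panel_fixture <- function() {
  calls <- utils::read.delim(panelval_example("panel_calls.tsv"),
                             colClasses = "character")
  calls$pos <- as.integer(calls$pos)
  calls$gq <- as.integer(calls$gq)
  calls$dp <- as.integer(calls$dp)
  calls$ab_reported <- as.numeric(calls$ab)
  calls$ab <- NULL
  calls$ad_alt <- as.integer(ifelse(calls$gt == "hom", calls$dp,
                                    round(calls$ab_reported * calls$dp)))
  calls$boundary_dist <- parse_intronic_offset(calls$dna_change)
  list(calls = calls,
       maf = read_maf_table(panelval_example("maf_evs.tsv")),
       sanger = read_sanger_truth(panelval_example("sanger_truth.tsv")),
       clinical = read_clinical_truth(panelval_example("clinical_truth_synthetic.tsv")),
       cohort = utils::read.delim(panelval_example("cohort_synthetic.tsv"),
                                  colClasses = "character"))
}

# deterministic fixed-precision formatting for report files
.fmt <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(round_to(x, digits), format = "f",
                                 digits = digits))
}

#' Write pipeline reports
#'
#' Writes deterministic TSV reports into `outdir`: `per_gene_metrics.tsv`
#' (gene, TP/FP/TN/FN, sensitivity, specificity, FDR in both modes),
#' `class_summaries.tsv`, `calls_report.tsv` (the per-call table with
#' allele balance, confidence and validation label), and, when present,
#' `association.tsv`. Depth statistics are printed to the whole X,
#' proportions to two decimals, percentages to one; identical inputs give
#' byte-identical files.
#'
#' @param results A result list from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_reports <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  m <- results$metrics
  m$sensitivity <- .fmt(m$sensitivity, 2)
  m$specificity <- .fmt(m$specificity, 2)
  m$fdr_all <- .fmt(m$fdr_all, 2)
  m$fdr_filtered <- .fmt(m$fdr_filtered, 2)
  tsv(m, "per_gene_metrics.tsv")

  cs <- results$class_summaries
  if (!is.null(cs)) {
    cs$mean_dp <- .fmt(cs$mean_dp, 0)
    cs$mean_ab <- .fmt(cs$mean_ab, 2)
    cs$min_ab <- .fmt(cs$min_ab, 2)
    cs$max_ab <- .fmt(cs$max_ab, 2)
    cs$pct_tp <- .fmt(cs$pct_tp, 1)
    tsv(cs, "class_summaries.tsv")
  }

  calls <- results$calls
  if (!is.null(calls)) {
    calls$ab <- .fmt(calls$ab, 2)
    tsv(calls, "calls_report.tsv")
  }

  if (!is.null(results$association)) {
    a <- results$association
    rows <- lapply(names(a), function(nm) {
      r <- a[[nm]]
      data.frame(contrast = nm,
                 a = r$table[1, 1], b = r$table[1, 2],
                 c = r$table[2, 1], d = r$table[2, 2],
                 p_value = formatC(r$p_value, format = "e", digits = 3),
                 odds_ratio = .fmt(r$estimate, 2),
                 ci95_low = .fmt(r$conf_int[1], 2),
                 ci95_high = .fmt(r$conf_int[2], 2),
                 stringsAsFactors = FALSE)
    })
    tsv(do.call(rbind, rows), "association.tsv")
  }
  invisible(outdir)
}
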