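# Concordance against orthogonal truth: TP/FP labels from Sanger
# validation, FN/TN from prior clinical gene screening, and the derived
# sensitivity / specificity / FDR metrics.

#' Read a Sanger validation truth table
#'
#' TSV with columns `sample`, `chrom`, `pos`, `ref`, `alt`, `outcome`
#' (`confirmed` / `not_confirmed`): one orthogonal-assay verdict per
#' sample-level call.
#'
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
read_sanger_truth <- function(path) {
  if (!file.exists(path)) config_error(sprintf("Sanger truth not found: %s", path))
  x <- utils::read.delim(path, colClasses = "character")
  need <- c("sample", "chrom", "pos", "ref", "alt", "outcome")
  if (!all(need %in% names(x)))
    parse_error(sprintf("Sanger truth %s lacks required columns", path))
  if (!all(x$outcome %in% c("confirmed", "not_confirmed")))
    data_error(sprintf("Sanger truth %s: outcome must be confirmed/not_confirmed", path))
  x$pos <- as.integer(x$pos)
  x
}

#' Read a clinical-screening truth table
#'
#' TSV with columns `sample`, `gene`, `scope` (`full_screen` for complete
#' gene screening, `targeted` for single-variant familial testing),
#' `outcome` (`negative_full_screen` / `positive`), and the reported variant
#' key (`chrom`, `pos`, `ref`, `alt`, `.` when negative). Positive records
#' must carry a variant key; a sample may have at most one record per gene.
#'
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
read_clinical_truth <- function(path) {
  if (!file.exists(path)) config_error(sprintf("clinical truth not found: %s", path))
  x <- utils::read.delim(path, colClasses = "character")
  need <- c("sample", "gene", "scope", "outcome", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x)))
    parse_error(sprintf("clinical truth %s lacks required columns", path))
  if (!all(x$outcome %in% c("negative_full_screen", "positive")))
    data_error(sprintf("clinical truth %s: bad outcome value", path))
  if (any(x$outcome == "positive" & (x$chrom == "." | x$pos == ".")))
    data_error(sprintf("clinical truth %s: positive record without variant key", path))
  if (anyDuplicated(paste(x$sample, x$gene)))
    data_error(sprintf("clinical truth %s: more than one record per sample x gene", path))
  x
}

#' Label calls TP/FP from Sanger validation
#'
#' Matches each call to its Sanger verdict by sample and normalized variant
#' key ([variant_key()]): `confirmed` becomes `TP`, `not_confirmed` becomes
#' `FP`. Calls without any verdict are labeled `unresolved` and excluded
#' from downstream metrics (their count is reported via a message).
#'
#' @param calls A call table.
#' @param sanger A Sanger truth table ([read_sanger_truth()]).
#' @return `calls` with an added `label` column.
#' @export
label_calls <- function(calls, sanger) {
  if (!nrow(calls)) {
    calls$label <- character(0)
    return(calls)
  }
  ck <- paste(calls$sample, variant_key(calls$chrom, calls$pos, calls$ref, calls$alt))
  sk <- paste(sanger$sample, variant_key(sanger$chrom, sanger$pos, sanger$ref, sanger$alt))
  dup <- duplicated(sk)
  if (any(dup)) {
    agree <- tapply(sanger$outcome, sk, function(o) length(unique(o)) == 1L)
    if (!all(agree))
      data_error(sprintf("contradictory Sanger records for %s",
                         names(agree)[which(!agree)[1L]]))
    sanger <- sanger[!dup, , drop = FALSE]
    sk <- sk[!dup]
  }
  idx <- match(ck, sk)
  lab <- ifelse(is.na(idx), "unresolved",
                ifelse(sanger$outcome[idx] == "confirmed", "TP", "FP"))
  if (any(lab == "unresolved"))
    message(sprintf("label_calls: %d call(s) without Sanger truth left unresolved",
                    sum(lab == "unresolved")))
  calls$label <- lab
  calls
}

#' False negatives per gene from clinical truth
#'
#' A false negative is a clinically identified, laboratory-confirmed variant
#' with no matching panel call in the same sample (matching by sample and
#' normalized variant key).
#'
#' @param clinical A clinical truth table ([read_clinical_truth()]).
#' @param calls The call table searched for matches.
#' @return `data.frame` with `gene` and `fn` counts, one row per gene with
#'   clinical truth (zero rows when there are no clinical records).
#' @export
derive_fn <- function(clinical, calls) {
  genes <- sort(unique(clinical$gene))
  if (!length(genes)) return(data.frame(gene = character(), fn = integer()))
  pos <- clinical[clinical$outcome == "positive", , drop = FALSE]
  ck <- paste(calls$sample, variant_key(calls$chrom, calls$pos, calls$ref, calls$alt))
  fn <- vapply(genes, function(g) {
    p <- pos[pos$gene == g, , drop = FALSE]
    if (!nrow(p)) return(0L)
    pk <- paste(p$sample, variant_key(p$chrom, p$pos, p$ref, p$alt))
    sum(!(pk %in% ck))
  }, integer(1))
  data.frame(gene = genes, fn = fn, stringsAsFactors = FALSE)
}

#' True negatives per gene from clinical truth
#'
#' A true-negative unit is a (sample, gene) pair: a sample whose full-gene
#' clinical screen was negative and in which the panel called no pathogenic
#' variant of that gene. Samples tested only for a single familial variant
#' (`scope = "targeted"`) never count, and calls whose clinical-significance
#' annotation is not pathogenic (VUS, benign, ...) do not break TN status.
#'
#' @param clinical A clinical truth table.
#' @param calls The (labeled) call table; needs `clinvar` annotations.
#' @param pathogenic_labels Clinical-significance strings counted as
#'   pathogenic (case-insensitive).
#' @return `data.frame` with `gene` and `tn` counts per screened gene.
#' @export
derive_tn <- function(clinical, calls,
                      pathogenic_labels = c("pathogenic", "risk factor")) {
  neg <- clinical[clinical$outcome == "negative_full_screen" &
                    clinical$scope == "full_screen", , drop = FALSE]
  genes <- sort(unique(clinical$gene))
  if (!length(genes)) return(data.frame(gene = character(), tn = integer()))
  clnsig <- tolower(calls$clinvar %||% rep("", nrow(calls)))
  path_call <- clnsig %in% tolower(pathogenic_labels)
  tn <- vapply(genes, function(g) {
    s <- neg$sample[neg$gene == g]
    bad <- unique(calls$sample[path_call & calls$gene == g])
    sum(!(s %in% bad))
  }, integer(1))
  data.frame(gene = genes, tn = tn, stringsAsFactors = FALSE)
}

ratio_or_na <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Concordance metrics per gene and pooled
#'
#' Counts TP/FP per gene from labeled calls, merges FN/TN from clinical
#' truth, and derives sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' and the false discovery rate `FP/(TP+FP)` in two modes: `fdr_all` over
#' all calls and `fdr_filtered` after removing calls with allele balance at
#' or below the exclusion boundary ([exclude_low_ab()]). Undefined ratios
#' are `NA`, never 0. Sensitivity and specificity are only defined for
#' genes with clinical truth; the `pooled` row aggregates counts over those
#' genes (TN units are (sample, gene) pairs, so six negative-screened
#' samples contribute six TNs to *each* screened gene).
#'
#' @param labeled Calls labeled by [label_calls()] (unresolved calls are
#'   dropped from the counts).
#' @param fn,tn Per-gene count tables from [derive_fn()] / [derive_tn()],
#'   or `NULL` when no clinical truth exists.
#' @param thresholds A [triage_thresholds()] object (for the exclusion
#'   boundary of the filtered mode).
#' @param mode Which mode the headline `sensitivity` / `specificity`
#'   columns use: `"all"` keeps every call, `"ab_filtered"` recomputes
#'   TP/FP after the allele-balance exclusion.
#' @return A `data.frame`, one row per gene plus a final `pooled` row, with
#'   columns `gene`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `fdr_all`, `fdr_filtered`.
#' @export
concordance_metrics <- function(labeled, fn = NULL, tn = NULL,
                                thresholds = triage_thresholds(),
                                mode = c("all", "ab_filtered")) {
  mode <- match.arg(mode)
  resolved <- labeled[labeled$label %in% c("TP", "FP"), , drop = FALSE]
  kept <- exclude_low_ab(resolved, thresholds)
  used <- if (mode == "all") resolved else kept
  genes <- sort(unique(c(resolved$gene, fn$gene, tn$gene)))
  count <- function(df, g, lab) sum(df$gene == g & df$label == lab)
  rows <- lapply(genes, function(g) {
    tp_a <- count(resolved, g, "TP"); fp_a <- count(resolved, g, "FP")
    tp_f <- count(kept, g, "TP");     fp_f <- count(kept, g, "FP")
    tp_u <- count(used, g, "TP");     fp_u <- count(used, g, "FP")
    fng <- if (!is.null(fn) && g %in% fn$gene) fn$fn[fn$gene == g] else NA_integer_
    tng <- if (!is.null(tn) && g %in% tn$gene) tn$tn[tn$gene == g] else NA_integer_
    data.frame(
      gene = g, tp = tp_a, fp = fp_a, tn = tng, fn = fng,
      sensitivity = if (is.na(fng)) NA_real_ else ratio_or_na(tp_u, tp_u + fng),
      specificity = if (is.na(tng)) NA_real_ else ratio_or_na(tng, tng + fp_u),
      fdr_all = ratio_or_na(fp_a, tp_a + fp_a),
      fdr_filtered = ratio_or_na(fp_f, tp_f + fp_f),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # pooled over the clinically screened gene set
  cg <- intersect(genes, unique(c(fn$gene, tn$gene)))
  if (length(cg)) {
    p <- out[out$gene %in% cg, , drop = FALSE]
    tp_u <- sum(vapply(cg, function(g) count(used, g, "TP"), integer(1)))
    fp_u <- sum(vapply(cg, function(g) count(used, g, "FP"), integer(1)))
    tp_f <- sum(vapply(cg, function(g) count(kept, g, "TP"), integer(1)))
    fp_f <- sum(vapply(cg, function(g) count(kept, g, "FP"), integer(1)))
    pooled <- data.frame(
      gene = "pooled", tp = sum(p$tp), fp = sum(p$fp),
      tn = sum(p$tn), fn = sum(p$fn),
      sensitivity = ratio_or_na(tp_u, tp_u + sum(p$fn)),
      specificity = ratio_or_na(sum(p$tn), sum(p$tn) + fp_u),
      fdr_all = ratio_or_na(sum(p$fp), sum(p$tp) + sum(p$fp)),
      fdr_filtered = ratio_or_na(fp_f, tp_f + fp_f),
      stringsAsFactors = FALSE)
    out <- rbind(out, pooled)
  }
  rownames(out) <- NULL
  out
}

#' Depth and allele-balance summaries per concordance class
#'
#' Summarizes read depth and allele balance for the TP and FP classes plus
#' the triage-relevant subsets: calls below the depth threshold, TPs below
#' the depth threshold, heterozygous TPs at or above it, and
#' high-confidence calls. Depth means are conventionally read to the whole
#' X and allele balance to two decimals.
#'
#' @param labeled Calls labeled by [label_calls()], with `ab` computed (see
#'   [triage_calls()]).
#' @param thresholds A [triage_thresholds()] object.
#' @return A `data.frame`, one row per class: `class`, `n`, `mean_dp`,
#'   `min_dp`, `max_dp`, `mean_ab`, `min_ab`, `max_ab`, `pct_tp`.
#' @export
class_summaries <- function(labeled, thresholds = triage_thresholds()) {
  if (is.null(labeled$ab)) labeled <- triage_calls(labeled, thresholds)
  if (is.null(labeled$confidence))
    labeled$confidence <- classify_confidence(labeled$dp, labeled$ab, thresholds)
  deep <- labeled$dp >= thresholds$min_depth
  subsets <- list(
    TP = labeled$label == "TP",
    FP = labeled$label == "FP",
    below_depth = !deep,
    TP_below_depth = !deep & labeled$label == "TP",
    at_or_above_depth = deep,
    TP_het_deep = deep & labeled$label == "TP" & labeled$gt == "het",
    high_confidence = labeled$confidence == "high")
  rows <- lapply(names(subsets), function(nm) {
    d <- labeled[subsets[[nm]], , drop = FALSE]
    if (!nrow(d))
      return(data.frame(class = nm, n = 0L, mean_dp = NA_real_,
                        min_dp = NA_real_, max_dp = NA_real_,
                        mean_ab = NA_real_, min_ab = NA_real_,
                        max_ab = NA_real_, pct_tp = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(class = nm, n = nrow(d),
               mean_dp = mean(d$dp), min_dp = min(d$dp), max_dp = max(d$dp),
               mean_ab = mean(d$ab), min_ab = min(d$ab), max_ab = max(d$ab),
               pct_tp = 100 * mean(d$label == "TP"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
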