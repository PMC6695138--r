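# End-to-end orchestration: filter -> triage -> concordance -> association.

#' Pipeline configuration
#'
#' Collects inputs and tunables for [run_pipeline()]. Each input may be a
#' path to its interchange file or an already-loaded `data.frame`; paths
#' are checked before any computation.
#'
#' @param calls Call table, or path to a VCF ([read_vcf()]).
#' @param maf MAF table or path ([read_maf_table()]); `NULL` skips the
#'   rarity filter.
#' @param sanger Sanger truth table or path ([read_sanger_truth()]).
#' @param clinical Clinical truth table or path ([read_clinical_truth()]);
#'   `NULL` skips FN/TN derivation.
#' @param cohort Cohort table (`sample`, `group`) or path; `NULL` skips
#'   the ancestry association stage.
#' @param targets Target-region table or BED path; optional, used for
#'   boundary distances.
#' @param genes Gene subset to assess; `NULL` keeps all.
#' @param maf_cutoff Inclusive MAF cutoff (proportion).
#' @param intron_window Intronic window around exon boundaries (bp).
#' @param thresholds A [triage_thresholds()] object.
#' @param outdir Report directory, or `NULL` for no files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(calls, maf = NULL, sanger = NULL, clinical = NULL,
                            cohort = NULL, targets = NULL, genes = NULL,
                            maf_cutoff = 0.02, intron_window = 10,
                            thresholds = triage_thresholds(), outdir = NULL) {
  for (nm in c("calls", "maf", "sanger", "clinical", "cohort", "targets")) {
    x <- get(nm)
    if (is.character(x) && !file.exists(x))
      config_error(sprintf("pipeline_config: %s path does not exist: %s", nm, x))
  }
  if (!is_proportion(maf_cutoff))
    config_error("pipeline_config: maf_cutoff must be a proportion")
  if (!is_count(intron_window))
    config_error("pipeline_config: intron_window must be a count")
  stopifnot(inherits(thresholds, "triage_thresholds"))
  structure(list(calls = calls, maf = maf, sanger = sanger,
                 clinical = clinical, cohort = cohort, targets = targets,
                 genes = genes, maf_cutoff = maf_cutoff,
                 intron_window = intron_window, thresholds = thresholds,
                 outdir = outdir), class = "pipeline_config")
}

.load_input <- function(x, reader) {
  if (is.null(x) || is.data.frame(x)) return(x)
  reader(x)
}

#' Run the analytical-validity pipeline
#'
#' Executes the full downstream-of-VCF assessment: gene restriction and
#' the rarity/positional filtering cascade, allele-balance triage,
#' TP/FP labeling against Sanger truth, FN/TN derivation from clinical
#' screening, per-gene and pooled concordance metrics in both FDR modes,
#' class summary statistics, and the ancestry burden contrasts with exact
#' 2x2 inference. Per-stage call counts are reported via `message()`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `calls` (filtered, triaged,
#'   labeled), `audit`, `metrics` (mode `"all"`), `metrics_ab_filtered`,
#'   `class_summaries`, `association` (or `NULL`), `fn`, `tn`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  calls <- .load_input(config$calls, read_vcf)
  maf <- .load_input(config$maf, read_maf_table)
  sanger <- .load_input(config$sanger, read_sanger_truth)
  clinical <- .load_input(config$clinical, read_clinical_truth)
  cohort <- .load_input(config$cohort, function(p)
    utils::read.delim(p, colClasses = "character"))
  targets <- if (is.character(config$targets)) read_targets_bed(config$targets)
  else config$targets

  message(sprintf("pipeline: %d call(s) in", nrow(calls)))
  fc <- filter_calls(calls, maf = maf, targets = targets,
                     genes = config$genes, cutoff = config$maf_cutoff,
                     window = config$intron_window)
  calls <- fc$calls
  for (i in seq_len(nrow(fc$audit)))
    message(sprintf("pipeline: %s kept %d/%d",
                    fc$audit$stage[i], fc$audit$n_kept[i], fc$audit$n_in[i]))

  calls <- triage_calls(calls, config$thresholds)

  fn <- NULL; tn <- NULL
  if (!is.null(sanger)) {
    calls <- label_calls(calls, sanger)
    message(sprintf("pipeline: %d TP, %d FP, %d unresolved",
                    sum(calls$label == "TP"), sum(calls$label == "FP"),
                    sum(calls$label == "unresolved")))
  } else {
    calls$label <- "unresolved"
  }
  if (!is.null(clinical)) {
    fn <- derive_fn(clinical, calls)
    tn <- derive_tn(clinical, calls)
  }
  metrics <- concordance_metrics(calls, fn, tn, config$thresholds, mode = "all")
  metrics_f <- concordance_metrics(calls, fn, tn, config$thresholds,
                                   mode = "ab_filtered")
  cs <- class_summaries(calls, config$thresholds)

  assoc <- NULL
  if (!is.null(cohort)) {
    tabs <- tp_burden_tables(calls, cohort)
    assoc <- list(any_tp = fisher_exact(tabs$any_tp),
                  multiple_tp = fisher_exact(tabs$multiple_tp))
  }

  res <- structure(list(calls = calls, audit = fc$audit, metrics = metrics,
                        metrics_ab_filtered = metrics_f,
                        class_summaries = cs, association = assoc,
                        fn = fn, tn = tn),
                   class = "pipeline_result")
  if (!is.null(config$outdir)) write_reports(res, config$outdir)
  res
}
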