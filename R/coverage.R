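# Depth-of-coverage summaries: per-region, per-depth-bin, and panel-wide.

#' Default depth thresholds for coverage reporting
#'
#' Fold-coverage thresholds at which the percentage of covered bases is
#' reported, the grid conventionally used when benchmarking capture panels.
#' @export
coverage_thresholds <- function() c(1, 10, 20, 50, 100, 250, 500, 1000, 10000)

#' Read a per-base depth table
#'
#' Parses a GATK DepthOfCoverage-style TSV with columns `chrom`, `pos`
#' (1-based), `total_depth`, and optionally one additional integer depth
#' column per sample. All depth columns must be non-negative integers, and
#' no locus may appear twice.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with the file's columns; attribute `samples` holds
#'   the per-sample column names (possibly empty).
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) config_error(sprintf("depth table not found: %s", path))
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("chrom", "pos", "total_depth")
  if (!all(need %in% names(raw)))
    parse_error(sprintf("depth table %s lacks required columns: %s", path,
                        paste(setdiff(need, names(raw)), collapse = ", ")))
  num_cols <- setdiff(names(raw), "chrom")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      parse_error(sprintf(
        "depth table %s: column %s has a non-integer value %s at line %d",
        path, cn, raw[[cn]][bad[1L]], bad[1L] + 1L))
    raw[[cn]] <- as.integer(v)
  }
  key <- paste(raw$chrom, raw$pos)
  if (anyDuplicated(key))
    data_error(sprintf("depth table %s: duplicated locus %s",
                       path, key[which(duplicated(key))[1L]]))
  structure(raw, samples = setdiff(names(raw), need))
}

#' Write a per-base depth table
#'
#' @param depth A depth table as returned by [read_depth_table()] or
#'   produced by [simulate_panel()].
#' @param path Output path.
#' @export
write_depth_table <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Per-base depth values over a region; absent loci count as 0 (uncovered).
region_depth_values <- function(region, depth, what = c("mean", "total")) {
  what <- match.arg(what)
  positions <- seq.int(region$start + 1L, region$end)
  sel <- depth$chrom == region$chrom & depth$pos %in% positions
  d <- depth[sel, , drop = FALSE]
  samples <- attr(depth, "samples") %||% character()
  vals <- if (what == "mean" && length(samples)) {
    rowMeans(as.matrix(d[, samples, drop = FALSE]))
  } else if (what == "mean" && !length(samples)) {
    d$total_depth
  } else {
    d$total_depth
  }
  out <- numeric(length(positions))
  out[match(d$pos, positions)] <- vals
  out
}

summarize_depth_vector <- function(vals, thresholds) {
  qs <- unname(stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7))
  pct <- vapply(thresholds, function(t) 100 * mean(vals >= t), numeric(1))
  c(list(length = length(vals), mean_depth = mean(vals),
         q1 = qs[1], median = qs[2], q3 = qs[3]),
    stats::setNames(as.list(pct), paste0("pct_ge_", thresholds)))
}

#' Summarize coverage over one target region
#'
#' Computes, over every base of the region (bases absent from the depth
#' table count as depth 0), the arithmetic mean depth, quartiles (linear
#' interpolation between order statistics, quantile type 7), and the
#' percentage of bases at or above each threshold.
#'
#' @param region A single-row target-region `data.frame` (see
#'   [target_regions()]).
#' @param depth A depth table from [read_depth_table()].
#' @param what Use the `"mean"` across per-sample columns (cohort-average
#'   depth; falls back to `total_depth` when no sample columns exist) or the
#'   pooled `"total"` depth.
#' @param thresholds Depth thresholds for the percent-covered columns.
#' @return A one-row `data.frame`: `region_id`, `gene`, `length`,
#'   `mean_depth`, `q1`, `median`, `q3`, and one `pct_ge_<t>` column per
#'   threshold.
#' @export
summarize_region <- function(region, depth, what = c("mean", "total"),
                             thresholds = coverage_thresholds()) {
  if (nrow(region) != 1L) config_error("summarize_region expects one region")
  if (region$end <= region$start) config_error("zero-length region")
  vals <- region_depth_values(region, depth, what)
  s <- summarize_depth_vector(vals, thresholds)
  cbind(data.frame(region_id = region$region_id, gene = region$gene,
                   stringsAsFactors = FALSE),
        as.data.frame(s, check.names = FALSE))
}

#' Summarize coverage for every region of a panel
#'
#' @inheritParams summarize_region
#' @param targets A target-region table.
#' @return One row per region, as in [summarize_region()].
#' @export
summarize_regions <- function(targets, depth, what = c("mean", "total"),
                              thresholds = coverage_thresholds()) {
  if (!nrow(targets)) config_error("summarize_regions: empty target table")
  out <- lapply(seq_len(nrow(targets)), function(i)
    summarize_region(targets[i, , drop = FALSE], depth, what, thresholds))
  do.call(rbind, out)
}

#' Bin region summaries by average sequencing depth
#'
#' Groups regions into bins of average depth (`[0,100)`, `[100,200)`, ...,
#' `[1400,1500)`, `[1500,Inf)`, closed on the left) and reports per bin the
#' region count and the unweighted mean of each percent-covered column, the
#' usual shape of a panel depth-distribution table.
#'
#' @param summaries Region summaries from [summarize_regions()].
#' @param width Bin width in X.
#' @param top Lower edge of the open top bin.
#' @return A `data.frame` with `bin` (label), `n_regions`, and the averaged
#'   `pct_ge_*` columns. Bin counts sum to `nrow(summaries)`.
#' @export
bin_regions <- function(summaries, width = 100, top = 1500) {
  if (!nrow(summaries)) config_error("bin_regions: empty summary list")
  edges <- c(seq(0, top, by = width), Inf)
  labels <- c(sprintf("<%d", width),
              sprintf("%d-%d", seq(width, top - width, by = width),
                      seq(2 * width, top, by = width) - 1L),
              sprintf(">%d", top))
  idx <- findInterval(summaries$mean_depth, edges, rightmost.closed = FALSE)
  pct_cols <- grep("^pct_ge_", names(summaries), value = TRUE)
  rows <- lapply(sort(unique(idx)), function(b) {
    m <- summaries[idx == b, pct_cols, drop = FALSE]
    cbind(data.frame(bin = labels[b], n_regions = sum(idx == b),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(m)), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  out[order(match(out$bin, labels)), , drop = FALSE]
}

#' Panel-wide coverage summary
#'
#' Pools the per-base depth multiset of every region (not a mean of region
#' means) and summarizes it like [summarize_region()]. The pooled mean is
#' identical to the length-weighted mean of the region means.
#'
#' @inheritParams summarize_regions
#' @return A one-row `data.frame` with `region_id = "panel"`.
#' @export
panel_summary <- function(targets, depth, what = c("mean", "total"),
                          thresholds = coverage_thresholds()) {
  if (!nrow(targets)) config_error("panel_summary: empty target table")
  vals <- unlist(lapply(seq_len(nrow(targets)), function(i)
    region_depth_values(targets[i, , drop = FALSE], depth, what)))
  s <- summarize_depth_vector(vals, thresholds)
  cbind(data.frame(region_id = "panel", gene = "all", stringsAsFactors = FALSE),
        as.data.frame(s, check.names = FALSE))
}
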