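# Variant-filtering cascade: gene restriction, population-frequency filter,
# positional (coding / near-splice) filter. The filters are conjunctive
# predicates: order-independent and idempotent.

#' Read a population minor-allele-frequency table
#'
#' TSV keyed by variant (`chrom`, `pos`, `ref`, `alt`) with one numeric MAF
#' column per ancestry group; `.` denotes a variant absent from the control
#' repository for that group. Duplicate keys with conflicting values are a
#' data error; exact duplicate rows are collapsed.
#'
#' @param path Path to the TSV.
#' @return A `data.frame`; attribute `groups` names the MAF columns.
#' @export
read_maf_table <- function(path) {
  if (!file.exists(path)) config_error(sprintf("MAF table not found: %s", path))
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(raw)))
    parse_error(sprintf("MAF table %s lacks key columns", path))
  raw <- unique(raw)
  key <- variant_key(raw$chrom, raw$pos, raw$ref, raw$alt)
  if (anyDuplicated(key))
    data_error(sprintf("MAF table %s: conflicting rows for variant %s",
                       path, key[which(duplicated(key))[1L]]))
  groups <- setdiff(names(raw), need)
  for (g in groups) {
    v <- suppressWarnings(as.numeric(ifelse(raw[[g]] == ".", NA, raw[[g]])))
    bad <- !is.na(v) & (v < 0 | v > 0.5)
    if (any(bad))
      data_error(sprintf("MAF table %s: %s out of [0, 0.5] for %s",
                         path, g, key[which(bad)[1L]]))
    raw[[g]] <- v
  }
  raw$pos <- as.integer(raw$pos)
  structure(raw, groups = groups)
}

#' Attach population MAFs to calls
#'
#' Joins per-ancestry-group minor allele frequencies onto a call table by
#' normalized variant key. Variants absent from the table get `NA` in every
#' group (absent from the control repository).
#'
#' @param calls A call table (one row per sample-level call) with `chrom`,
#'   `pos`, `ref`, `alt` columns.
#' @param maf A MAF table from [read_maf_table()].
#' @return `calls` with one added numeric column `maf_<group>` per group.
#' @export
annotate_maf <- function(calls, maf) {
  groups <- attr(maf, "groups") %||%
    setdiff(names(maf), c("chrom", "pos", "ref", "alt"))
  ck <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  mk <- variant_key(maf$chrom, maf$pos, maf$ref, maf$alt)
  if (anyDuplicated(mk))
    data_error(sprintf("MAF table: conflicting rows for variant %s",
                       mk[which(duplicated(mk))[1L]]))
  idx <- match(ck, mk)
  for (g in groups) calls[[paste0("maf_", g)]] <- maf[[g]][idx]
  calls
}

#' Keep rare variants only
#'
#' Retains calls whose population MAF is at or below `cutoff` in *every*
#' ancestry group. A missing MAF (variant absent from the control
#' repository) satisfies the cutoff: absence of frequency evidence is read
#' as rarity, the convention forced by call tables that retain variants
#' unobserved in one or both control populations.
#'
#' @param calls A call table annotated by [annotate_maf()].
#' @param cutoff Inclusive MAF cutoff as a proportion (default 0.02).
#' @return The surviving subset of `calls`, order preserved.
#' @export
filter_rare <- function(calls, cutoff = 0.02) {
  cols <- grep("^maf_", names(calls), value = TRUE)
  if (!length(cols)) config_error("filter_rare: calls carry no maf_* columns")
  m <- as.matrix(calls[, cols, drop = FALSE])
  keep <- apply(m, 1L, function(r) all(is.na(r) | r <= cutoff))
  calls[keep, , drop = FALSE]
}

#' Keep coding and near-splice variants
#'
#' Retains calls whose functional class is coding (`nonsynonymous`,
#' `synonymous`, `frameshift`) and intronic calls within `window` bp of an
#' intron-exon boundary. The boundary distance is taken from a
#' `boundary_dist` column when present, else parsed from a cDNA-style
#' `dna_change` annotation, else computed from the target exon model.
#' Intronic calls whose distance cannot be established are dropped with a
#' warning.
#'
#' @param calls A call table with a `func` column.
#' @param targets Optional target-region table used to compute boundary
#'   distances for calls lacking annotation.
#' @param window Maximum intronic distance retained (bp, default 10).
#' @param coding_classes Functional classes kept unconditionally.
#' @return The surviving subset of `calls`, order preserved.
#' @export
filter_positional <- function(calls, targets = NULL, window = 10,
                              coding_classes = c("nonsynonymous",
                                                 "synonymous", "frameshift")) {
  dist <- calls$boundary_dist %||% rep(NA_integer_, nrow(calls))
  dist <- as.integer(dist)
  if (!is.null(calls$dna_change)) {
    parsed <- parse_intronic_offset(calls$dna_change)
    dist[is.na(dist)] <- parsed[is.na(dist)]
  }
  if (!is.null(targets)) {
    miss <- is.na(dist) & calls$func == "intronic"
    if (any(miss))
      dist[miss] <- boundary_distance(calls$pos[miss], calls$chrom[miss], targets)
  }
  intronic <- calls$func == "intronic"
  unplaced <- intronic & is.na(dist)
  if (any(unplaced))
    warning(sprintf("filter_positional: dropping %d intronic call(s) with no locatable boundary",
                    sum(unplaced)), call. = FALSE)
  keep <- calls$func %in% coding_classes | (intronic & !is.na(dist) & dist <= window)
  calls[keep, , drop = FALSE]
}

#' Restrict calls to a gene set
#'
#' @param calls A call table with a `gene` column.
#' @param genes Character vector of gene symbols to keep.
#' @return The surviving subset of `calls`, order preserved.
#' @export
restrict_genes <- function(calls, genes) {
  calls[calls$gene %in% genes, , drop = FALSE]
}

#' Run the full filtering cascade with an audit trail
#'
#' Applies [restrict_genes()], [annotate_maf()] + [filter_rare()], and
#' [filter_positional()] in sequence and records per-stage in/out counts.
#'
#' @inheritParams filter_rare
#' @inheritParams filter_positional
#' @param genes Gene set to assess; `NULL` keeps all genes.
#' @param maf A MAF table, or `NULL` to skip the rarity filter.
#' @return A list with `calls` (the surviving table) and `audit`
#'   (`data.frame` of stage, n_in, n_kept, n_dropped).
#' @export
filter_calls <- function(calls, maf = NULL, targets = NULL, genes = NULL,
                         cutoff = 0.02, window = 10) {
  audit <- list()
  note <- function(stage, n_in, n_out)
    data.frame(stage = stage, n_in = n_in, n_kept = n_out,
               n_dropped = n_in - n_out, stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    n0 <- nrow(calls); calls <- restrict_genes(calls, genes)
    audit <- c(audit, list(note("restrict_genes", n0, nrow(calls))))
  }
  if (!is.null(maf)) {
    calls <- annotate_maf(calls, maf)
    n0 <- nrow(calls); calls <- filter_rare(calls, cutoff)
    audit <- c(audit, list(note("filter_rare", n0, nrow(calls))))
  }
  n0 <- nrow(calls); calls <- filter_positional(calls, targets, window)
  audit <- c(audit, list(note("filter_positional", n0, nrow(calls))))
  list(calls = calls, audit = do.call(rbind, audit))
}
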