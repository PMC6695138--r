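# Target regions: captured intervals with an exonic core and intronic flanks.

#' Construct a table of target regions
#'
#' A target region is one captured interval of a panel design: an exonic core
#' plus intronic flanking bases retained on either side (panel designs of
#' this kind typically keep 10 bp of flanking intron so that near-splice
#' variants stay visible). Coordinates are 0-based half-open, BED convention.
#'
#' @param gene Gene symbol per region.
#' @param chrom Chromosome per region.
#' @param start,end Region interval, 0-based half-open.
#' @param exon_start,exon_end Exonic core inside the region, 0-based
#'   half-open. Defaults place the core `flank` bp inside each region edge.
#' @param accession Transcript accession (optional, recycled).
#' @param region_id Region identifier; defaults to `gene.<index within gene>`.
#' @param flank Intronic flank width used for the default exon core.
#' @return A `data.frame` with columns `region_id`, `gene`, `accession`,
#'   `chrom`, `start`, `end`, `exon_start`, `exon_end`.
#' @export
target_regions <- function(gene, chrom, start, end,
                           exon_start = NULL, exon_end = NULL,
                           accession = NA_character_, region_id = NULL,
                           flank = 10L) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) config_error("target_regions: every start must be < end")
  n <- length(gene)
  # regions too short for the full flanks keep a centred exon core
  f2 <- pmin(as.integer(flank), (end - start - 1L) %/% 2L)
  exon_start <- as.integer(exon_start %||% (start + f2))
  exon_end <- as.integer(exon_end %||% (end - f2))
  if (any(exon_start < start | exon_end > end | exon_start >= exon_end))
    config_error("target_regions: exon core must lie within [start, end)")
  if (is.null(region_id)) {
    idx <- stats::ave(seq_len(n), gene, FUN = seq_along)
    region_id <- paste(gene, idx, sep = ".")
  }
  df <- data.frame(region_id = region_id, gene = gene,
                   accession = rep_len(accession, n), chrom = chrom,
                   start = start, end = end,
                   exon_start = exon_start, exon_end = exon_end,
                   stringsAsFactors = FALSE)
  ov <- by(df, df$gene, function(d) {
    d <- d[order(d$start), ]
    nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)] & d$chrom[-1] == d$chrom[-nrow(d)])
  })
  if (any(unlist(ov))) config_error("target_regions: regions of a gene overlap")
  df
}

#' Distance from a position to the nearest intron-exon boundary
#'
#' For a 1-based position inside a target region, returns 0 when the base is
#' exonic and otherwise the number of intronic bases separating it from the
#' nearest exon edge (1 = immediately adjacent to the exon). Matches the
#' counting of cDNA-style intronic offsets (`c.100-7A>G` lies 7 bp from the
#' boundary).
#'
#' @param pos 1-based positions.
#' @param chrom Chromosomes matching `pos`.
#' @param targets A target-region table from [target_regions()].
#' @return Integer distances; `NA` for positions outside every region.
#' @export
boundary_distance <- function(pos, chrom, targets) {
  pos <- as.integer(pos)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(pos)) {
    hit <- targets$chrom == chrom[i] & targets$start < pos[i] & targets$end >= pos[i]
    if (!any(hit)) next
    r <- targets[which(hit)[1L], ]
    if (pos[i] > r$exon_start && pos[i] <= r$exon_end) {
      out[i] <- 0L
    } else if (pos[i] <= r$exon_start) {
      out[i] <- r$exon_start + 1L - pos[i]
    } else {
      out[i] <- pos[i] - r$exon_end
    }
  }
  out
}

#' Parse the intronic offset out of a cDNA change string
#'
#' Intronic variants are conventionally written with their distance to the
#' nearest exon encoded in the cDNA name (`c.186-7C>T` is 7 bp upstream of an
#' exon, `c.3993+5G>T` 5 bp downstream). When call tables carry such
#' annotations, the offset can be read directly instead of recomputed from an
#' exon model.
#'
#' @param dna_change Character vector of cDNA change strings.
#' @return Integer distances in bp; `NA` where no intronic offset is encoded.
#' @examples
#' parse_intronic_offset(c("c.186-7C>T", "c.3993+5G>T", "c.146C>G"))
#' @export
parse_intronic_offset <- function(dna_change) {
  m <- regmatches(dna_change,
                  regexpr("c\\.[0-9]+(_[0-9]+)?[+-][0-9]+", dna_change))
  out <- rep(NA_integer_, length(dna_change))
  has <- grepl("c\\.[0-9]+(_[0-9]+)?[+-][0-9]+", dna_change)
  off <- sub("^c\\.[0-9]+(_[0-9]+)?([+-][0-9]+)$", "\\2", m)
  out[has] <- abs(as.integer(off))
  out
}
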