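# Internal helpers: structured conditions and variant-key handling.

pv_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "panelval_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

config_error <- function(msg) pv_stop(msg, "panelval_config_error")
data_error   <- function(msg) pv_stop(msg, "panelval_data_error")
parse_error  <- function(msg) pv_stop(msg, "panelval_parse_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_proportion <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)
}

#' Normalize a variant key
#'
#' Left-normalizes an allele pair so that equivalent representations of the
#' same indel compare equal: `"-"` / `"."` placeholders become empty strings,
#' shared trailing bases are trimmed, then shared leading bases are trimmed
#' with the position advanced accordingly. SNVs pass through unchanged.
#' Indels inside short tandem repeats can be printed under several
#' right-shifted names; matching calls against truth records uses the
#' normalized key so those aliases agree.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position (integer).
#' @param ref,alt Reference and alternate alleles; `"-"` or `"."` denote an
#'   empty allele (ANNOVAR-style indels).
#' @return A character vector of keys `"chrom:pos:ref:alt"` (empty alleles
#'   shown as `-`).
#' @examples
#' variant_key("chr13", 32339966, "AGTAA", "-")
#' variant_key("chr17", 43051071, "A", "C")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  n <- length(chrom)
  pos <- as.integer(pos)
  ref <- toupper(ifelse(ref %in% c("-", "."), "", ref))
  alt <- toupper(ifelse(alt %in% c("-", "."), "", alt))
  out <- character(n)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim the shared prefix first (drops VCF anchor bases), advancing the
    # position, then any shared suffix
    while (nchar(r) > 0 && nchar(a) > 0 && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    while (nchar(r) > 0 && nchar(a) > 0 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    out[i] <- paste(chrom[i], p,
                    if (nchar(r)) r else "-",
                    if (nchar(a)) a else "-", sep = ":")
  }
  out
}

round_to <- function(x, digits) {
  # round() with a fixed tie-break away from zero, so report files are
  # byte-identical across platforms
  s <- sign(x)
  y <- abs(x) * 10^digits
  s * floor(y + 0.5) / 10^digits
}
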