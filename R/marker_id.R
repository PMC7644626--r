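#' Parse DGRP-style marker identifiers
#'
#' Marker identifiers follow the `chrom_pos_class` convention used by DGRP
#' genotype releases, e.g. `"3R_21373234_SNP"`: chromosome arm, 1-based
#' position, and a variant-class token (`SNP`, `DEL`, `INS`, `MNP`).
#' Chromosome labels may themselves contain underscores; the last two
#' underscore-separated fields are always position and class.
#'
#' @param x character vector of marker ids.
#' @return A data.frame with columns `marker`, `chrom`, `pos` (integer) and
#'   `var_class`.
#' @examples
#' parse_marker_id("3R_21373234_SNP")
#' @export
parse_marker_id <- function(x) {
  if (!is.character(x) || length(x) == 0)
    stop_radgut("marker ids must be a non-empty character vector")
  parts <- strsplit(x, "_", fixed = TRUE)
  n <- lengths(parts)
  bad <- which(n < 3L)
  if (length(bad))
    stop_radgut("malformed marker id '%s' (entry %d): expected chrom_pos_class",
                x[bad[1L]], bad[1L])
  chrom <- vapply(parts, function(p) paste(p[seq_len(length(p) - 2L)], collapse = "_"),
                  character(1))
  pos_chr <- vapply(parts, function(p) p[length(p) - 1L], character(1))
  var_class <- vapply(parts, function(p) p[length(p)], character(1))
  pos <- suppressWarnings(as.integer(pos_chr))
  bad <- which(is.na(pos) | pos < 1L | pos_chr != as.character(pos))
  if (length(bad))
    stop_radgut("malformed marker id '%s' (entry %d): position must be a positive integer",
                x[bad[1L]], bad[1L])
  bad <- which(!grepl("^[A-Za-z0-9]+$", var_class))
  if (length(bad))
    stop_radgut("malformed marker id '%s' (entry %d): bad variant-class token",
                x[bad[1L]], bad[1L])
  data.frame(marker = x, chrom = chrom, pos = pos, var_class = var_class,
             stringsAsFactors = FALSE)
}

#' Format marker identifiers from components
#'
#' Inverse of [parse_marker_id()]: `format_marker_id(parse_marker_id(x))`
#' is the identity.
#'
#' @param chrom chromosome-arm labels, or a data.frame with columns
#'   `chrom`, `pos`, `var_class`.
#' @param pos 1-based positions.
#' @param var_class variant-class tokens.
#' @return Character vector of `chrom_pos_class` ids.
#' @export
format_marker_id <- function(chrom, pos = NULL, var_class = NULL) {
  if (is.data.frame(chrom)) {
    pos <- chrom$pos
    var_class <- chrom$var_class
    chrom <- chrom$chrom
  }
  if (any(pos < 1L))
    stop_radgut("marker positions must be >= 1")
  paste(chrom, pos, var_class, sep = "_")
}
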