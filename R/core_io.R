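# Domain containers and plain-text readers/writers.
#
# Conventions: all coordinates are 1-based closed intervals (DGRP marker
# naming, GFF3). Genotype calls are 0 = major, 1 = minor, NA = missing; lines
# are fully inbred so a single biallelic call per line suffices. Readers
# reject out-of-contract values rather than coercing them.

#' Construct a genotype panel
#'
#' A marker-by-line matrix of homozygous biallelic calls (0 = major allele,
#' 1 = minor allele, `NA` = missing) with marker coordinates parsed from
#' DGRP-style row names.
#'
#' @param calls integer matrix (markers x lines) with entries 0/1/NA. Row
#'   names must be `chrom_pos_class` marker ids, column names line ids.
#' @param markers optional pre-parsed marker data.frame as returned by
#'   [parse_marker_id()]; derived from `rownames(calls)` when `NULL`.
#' @return An object of class `genotype_panel`: a list with elements
#'   `calls`, `markers`, `line_ids`.
#' @export
genotype_panel <- function(calls, markers = NULL) {
  if (!is.matrix(calls))
    stop_radgut("calls must be a matrix")
  if ((nrow(calls) > 0 && is.null(rownames(calls))) ||
      (ncol(calls) > 0 && is.null(colnames(calls))))
    stop_radgut("calls must have marker row names and line column names")
  storage.mode(calls) <- "integer"
  vals <- calls[!is.na(calls)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop_radgut("genotype calls must be 0, 1 or NA (found '%s')",
                vals[!vals %in% c(0L, 1L)][1L])
  if (anyDuplicated(colnames(calls)))
    stop_radgut("duplicated line id '%s'", colnames(calls)[duplicated(colnames(calls))][1L])
  if (anyDuplicated(rownames(calls)))
    stop_radgut("duplicated marker id '%s'", rownames(calls)[duplicated(rownames(calls))][1L])
  if (is.null(markers)) markers <- parse_marker_id(rownames(calls))
  if (nrow(markers) != nrow(calls))
    stop_radgut("marker table (%d rows) does not match call matrix (%d rows)",
                nrow(markers), nrow(calls))
  structure(list(calls = calls, markers = markers,
                 line_ids = colnames(calls) %||% character(0)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d markers x %d lines (%d missing calls)\n",
              nrow(x$calls), ncol(x$calls), sum(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

#' Subset a genotype panel by markers and/or lines
#'
#' @param x a `genotype_panel`.
#' @param i marker index (integer/logical/character).
#' @param j line index.
#' @param ... ignored.
#' @return A `genotype_panel`.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  if (is.character(i)) i <- match(i, rownames(x$calls))
  if (is.logical(i)) i <- which(i)
  genotype_panel(calls, markers = x$markers[i, , drop = FALSE])
}

#' Construct/validate a Smurf phenotype table
#'
#' Long-format per-line, per-dose (optionally per-vial) counts of Smurf
#' (gut-permeable) flies. Counts, not proportions, are stored so that
#' binomial sampling depth is preserved.
#'
#' @param x data.frame with columns `line_id`, `dose_gy`, `n_total`,
#'   `n_smurf` and optionally `vial_id`.
#' @return The validated data.frame with class `phenotype_table`.
#' @export
phenotype_table <- function(x) {
  need <- c("line_id", "dose_gy", "n_total", "n_smurf")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_radgut("phenotype table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(x) == 0) stop_radgut("phenotype table is empty")
  x$line_id <- as.character(x$line_id)
  for (cl in c("dose_gy", "n_total", "n_smurf")) {
    x[[cl]] <- as.numeric(x[[cl]])
    if (anyNA(x[[cl]])) stop_radgut("column '%s' contains missing/non-numeric values", cl)
  }
  if (any(x$dose_gy < 0)) stop_radgut("dose_gy must be >= 0")
  if (any(x$n_total <= 0 | x$n_total != round(x$n_total)))
    stop_radgut("n_total must be a positive integer count")
  if (any(x$n_smurf < 0 | x$n_smurf != round(x$n_smurf)))
    stop_radgut("n_smurf must be a non-negative integer count")
  if (any(x$n_smurf > x$n_total))
    stop_radgut("n_smurf exceeds n_total in row %d", which(x$n_smurf > x$n_total)[1L])
  key <- if ("vial_id" %in% names(x))
    paste(x$line_id, x$dose_gy, x$vial_id) else paste(x$line_id, x$dose_gy)
  if (anyDuplicated(key))
    stop_radgut("duplicated (line_id, dose_gy%s) record: %s",
                if ("vial_id" %in% names(x)) ", vial_id" else "",
                key[duplicated(key)][1L])
  class(x) <- unique(c("phenotype_table", class(x)))
  x
}

#' Construct/validate a survival table
#'
#' @param x data.frame with columns `group`, `time` (days, > 0) and `event`
#'   (1/TRUE = death observed, 0/FALSE = right-censored).
#' @return Validated data.frame of class `survival_table`.
#' @export
survival_table <- function(x) {
  need <- c("group", "time", "event")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_radgut("survival table lacks column(s): %s", paste(miss, collapse = ", "))
  x$group <- as.character(x$group)
  x$time <- as.numeric(x$time)
  x$event <- as.integer(as.logical(x$event))
  if (any(!is.finite(x$time) | x$time <= 0))
    stop_radgut("survival times must be finite and positive")
  if (anyNA(x$event)) stop_radgut("event flags must be 0/1")
  class(x) <- unique(c("survival_table", class(x)))
  x
}

#' Construct/validate a set of 3'UTR sequences
#'
#' @param x named character vector of sequences over the alphabet
#'   `A C G T U N` (case-insensitive). Names must be unique; sequences
#'   non-empty. Records consisting only of `N` are retained but flagged
#'   zero-information in the `"zero_information"` attribute.
#' @return Named character vector of class `utr_set`.
#' @export
utr_set <- function(x) {
  if (length(x) == 0) stop_radgut("empty sequence set")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop_radgut("all sequences must be named")
  if (anyDuplicated(names(x)))
    stop_radgut("duplicated sequence name '%s'", names(x)[duplicated(names(x))][1L])
  nm <- names(x)
  x <- stats::setNames(toupper(as.character(x)), nm)
  if (any(!nzchar(x))) stop_radgut("sequence '%s' is empty", names(x)[!nzchar(x)][1L])
  bad <- regexpr("[^ACGTUN]", x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop_radgut("sequence '%s' has invalid character '%s' at offset %d",
                names(x)[i], substr(x[i], bad[i], bad[i]), bad[i])
  }
  attr(x, "zero_information") <- names(x)[grepl("^N+$", x)]
  class(x) <- "utr_set"
  x
}

#' Construct a gene-feature interval index
#'
#' Per-chromosome 1-based closed intervals carrying a feature class (a
#' controlled vocabulary including `EXON`, `INTRON`, `NON_CODING`) and a gene
#' name, used to label markers the way GWAS candidate tables report
#' "Effect/location".
#'
#' @param x data.frame with columns `chrom`, `start`, `end`,
#'   `feature_class`, `gene`.
#' @return Validated data.frame of class `feature_index`.
#' @export
feature_index <- function(x) {
  need <- c("chrom", "start", "end", "feature_class", "gene")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_radgut("feature index lacks column(s): %s", paste(miss, collapse = ", "))
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$feature_class <- toupper(as.character(x$feature_class))
  x$gene <- as.character(x$gene)
  if (any(x$end < x$start))
    stop_radgut("feature interval with end < start at row %d", which(x$end < x$start)[1L])
  class(x) <- unique(c("feature_index", class(x)))
  x
}

# ---------------------------------------------------------------------------
# Readers

#' Read a DGRP-style genotype matrix
#'
#' Tab-separated, one row per marker: first column the `chrom_pos_class`
#' marker id, remaining columns one per line. Two call dialects are
#' supported: `"standard"` codes calls as `0`/`1`/`NA`; `"dgrp"` uses the
#' DGRP release coding `0`/`2`/`-`, remapped here as 2 -> 1 (minor) and
#' `-` -> missing.
#'
#' @param path path to the TSV file; first header field names the marker
#'   column, the rest are line ids.
#' @param dialect `"standard"` or `"dgrp"`.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, dialect = c("standard", "dgrp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_radgut("genotype file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1)
    stop_radgut("ragged genotype file %s: rows have %s fields", path,
                paste(unique(nf), collapse = "/"))
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, colClasses = "character",
                      check.names = FALSE, na.strings = NULL, fill = FALSE,
                      blank.lines.skip = TRUE),
    error = function(e) stop_radgut("ragged or unreadable genotype file %s: %s",
                                    path, conditionMessage(e)))
  if (ncol(raw) < 2) stop_radgut("genotype file must have a marker column plus line columns")
  ids <- raw[[1L]]
  markers <- parse_marker_id(ids)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  allowed <- if (dialect == "dgrp") c("0", "2", "-") else c("0", "1", "NA", "")
  bad <- which(!(m %in% allowed))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop_radgut("unknown call symbol '%s' at marker %s, line %s",
                m[bad[1L]], ids[rc[1L]], colnames(m)[rc[2L]])
  }
  calls <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = list(ids, colnames(m)))
  if (dialect == "dgrp") {
    calls[m == "0"] <- 0L
    calls[m == "2"] <- 1L
  } else {
    calls[m == "0"] <- 0L
    calls[m == "1"] <- 1L
  }
  genotype_panel(calls, markers = markers)
}

#' Write a genotype panel to DGRP-style TSV
#'
#' @param panel a `genotype_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  m <- panel$calls
  df <- data.frame(marker = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a Smurf phenotype table
#'
#' Delimited file (comma or tab, auto-detected from the header line) with
#' columns `line_id`, `dose_gy`, `n_total`, `n_smurf`, optional `vial_id` —
#' one record per line x condition, or per vial when vials are scored
#' separately (e.g. 25 flies per vial).
#'
#' @param path file path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_radgut("phenotype file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  phenotype_table(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE))
}

#' Write a phenotype table
#'
#' @param phen a `phenotype_table`.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(as.data.frame(phen), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read 3'UTR sequences from FASTA
#'
#' DNA or RNA alphabets are accepted (`T` and `U` may be mixed across
#' records); motif scanning normalises T -> U.
#'
#' @param path FASTA file path.
#' @return A [utr_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_radgut("FASTA file not found: %s", path)
  seqs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop_radgut("duplicated FASTA record name '%s'", nm[duplicated(nm)][1L])
  utr_set(stats::setNames(as.character(seqs), nm))
}

#' Write a sequence set to FASTA
#'
#' @param utrs a `utr_set` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(utrs, path) {
  x <- Biostrings::BStringSet(stats::setNames(as.character(utrs), names(utrs)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Imports a GFF3 file and builds a [feature_index()] for marker location
#' labelling. Feature classes are taken from the GFF `type` column and
#' upper-cased; `ncRNA`-style types map to `NON_CODING`. The gene name is the
#' first populated attribute among `gene`, `gene_id`, `Name`, `ID`.
#'
#' @param path GFF3 file path.
#' @return A `feature_index`.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop_radgut("GFF file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_radgut("invalid GFF3 %s: %s", path,
                                                 conditionMessage(e)))
  df <- as.data.frame(gr)
  cls <- toupper(as.character(df$type))
  cls[grepl("NC_RNA|NCRNA|NON[-_ ]?CODING", cls)] <- "NON_CODING"
  gene <- rep(NA_character_, nrow(df))
  for (field in c("gene", "gene_id", "Name", "ID")) {
    if (field %in% names(df)) {
      v <- as.character(df[[field]])
      gene[is.na(gene) & !is.na(v) & nzchar(v)] <-
        v[is.na(gene) & !is.na(v) & nzchar(v)]
    }
  }
  feature_index(data.frame(chrom = as.character(df$seqnames),
                           start = df$start, end = df$end,
                           feature_class = cls, gene = gene,
                           stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# Scan-result TSV

scan_results_columns <- c("marker", "chrom", "pos", "class", "n_lines_used",
                          "beta_interaction", "se", "t", "p", "fdr_percent",
                          "location", "gene")

#' Write scan results to TSV
#'
#' Emits the candidate-table-compatible column set `marker, chrom, pos,
#' class, n_lines_used, beta_interaction, se, t, p, fdr_percent, location,
#' gene`. Numeric fields are printed at full IEEE precision so a
#' write-then-read round trip is the identity.
#'
#' @param scan a `gxe_scan` result (see [gxe_scan()]).
#' @param path output path.
#' @param fdr optional [empirical_fdr()] result aligned with `scan` (fills
#'   `fdr_percent`).
#' @param features optional [feature_index()] (fills `location`/`gene`).
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(scan, path, fdr = NULL, features = NULL) {
  df <- as.data.frame(scan)
  fdr_percent <- if (!is.null(fdr)) fdr$fdr_percent else rep(NA_real_, nrow(df))
  if (!is.null(fdr) && length(fdr_percent) != nrow(df))
    stop_radgut("fdr result (%d markers) does not match scan (%d markers)",
                length(fdr_percent), nrow(df))
  if (!is.null(features)) {
    ann <- annotate_markers(df, features)
    location <- ann$location
    gene <- ann$gene
  } else {
    location <- rep(NA_character_, nrow(df))
    gene <- rep(NA_character_, nrow(df))
  }
  out <- data.frame(marker = df$marker, chrom = df$chrom, pos = df$pos,
                    class = df$var_class, n_lines_used = df$n_obs,
                    beta_interaction = fmt_full(df$beta_interaction),
                    se = fmt_full(df$se_interaction),
                    t = fmt_full(df$t_interaction),
                    p = fmt_full(df$p),
                    fdr_percent = fmt_full(fdr_percent),
                    location = location, gene = gene,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a scan-results TSV written by [write_scan_results()]
#'
#' @param path file path.
#' @return data.frame with the standard result columns; numeric fields
#'   restored at full precision.
#' @export
read_scan_results <- function(path) {
  if (!file.exists(path)) stop_radgut("results file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(scan_results_columns, names(df))
  if (length(miss))
    stop_radgut("results file lacks column(s): %s", paste(miss, collapse = ", "))
  for (cl in c("pos", "n_lines_used")) df[[cl]] <- as.integer(df[[cl]])
  for (cl in c("beta_interaction", "se", "t", "p", "fdr_percent"))
    df[[cl]] <- as.numeric(df[[cl]])
  df
}
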