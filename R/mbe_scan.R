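# Musashi-Binding-Element scan of 3'UTR sequences.
#
# Musashi-family translational repressors bind a short single-stranded RNA
# element in target 3'UTRs; the literature consensus is (G/A)U(1-3)AGU.
# Sequences are scanned on the sense strand only (3'UTRs are sense-strand by
# contract; reverse complements are never taken implicitly). Genes carrying
# at least `min_sites` elements are shortlisted.

#' MBE scan configuration
#'
#' @param pattern motif specification as a regular expression over the RNA
#'   alphabet; default the consensus `[GA]U{1,3}AGU`.
#' @param min_sites shortlist threshold: genes with this many sites or more
#'   are flagged (default 4).
#' @param overlap_policy `"non_overlapping_greedy"` (default; after a match
#'   the scan resumes past its end, so reported intervals are pairwise
#'   disjoint — distinct "repeats") or `"all_overlapping"` (a match is
#'   counted at every start offset).
#' @param pwm optional 4 x w position weight matrix (rows A, C, G, U/T) for
#'   users who have a scoring model; scanning is then routed through
#'   [Biostrings::matchPWM()] with `pwm_min_score`, and `pattern` is
#'   ignored.
#' @param pwm_min_score minimum PWM score, as accepted by `matchPWM`
#'   (default `"80%"`).
#' @return list of class `mbe_config`.
#' @export
mbe_config <- function(pattern = "[GA]U{1,3}AGU", min_sites = 4L,
                       overlap_policy = c("non_overlapping_greedy",
                                          "all_overlapping"),
                       pwm = NULL, pwm_min_score = "80%") {
  overlap_policy <- match.arg(overlap_policy)
  if (!is.character(pattern) || !nzchar(pattern))
    stop_radgut("pattern must be a non-empty regular expression")
  if (!is_count(min_sites) || min_sites < 1)
    stop_radgut("min_sites must be >= 1")
  if (!is.null(pwm)) {
    pwm <- as.matrix(pwm)
    if (nrow(pwm) != 4) stop_radgut("pwm must have 4 rows (A, C, G, U/T)")
    rownames(pwm) <- c("A", "C", "G", "T")
  }
  structure(list(pattern = pattern, min_sites = as.integer(min_sites),
                 overlap_policy = overlap_policy, pwm = pwm,
                 pwm_min_score = pwm_min_score),
            class = "mbe_config")
}

# Upper-case, T -> U, and reject anything outside {A,C,G,U,N} naming the
# first bad offset. N never matches the consensus (the pattern only admits
# A/C/G/U literals).
normalize_rna <- function(seq) {
  s <- chartr("T", "U", toupper(seq))
  bad <- regexpr("[^ACGUN]", s)
  if (bad > 0)
    stop_radgut("invalid character '%s' at offset %d", substr(s, bad, bad), bad)
  s
}

#' Find MBE sites in one sequence
#'
#' Left-to-right scan of the (T -> U normalised) sequence for the configured
#' motif. Intervals are 1-based and closed, reported in ascending order.
#'
#' @param seq one sequence (DNA or RNA alphabet; N allowed, never matches).
#' @param config an [mbe_config()].
#' @return data.frame with columns `start`, `end` (1-based closed).
#' @examples
#' find_mbe_sites("GGAUAGUGG")  # one site: the AUAGU at 3..7
#' @export
find_mbe_sites <- function(seq, config = mbe_config()) {
  if (length(seq) != 1) stop_radgut("find_mbe_sites() scans one sequence at a time")
  s <- normalize_rna(seq)
  if (!is.null(config$pwm)) {
    subject <- Biostrings::DNAString(chartr("U", "T", s))
    hits <- Biostrings::matchPWM(config$pwm, subject,
                                 min.score = config$pwm_min_score)
    return(data.frame(start = BiocGenerics::start(hits),
                      end = BiocGenerics::end(hits)))
  }
  if (config$overlap_policy == "non_overlapping_greedy") {
    m <- gregexpr(config$pattern, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(data.frame(start = integer(0), end = integer(0)))
    start <- as.integer(m)
    len <- attr(m, "match.length")
    return(data.frame(start = start, end = start + len - 1L))
  }
  # all_overlapping: test an anchored match at every start offset
  anchored <- paste0("^(?:", config$pattern, ")")
  n <- nchar(s)
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(n)) {
    m <- regexpr(anchored, substr(s, i, n), perl = TRUE)
    if (m == 1L) {
      starts <- c(starts, i)
      ends <- c(ends, i + attr(m, "match.length") - 1L)
    }
  }
  data.frame(start = starts, end = ends)
}

#' Count MBE sites per gene and shortlist
#'
#' @param utrs a [utr_set()].
#' @param config an [mbe_config()].
#' @return data.frame of class `mbe_report`: columns `gene`, `n_sites`,
#'   `shortlisted` (TRUE iff `n_sites >= min_sites`); the per-gene site
#'   interval tables are attached as attribute `"sites"`.
#' @export
shortlist_genes <- function(utrs, config = mbe_config()) {
  utrs <- utr_set(unclass(utrs))
  sites <- lapply(as.character(utrs), find_mbe_sites, config = config)
  names(sites) <- names(utrs)
  out <- data.frame(gene = names(utrs),
                    n_sites = vapply(sites, nrow, integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$shortlisted <- out$n_sites >= config$min_sites
  rownames(out) <- NULL
  attr(out, "sites") <- sites
  class(out) <- c("mbe_report", "data.frame")
  out
}

#' Export MBE sites to BED
#'
#' Converts the report's 1-based closed intervals to BED's 0-based
#' half-open convention.
#'
#' @param report an `mbe_report` from [shortlist_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mbe_bed <- function(report, path) {
  sites <- attr(report, "sites")
  if (is.null(sites)) stop_radgut("report carries no site intervals")
  rows <- do.call(rbind, lapply(names(sites), function(g) {
    s <- sites[[g]]
    if (!nrow(s)) return(NULL)
    data.frame(chrom = g, start = s$start - 1L, end = s$end,
               name = sprintf("MBE_%d", seq_len(nrow(s))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(chrom = character(0), start = integer(0),
                                        end = integer(0), name = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
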