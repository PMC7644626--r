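# Synthetic DGRP-like data with planted effects.
#
# The generator emulates the study conditions of the screen: ~156 fully
# inbred lines phenotyped with ~100 flies per line in paired 0 Gy / 100 Gy
# conditions. The generative model mirrors the fitted one — a per-line
# latent value baseline + dose_effect*D + sum(b_G*G + b_GxD*G*D) + line
# effect, mapped to a Smurf probability and observed through binomial
# sampling — so that planted interaction effects are recoverable on the
# scale the scan estimates them.

#' Simulation configuration
#'
#' @param n_lines number of inbred panel lines (default 156).
#' @param n_markers number of biallelic markers (default 5000 at desk scale).
#' @param maf_range minor-allele-frequency bounds in (0, 0.5]; each marker's
#'   MAF is drawn uniformly between them (equal bounds give a point mass).
#' @param n_flies_per_line flies phenotyped per line and condition
#'   (default 100).
#' @param doses Gy levels, default `c(0, 100)` (paired control/irradiated).
#' @param baseline_p Smurf probability of a non-carrier line at dose 0.
#' @param dose_effect additive shift for irradiated flies on the modelling
#'   scale (probability scale by default).
#' @param causal data.frame with columns `index`, `b_g`, `b_gxd`: planted
#'   marker main and interaction effects (NULL = global null).
#' @param line_sd standard deviation of the Gaussian per-line random effect
#'   on the modelling scale; the default 0.05 loosely matches the visual
#'   between-line spread of the published panel (a calibration, not a fit).
#' @param scale `"proportion"` (identity link with clamping to \[0, 1\]) or
#'   `"logit"` (effects are log-odds increments; inverse-logit mapping).
#' @param missing_rate fraction of genotype calls masked to NA (default 0).
#' @param vial_size if non-NULL, flies are split into vials of this size
#'   (e.g. 25) with one phenotype record per vial.
#' @param seed RNG seed; sub-streams per stage are derived deterministically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 156L, n_markers = 5000L,
                       maf_range = c(0.05, 0.5), n_flies_per_line = 100L,
                       doses = c(0, 100), baseline_p = 0.1,
                       dose_effect = 0.15, causal = NULL, line_sd = 0.05,
                       scale = c("proportion", "logit"),
                       missing_rate = 0, vial_size = NULL, seed = NULL) {
  scale <- match.arg(scale)
  if (!is_count(n_lines) || n_lines < 2) stop_radgut("n_lines must be >= 2")
  if (!is_count(n_markers) || n_markers < 1) stop_radgut("n_markers must be >= 1")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5))
    stop_radgut("maf_range bounds must lie in (0, 0.5]")
  if (maf_range[1] > maf_range[2])
    stop_radgut("degenerate maf_range: low (%g) > high (%g)",
                maf_range[1], maf_range[2])
  if (!is_count(n_flies_per_line)) stop_radgut("n_flies_per_line must be a count")
  if (length(doses) < 2 || anyDuplicated(doses) || any(doses < 0))
    stop_radgut("doses must be >= 2 distinct non-negative Gy values")
  if (baseline_p <= 0 || baseline_p >= 1)
    stop_radgut("baseline_p must lie strictly in (0, 1)")
  if (line_sd < 0) stop_radgut("line_sd must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop_radgut("missing_rate must be in [0, 1)")
  if (!is.null(causal)) {
    causal <- as.data.frame(causal)
    need <- c("index", "b_g", "b_gxd")
    if (!all(need %in% names(causal)))
      stop_radgut("causal must have columns index, b_g, b_gxd")
    if (any(causal$index < 1 | causal$index > n_markers))
      stop_radgut("causal marker index out of range 1..%d", n_markers)
  }
  structure(list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
                 maf_range = as.numeric(maf_range),
                 n_flies_per_line = as.integer(n_flies_per_line),
                 doses = as.numeric(sort(doses)), baseline_p = baseline_p,
                 dose_effect = dose_effect, causal = causal, line_sd = line_sd,
                 scale = scale, missing_rate = missing_rate,
                 vial_size = if (is.null(vial_size)) NULL else as.integer(vial_size),
                 seed = seed),
            class = "sim_config")
}

#' Simulate a DGRP-like genotype panel
#'
#' Each marker's MAF is drawn uniformly from `maf_range`; each line's call
#' is an independent Bernoulli(MAF) draw (fully inbred lines carry a single
#' homozygous 0/1 call). Marker coordinates are synthetic but well-formed
#' `chrom_pos_class` ids on the five major chromosome arms.
#'
#' @param config a [sim_config()].
#' @return list with elements `panel` (a [genotype_panel()]) and `truth`
#'   (list: per-marker `maf`, and `causal` with marker ids and planted
#'   effects).
#' @export
simulate_panel <- function(config = sim_config()) {
  M <- config$n_markers; L <- config$n_lines
  with_seed(sub_seed(config$seed, 0L), {
    maf <- stats::runif(M, config$maf_range[1], config$maf_range[2])
    calls <- matrix(stats::rbinom(M * L, 1L, rep(maf, times = L)), nrow = M)
    if (config$missing_rate > 0) {
      mask <- stats::runif(M * L) < config$missing_rate
      calls[mask] <- NA_integer_
    }
    arms <- c("2L", "2R", "3L", "3R", "X")
    chrom <- sample(arms, M, replace = TRUE)
    pos <- sample.int(25000000L, M)
    while (anyDuplicated(paste(chrom, pos))) {
      dup <- duplicated(paste(chrom, pos))
      pos[dup] <- sample.int(25000000L, sum(dup))
    }
  })
  ids <- format_marker_id(chrom, pos, rep("SNP", M))
  dimnames(calls) <- list(ids, sprintf("line_%03d", seq_len(L)))
  panel <- genotype_panel(calls)
  causal <- config$causal
  if (!is.null(causal)) causal$marker <- ids[causal$index]
  list(panel = panel,
       truth = list(maf = stats::setNames(maf, ids), causal = causal))
}

#' Simulate Smurf phenotypes over a panel
#'
#' The latent value of line `l` at dose `d` is
#' `baseline_p + dose_effect*D + sum(b_g*G + b_gxd*G*D) + a_l`, with `D` the
#' irradiation indicator (`dose > 0`), `G` the line's call at each causal
#' marker (missing calls contribute 0), and `a_l ~ N(0, line_sd)` shared
#' across doses within a line. On the proportion scale the latent value is
#' clamped to \[0, 1\] (clamp count recorded in attribute `"n_clamped"`,
#' with a warning); on the logit scale it is passed through the inverse
#' logit. Observed `n_smurf` is Binomial(n_total, probability) per record.
#'
#' @param panel a [genotype_panel()] (typically from [simulate_panel()]).
#' @param config the same [sim_config()].
#' @return A [phenotype_table()] with attributes `"truth_prob"` (line x dose
#'   matrix of realized probabilities) and `"n_clamped"`.
#' @export
simulate_phenotypes <- function(panel, config = sim_config()) {
  L <- length(panel$line_ids)
  if (L != config$n_lines)
    stop_radgut("panel has %d lines but config says %d", L, config$n_lines)
  if (config$n_flies_per_line == 0) stop_radgut("n_flies_per_line must be > 0")
  base <- if (config$scale == "logit") stats::qlogis(config$baseline_p) else config$baseline_p
  with_seed(sub_seed(config$seed, 1L), {
    line_eff <- stats::rnorm(L, 0, config$line_sd)
    gshift <- numeric(L); gxshift <- numeric(L)
    if (!is.null(config$causal)) {
      for (i in seq_len(nrow(config$causal))) {
        g <- panel$calls[config$causal$index[i], ]
        g[is.na(g)] <- 0L
        gshift <- gshift + config$causal$b_g[i] * g
        gxshift <- gxshift + config$causal$b_gxd[i] * g
      }
    }
    n_clamped <- 0L
    probs <- sapply(config$doses, function(dose) {
      D <- as.numeric(dose > 0)
      eta <- base + config$dose_effect * D + gshift + gxshift * D + line_eff
      if (config$scale == "logit") stats::plogis(eta) else {
        n_clamped <<- n_clamped + sum(eta < 0 | eta > 1)
        pmin(pmax(eta, 0), 1)
      }
    })
    probs <- matrix(probs, nrow = L,
                    dimnames = list(panel$line_ids, paste0(config$doses, "Gy")))
    recs <- list()
    for (j in seq_along(config$doses)) {
      if (is.null(config$vial_size)) {
        n_tot <- rep(config$n_flies_per_line, L)
        recs[[length(recs) + 1L]] <- data.frame(
          line_id = panel$line_ids, dose_gy = config$doses[j],
          n_total = n_tot,
          n_smurf = stats::rbinom(L, n_tot, probs[, j]),
          stringsAsFactors = FALSE)
      } else {
        n_full <- config$n_flies_per_line %/% config$vial_size
        sizes <- rep(config$vial_size, n_full)
        rem <- config$n_flies_per_line %% config$vial_size
        if (rem > 0) sizes <- c(sizes, rem)
        for (v in seq_along(sizes)) {
          recs[[length(recs) + 1L]] <- data.frame(
            line_id = panel$line_ids, dose_gy = config$doses[j],
            vial_id = sprintf("v%02d", v),
            n_total = sizes[v],
            n_smurf = stats::rbinom(L, sizes[v], probs[, j]),
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  if (n_clamped > 0)
    warning(sprintf("%d latent probabilities clamped to [0, 1]", n_clamped))
  out <- phenotype_table(do.call(rbind, recs))
  attr(out, "truth_prob") <- probs
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Simulate a complete Smurf study
#'
#' Convenience wrapper: [simulate_panel()] then [simulate_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `phenotypes`, `truth`.
#' @export
simulate_smurf_study <- function(config = sim_config()) {
  sim <- simulate_panel(config)
  phen <- simulate_phenotypes(sim$panel, config)
  sim$truth$prob <- attr(phen, "truth_prob")
  list(panel = sim$panel, phenotypes = phen, truth = sim$truth)
}

#' Simulate right-censored lifespans
#'
#' Lifespans are drawn from an exponential law (constant hazard `rate`) or a
#' two-parameter Gompertz law with hazard `rate * exp(shape * t)`, sampled
#' by the closed-form inverse CDF `t = log1p(shape/rate * E) / shape`,
#' `E ~ Exp(1)`. Flies alive at `censor_day` are right-censored there.
#'
#' @param n_per_group named integer vector: subjects per group.
#' @param rate per-group hazard rate (scalar recycled, or named like
#'   `n_per_group`).
#' @param shape Gompertz shape (ignored for exponential).
#' @param law `"exponential"` or `"gompertz"`.
#' @param censor_day end of study (default Inf = no censoring).
#' @param seed RNG seed.
#' @return A [survival_table()].
#' @export
simulate_survival <- function(n_per_group, rate, shape = 0.1,
                              law = c("exponential", "gompertz"),
                              censor_day = Inf, seed = NULL) {
  law <- match.arg(law)
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("group", seq_along(n_per_group))
  if (any(n_per_group < 1)) stop_radgut("group sizes must be positive")
  if (length(rate) == 1) rate <- stats::setNames(rep(rate, length(n_per_group)),
                                                 names(n_per_group))
  if (any(rate <= 0)) stop_radgut("hazard rates must be positive")
  with_seed(sub_seed(seed, 2L), {
    recs <- lapply(names(n_per_group), function(g) {
      n <- n_per_group[[g]]
      t <- if (law == "exponential") stats::rexp(n, rate[[g]])
           else log1p(shape / rate[[g]] * stats::rexp(n)) / shape
      event <- t <= censor_day
      data.frame(group = g, time = pmin(t, censor_day),
                 event = as.integer(event), stringsAsFactors = FALSE)
    })
  })
  survival_table(do.call(rbind, recs))
}

# ---------------------------------------------------------------------------
# Synthetic 3'UTRs with planted MBE motifs

# One concrete realization of the consensus (G/A)U(1-3)AGU.
random_mbe_instance <- function() {
  paste0(sample(c("G", "A"), 1L), strrep("U", sample.int(3L, 1L)), "AGU")
}

#' Simulate 3'UTR sequences with an exact planted motif count
#'
#' Backgrounds are uniform over `{A, C, G, U}` and rejected until they hold
#' zero matches of the motif pattern; planted instances are then written at
#' non-overlapping random offsets and the whole sequence re-scanned, with
#' rejection of any accidental extra or merged match — so the truth count is
#' exact by construction under the greedy counting policy.
#'
#' @param n_genes number of sequences.
#' @param length_nt sequence length in nucleotides (scalar, recycled).
#' @param planted_counts motifs per gene (recycled over genes).
#' @param config an [mbe_config()]; the pattern being planted and counted.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling cap per gene.
#' @return list with `utrs` (a [utr_set()]) and `truth` (named planted
#'   counts).
#' @export
simulate_utrs <- function(n_genes, length_nt = 300L, planted_counts = 0L,
                          config = mbe_config(), seed = NULL,
                          max_tries = 2000L) {
  if (!is_count(n_genes) || n_genes < 1) stop_radgut("n_genes must be >= 1")
  lens <- rep_len(as.integer(length_nt), n_genes)
  counts <- rep_len(as.integer(planted_counts), n_genes)
  if (any(lens < 1)) stop_radgut("length_nt must be positive")
  if (any(counts * 6L > lens))
    stop_radgut("planted motifs cannot fit: gene %d needs %d nt in %d",
                which(counts * 6L > lens)[1L], counts[which(counts * 6L > lens)[1L]] * 6L,
                lens[which(counts * 6L > lens)[1L]])
  with_seed(sub_seed(seed, 3L), {
    seqs <- character(n_genes)
    for (i in seq_len(n_genes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- paste(sample(c("A", "C", "G", "U"), lens[i], replace = TRUE),
                   collapse = "")
        if (nrow(find_mbe_sites(s, config)) != 0L) next
        if (counts[i] > 0L) {
          motifs <- replicate(counts[i], random_mbe_instance())
          ml <- nchar(motifs)
          starts <- integer(0)
          placed <- TRUE
          occupied <- logical(lens[i])
          for (k in seq_len(counts[i])) {
            cand <- which(!occupied[seq_len(lens[i] - ml[k] + 1L)])
            cand <- cand[vapply(cand, function(st)
              !any(occupied[st:(st + ml[k] - 1L)]), logical(1))]
            if (!length(cand)) { placed <- FALSE; break }
            st <- cand[sample.int(length(cand), 1L)]
            occupied[st:(st + ml[k] - 1L)] <- TRUE
            substr(s, st, st + ml[k] - 1L) <- motifs[k]
          }
          if (!placed) next
        }
        if (nrow(find_mbe_sites(s, config)) == counts[i]) { ok <- TRUE; break }
      }
      if (!ok)
        stop_radgut("failed to plant exactly %d motif(s) in %d nt after %d tries",
                    counts[i], lens[i], max_tries)
      seqs[i] <- s
    }
  })
  names(seqs) <- sprintf("gene_%03d", seq_len(n_genes))
  list(utrs = utr_set(seqs), truth = stats::setNames(counts, names(seqs)))
}
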