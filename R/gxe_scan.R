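# Genotype x irradiation-dose association scan.
#
# Per marker, the Smurf phenotype is regressed on the linear model
#
#   phenotype = beta0 + beta1*Genotype + beta2*Dose + beta3*Genotype*Dose
#
# by ordinary least squares; the interaction term beta3 captures the
# dose-dependent portion of the genetic effect and is the tested term by
# default. With binary genotype (inbred homozygous lines) and binary dose
# the design is a saturated 2x2 cell-means model, which admits a closed-form
# fit that vectorises across all markers at once; a general QR path handles
# every other configuration and serves as the reference implementation.

#' Scan configuration
#'
#' @param maf_min minor-allele-frequency threshold; markers are retained when
#'   MAF is *strictly* greater than this (default 0.25, i.e. "> 25%").
#' @param dose_coding `"binary"` codes dose as 0 (unirradiated) / 1 (any
#'   positive Gy); `"gray"` uses raw Gy, for staggered-dose designs.
#' @param response `"proportion"` regresses the raw Smurf proportion;
#'   `"logit_proportion"` applies a logit with the Haldane–Anscombe 0.5
#'   correction to guard 0% and 100% vials.
#' @param tested_term which coefficient's p-value the scan reports:
#'   `"interaction"` (default), `"genotype"`, or `"dose"`.
#' @param min_lines_per_cell minimum distinct observations required in each
#'   genotype x dose cell for a non-degenerate fit (default 3).
#' @param pool_vials pool per-vial counts into one record per line x dose
#'   before fitting (default TRUE); FALSE keeps vials as replicates.
#' @param reorient verify the empirical frequency of allele 1 and flip
#'   markers where it exceeds 0.5, with a warning (default TRUE). Flipping
#'   negates `beta1` and `beta3` but leaves p-values unchanged; flipped
#'   markers are flagged in the result.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(maf_min = 0.25,
                        dose_coding = c("binary", "gray"),
                        response = c("proportion", "logit_proportion"),
                        tested_term = c("interaction", "genotype", "dose"),
                        min_lines_per_cell = 3L,
                        pool_vials = TRUE,
                        reorient = TRUE) {
  dose_coding <- match.arg(dose_coding)
  response <- match.arg(response)
  tested_term <- match.arg(tested_term)
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min >= 0.5)
    stop_radgut("maf_min must lie in [0, 0.5)")
  if (!is_count(min_lines_per_cell) || min_lines_per_cell < 1)
    stop_radgut("min_lines_per_cell must be a positive count")
  structure(list(maf_min = maf_min, dose_coding = dose_coding,
                 response = response, tested_term = tested_term,
                 min_lines_per_cell = as.integer(min_lines_per_cell),
                 pool_vials = pool_vials, reorient = reorient),
            class = "scan_config")
}

#' Minor allele frequency of a call vector
#'
#' Frequency of the rarer allele among non-missing calls; missing calls are
#' excluded from the denominator. Symmetric under 0/1 label swap, so the
#' result always lies in `[0, 0.5]`.
#'
#' @param calls vector of 0/1/NA calls.
#' @return MAF in `[0, 0.5]`.
#' @examples
#' minor_allele_frequency(c(0, 0, 0, 1))   # 0.25
#' minor_allele_frequency(c(0, 1, NA, NA)) # 0.5
#' @export
minor_allele_frequency <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0)
    stop_radgut("minor allele frequency undefined: all calls missing")
  if (!all(calls %in% c(0, 1)))
    stop_radgut("calls must be 0, 1 or NA")
  f <- mean(calls == 1)
  min(f, 1 - f)
}

# Row-wise MAF for a call matrix; NaN for all-missing rows.
row_maf <- function(calls) {
  f1 <- rowMeans(calls == 1L, na.rm = TRUE)
  pmin(f1, 1 - f1)
}

#' Filter panel markers by minor allele frequency
#'
#' Retains exactly the markers whose MAF (computed among non-missing calls)
#' is strictly greater than `maf_min`; marker order is preserved. All-missing
#' markers are dropped with a warning. An empty result is allowed.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min threshold (strict `>`).
#' @return Filtered `genotype_panel`.
#' @export
filter_markers <- function(panel, maf_min = 0.25) {
  maf <- row_maf(panel$calls)
  all_missing <- is.nan(maf)
  if (any(all_missing)) {
    warning(sprintf("dropping %d marker(s) with all calls missing", sum(all_missing)))
    maf[all_missing] <- -Inf
  }
  panel[maf > maf_min, ]
}

# ---------------------------------------------------------------------------
# Response construction

# Returns data.frame(line, d, y): one row per observation, with dose coded
# per config and the response on the requested scale.
build_response <- function(phen, config) {
  phen <- phenotype_table(as.data.frame(phen))
  if (length(unique(phen$dose_gy)) < 2)
    stop_radgut("at least two distinct dose levels are required for a scan")
  d <- if (config$dose_coding == "binary") as.numeric(phen$dose_gy > 0)
       else as.numeric(phen$dose_gy)
  if (config$pool_vials) {
    key <- paste(phen$line_id, d, sep = "\r")
    s <- rowsum(phen$n_smurf, key)
    n <- rowsum(phen$n_total, key)
    parts <- strsplit(rownames(s), "\r", fixed = TRUE)
    line <- vapply(parts, `[`, character(1), 1L)
    dd <- as.numeric(vapply(parts, `[`, character(1), 2L))
    s <- s[, 1L]; n <- n[, 1L]
  } else {
    line <- phen$line_id; dd <- d; s <- phen$n_smurf; n <- phen$n_total
  }
  y <- if (config$response == "logit_proportion")
    log((s + 0.5) / (n - s + 0.5)) else s / n
  data.frame(line = line, d = dd, y = as.numeric(y), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Single-marker fit (general QR path)

#' Fit the genotype-by-dose model for one marker
#'
#' Ordinary least squares of the response on `[1, G, D, G*D]`. Observations
#' from lines with a missing call are dropped for this marker only. Standard
#' errors use the residual variance on `n_obs - 4` degrees of freedom;
#' two-sided p-values come from the Student-t distribution. The fit is
#' flagged degenerate (p undefined) when the design is rank-deficient, the
#' residual variance is zero, or a genotype x dose cell holds fewer
#' observations than `min_lines_per_cell`.
#'
#' @param calls named vector of 0/1/NA calls, names = line ids.
#' @param phen a [phenotype_table()].
#' @param config a [scan_config()].
#' @return A list of class `marker_fit` with elements `n_obs`, `df`,
#'   `coefficients`, `se`, `t`, `p_values` (all named `intercept`,
#'   `genotype`, `dose`, `interaction`), `p` (tested term) and `degenerate`.
#' @export
fit_marker_model <- function(calls, phen, config = scan_config()) {
  if (is.null(names(calls))) stop_radgut("calls must be named by line id")
  resp <- build_response(phen, config)
  g <- as.numeric(calls[resp$line])
  keep <- !is.na(g)
  fit_ols(g[keep], resp$d[keep], resp$y[keep], config)
}

term_names <- c("intercept", "genotype", "dose", "interaction")

fit_ols <- function(g, d, y, config) {
  n <- length(y)
  if (n < 5)
    stop_radgut("insufficient data: %d usable observations (need >= 5 for df >= 1)", n)
  X <- cbind(1, g, d, g * d)
  fit <- stats::lm.fit(X, y)
  rank <- fit$rank
  coef <- stats::setNames(fit$coefficients, term_names)
  out <- list(n_obs = n, df = n - 4L,
              coefficients = coef,
              se = stats::setNames(rep(NA_real_, 4), term_names),
              t = stats::setNames(rep(NA_real_, 4), term_names),
              p_values = stats::setNames(rep(NA_real_, 4), term_names),
              degenerate = FALSE)
  class(out) <- "marker_fit"
  cell_ok <- TRUE
  if (all(g %in% c(0, 1)) && length(unique(d)) == 2) {
    counts <- table(factor(g, levels = c(0, 1)), factor(d))
    cell_ok <- all(counts >= config$min_lines_per_cell)
  }
  if (rank < 4L) {
    out$degenerate <- TRUE
    out$p <- NA_real_
    return(out)
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - 4)
  if (rss <= 1e-12 * max(1, mean(y^2)) || !cell_ok) {
    out$degenerate <- TRUE
    if (rss <= 1e-12 * max(1, mean(y^2)))
      out$se <- stats::setNames(rep(0, 4), term_names)
    out$p <- NA_real_
    return(out)
  }
  R <- qr.R(fit$qr)
  cov_piv <- chol2inv(R)
  se <- numeric(4)
  se[fit$qr$pivot] <- sqrt(diag(cov_piv) * sigma2)
  out$se <- stats::setNames(se, term_names)
  out$t <- out$coefficients / out$se
  out$p_values <- 2 * stats::pt(abs(out$t), df = n - 4, lower.tail = FALSE)
  out$p <- unname(out$p_values[config$tested_term])
  out
}

#' @export
print.marker_fit <- function(x, ...) {
  cat(sprintf("marker_fit: n_obs = %d, df = %d%s\n", x$n_obs, x$df,
              if (x$degenerate) " (degenerate)" else ""))
  print(data.frame(beta = x$coefficients, se = x$se, t = x$t, p = x$p_values))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Panel-wide scan

#' Genotype-by-dose association scan over a panel
#'
#' Applies the MAF filter, optionally re-orients markers whose allele-1
#' frequency exceeds 0.5, and fits the interaction model to every retained
#' marker. With binary dose coding the saturated cell-means closed form is
#' used (vectorised over markers); it is algebraically identical to the QR
#' fit of [fit_marker_model()].
#'
#' @param panel a [genotype_panel()].
#' @param phen a [phenotype_table()]; line ids must overlap the panel in at
#'   least 5 lines.
#' @param config a [scan_config()].
#' @return A data.frame of class `gxe_scan`, one row per retained marker,
#'   with coefficients, standard errors, t and p for all four terms, the
#'   tested-term p-value in column `p`, MAF, orientation flag, and a
#'   `degenerate` flag. The configuration is attached as attribute
#'   `"config"`.
#' @export
gxe_scan <- function(panel, phen, config = scan_config()) {
  if (!inherits(panel, "genotype_panel")) stop_radgut("panel must be a genotype_panel")
  phen <- phenotype_table(as.data.frame(phen))
  common <- intersect(panel$line_ids, unique(phen$line_id))
  if (length(common) == 0)
    stop_radgut(paste0("no overlapping line ids between panel and phenotypes; ",
                       "panel-only: %s; phenotype-only: %s"),
                paste(utils::head(setdiff(panel$line_ids, phen$line_id), 5), collapse = ","),
                paste(utils::head(setdiff(unique(phen$line_id), panel$line_ids), 5), collapse = ","))
  if (length(common) < 5)
    stop_radgut("only %d overlapping lines between panel and phenotypes (need >= 5)",
                length(common))
  panel <- panel[, common]
  panel <- filter_markers(panel, config$maf_min)
  calls <- panel$calls
  M <- nrow(calls)
  resp <- build_response(phen[phen$line_id %in% common, , drop = FALSE], config)

  flipped <- logical(M)
  if (M > 0 && config$reorient) {
    f1 <- rowMeans(calls == 1L, na.rm = TRUE)
    flipped <- f1 > 0.5
    if (any(flipped)) {
      calls[flipped, ] <- 1L - calls[flipped, ]
      warning(sprintf("re-oriented %d marker(s) whose call-1 frequency exceeded 0.5",
                      sum(flipped)))
    }
  }

  if (M == 0) {
    res <- empty_scan_frame()
  } else if (config$dose_coding == "binary" && length(unique(resp$d)) == 2) {
    res <- scan_cellmeans(calls, resp, panel$line_ids, config)
  } else {
    res <- do.call(rbind, lapply(seq_len(M), function(i) {
      fit <- tryCatch(
        fit_marker_model(stats::setNames(calls[i, ], colnames(calls)), phen, config),
        radgut_error = function(e) NULL)
      fit_to_row(fit)
    }))
  }
  out <- cbind(panel$markers, maf = if (M) row_maf(panel$calls) else numeric(0),
               flipped = flipped, res, row.names = NULL)
  attr(out, "config") <- config
  class(out) <- c("gxe_scan", "data.frame")
  out
}

empty_scan_frame <- function() {
  data.frame(n_obs = integer(0), df = integer(0),
             beta_intercept = numeric(0), beta_genotype = numeric(0),
             beta_dose = numeric(0), beta_interaction = numeric(0),
             se_intercept = numeric(0), se_genotype = numeric(0),
             se_dose = numeric(0), se_interaction = numeric(0),
             t_intercept = numeric(0), t_genotype = numeric(0),
             t_dose = numeric(0), t_interaction = numeric(0),
             p_intercept = numeric(0), p_genotype = numeric(0),
             p_dose = numeric(0), p_interaction = numeric(0),
             p = numeric(0), degenerate = logical(0))
}

fit_to_row <- function(fit) {
  if (is.null(fit)) {
    row <- empty_scan_frame()[NA_integer_, , drop = FALSE]
    row$degenerate <- TRUE
    rownames(row) <- NULL
    return(row)
  }
  data.frame(n_obs = fit$n_obs, df = fit$df,
             beta_intercept = fit$coefficients[["intercept"]],
             beta_genotype = fit$coefficients[["genotype"]],
             beta_dose = fit$coefficients[["dose"]],
             beta_interaction = fit$coefficients[["interaction"]],
             se_intercept = fit$se[["intercept"]],
             se_genotype = fit$se[["genotype"]],
             se_dose = fit$se[["dose"]],
             se_interaction = fit$se[["interaction"]],
             t_intercept = fit$t[["intercept"]],
             t_genotype = fit$t[["genotype"]],
             t_dose = fit$t[["dose"]],
             t_interaction = fit$t[["interaction"]],
             p_intercept = fit$p_values[["intercept"]],
             p_genotype = fit$p_values[["genotype"]],
             p_dose = fit$p_values[["dose"]],
             p_interaction = fit$p_values[["interaction"]],
             p = if (fit$degenerate) NA_real_ else fit$p,
             degenerate = fit$degenerate)
}

# Vectorised saturated 2x2 fit. For the cell-means parameterisation the OLS
# solution is exact: beta0 = m00, beta1 = m10 - m00, beta2 = m01 - m00,
# beta3 = m11 - m10 - m01 + m00, with Var(beta) = sigma2 * (sums of inverse
# cell counts) and sigma2 the pooled within-cell variance on n - 4 df.
scan_cellmeans <- function(calls, resp, line_ids, config) {
  L <- length(line_ids)
  dl <- sort(unique(resp$d))
  per_dose <- lapply(dl, function(dv) {
    r <- resp[resp$d == dv, , drop = FALSE]
    idx <- match(r$line, line_ids)
    m <- tabulate(idx, nbins = L)
    s <- ss <- numeric(L)
    t1 <- rowsum(r$y, idx); s[as.integer(rownames(t1))] <- t1[, 1L]
    t2 <- rowsum(r$y^2, idx); ss[as.integer(rownames(t2))] <- t2[, 1L]
    list(m = m, s = s, ss = ss)
  })
  C1 <- calls == 1L; C1[is.na(C1)] <- FALSE; mode(C1) <- "numeric"
  C0 <- calls == 0L; C0[is.na(C0)] <- FALSE; mode(C0) <- "numeric"
  cell <- function(C, a) list(n = drop(C %*% a$m), s = drop(C %*% a$s),
                              ss = drop(C %*% a$ss),
                              l = drop(C %*% as.numeric(a$m > 0)))
  c00 <- cell(C0, per_dose[[1L]]); c01 <- cell(C0, per_dose[[2L]])
  c10 <- cell(C1, per_dose[[1L]]); c11 <- cell(C1, per_dose[[2L]])

  n_obs <- c00$n + c01$n + c10$n + c11$n
  dfree <- n_obs - 4
  any_empty <- c00$n == 0 | c01$n == 0 | c10$n == 0 | c11$n == 0
  mu <- function(cc) ifelse(cc$n > 0, cc$s / cc$n, NA_real_)
  m00 <- mu(c00); m01 <- mu(c01); m10 <- mu(c10); m11 <- mu(c11)
  b0 <- m00
  b1 <- m10 - m00
  b2 <- m01 - m00
  b3 <- m11 - m10 - m01 + m00
  wss <- function(cc) ifelse(cc$n > 0, cc$ss - cc$s^2 / pmax(cc$n, 1), 0)
  rss <- wss(c00) + wss(c01) + wss(c10) + wss(c11)
  ysq <- (c00$ss + c01$ss + c10$ss + c11$ss) / pmax(n_obs, 1)
  sigma2 <- ifelse(dfree > 0, rss / dfree, NA_real_)
  zero_var <- rss <= 1e-12 * pmax(1, ysq)
  cell_small <- c00$l < config$min_lines_per_cell | c01$l < config$min_lines_per_cell |
    c10$l < config$min_lines_per_cell | c11$l < config$min_lines_per_cell
  degenerate <- any_empty | dfree < 1 | zero_var | cell_small

  iv <- function(cc) ifelse(cc$n > 0, 1 / cc$n, NA_real_)
  v0 <- iv(c00)
  v1 <- iv(c00) + iv(c10)
  v2 <- iv(c00) + iv(c01)
  v3 <- iv(c00) + iv(c01) + iv(c10) + iv(c11)
  se0 <- sqrt(sigma2 * v0); se1 <- sqrt(sigma2 * v1)
  se2 <- sqrt(sigma2 * v2); se3 <- sqrt(sigma2 * v3)
  tt <- function(b, se) ifelse(degenerate, NA_real_, b / se)
  t0 <- tt(b0, se0); t1 <- tt(b1, se1); t2 <- tt(b2, se2); t3 <- tt(b3, se3)
  pv <- function(t) 2 * stats::pt(abs(t), df = pmax(dfree, 1), lower.tail = FALSE)
  p0 <- pv(t0); p1 <- pv(t1); p2 <- pv(t2); p3 <- pv(t3)
  p_test <- switch(config$tested_term, interaction = p3, genotype = p1, dose = p2)
  data.frame(n_obs = as.integer(n_obs), df = as.integer(dfree),
             beta_intercept = b0, beta_genotype = b1, beta_dose = b2,
             beta_interaction = b3,
             se_intercept = se0, se_genotype = se1, se_dose = se2,
             se_interaction = se3,
             t_intercept = t0, t_genotype = t1, t_dose = t2, t_interaction = t3,
             p_intercept = p0, p_genotype = p1, p_dose = p2, p_interaction = p3,
             p = p_test, degenerate = degenerate)
}

#' @export
print.gxe_scan <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("gxe_scan: %d markers (tested term: %s, MAF > %g)\n",
              nrow(x), cfg$tested_term, cfg$maf_min))
  if (nrow(x)) {
    top <- x[order(x$p), c("marker", "beta_interaction", "p")]
    print(utils::head(as.data.frame(top), 5), row.names = FALSE)
  }
  invisible(x)
}
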