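# Shared fixtures and independent oracles, all built in code.

# Small genotype panel: markers x lines matrix with explicit calls.
toy_panel <- function(calls, line_ids = NULL, chrom = "2L") {
  if (is.null(line_ids)) line_ids <- sprintf("line_%02d", seq_len(ncol(calls)))
  ids <- sprintf("%s_%d_SNP", chrom, seq_len(nrow(calls)) * 1000L)
  dimnames(calls) <- list(ids, line_ids)
  genotype_panel(calls)
}

# Paired-dose phenotype table from per-line Smurf counts.
toy_phen <- function(line_ids, smurf0, smurf100, n_total = 100L) {
  phenotype_table(data.frame(
    line_id = rep(line_ids, 2),
    dose_gy = rep(c(0, 100), each = length(line_ids)),
    n_total = n_total,
    n_smurf = c(smurf0, smurf100)))
}

# Independent OLS oracle: explicit normal equations, with p-values from
# numeric integration of the t density (no pt()).
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- drop(beta) / se
  p <- vapply(tval, function(tt)
    2 * stats::integrate(function(u) stats::dt(u, df), lower = abs(tt),
                         upper = Inf, rel.tol = 1e-12)$value, numeric(1))
  list(beta = drop(beta), se = se, t = tval, p = p, df = df)
}

# Brute-force SSE minimisation oracle (quasi-Newton with analytic gradient).
ols_sse_oracle <- function(X, y) {
  sse <- function(b) sum((y - X %*% b)^2)
  grad <- function(b) drop(-2 * crossprod(X, y - X %*% b))
  stats::optim(rep(0, ncol(X)), sse, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))$par
}

# Random genotype-by-dose dataset with at least min_cell observations per
# 2x2 cell; returns a phenotype-style response plus design vectors.
random_cell_dataset <- function(n_per_cell) {
  g <- rep(c(0, 0, 1, 1), n_per_cell)
  d <- rep(c(0, 1, 0, 1), n_per_cell)
  y <- 0.1 + 0.05 * g + 0.1 * d + 0.08 * g * d + rnorm(length(g), 0, 0.05)
  list(g = g, d = d, y = y, X = cbind(1, g, d, g * d))
}

# All permutations of a vector (small n).
perms_of <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- perms_of(v[-i])
    out <- rbind(out, cbind(v[i], sub, deparse.level = 0))
  }
  out
}

# Canonical string form of a phenotype table (line-block assignment),
# independent of row order.
phen_signature <- function(phen) {
  df <- as.data.frame(phen)
  df <- df[order(df$line_id, df$dose_gy), ]
  paste(sprintf("%s:%g:%d:%d", df$line_id, df$dose_gy, df$n_total, df$n_smurf),
        collapse = "|")
}

# Global-null study configuration used by the calibration checks: panel of
# 156 inbred lines, common markers (MAF drawn in 0.3-0.5 so virtually all
# pass the >25% filter), pure binomial phenotype noise.
null_study <- function(seed, n_markers = 2000L) {
  simulate_smurf_study(sim_config(
    n_lines = 156L, n_markers = n_markers, maf_range = c(0.3, 0.5),
    n_flies_per_line = 100L, baseline_p = 0.1, dose_effect = 0.15,
    line_sd = 0, seed = seed))
}
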