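test_that("minor allele frequency folds labels and excludes missing calls", {
  expect_equal(minor_allele_frequency(c(0, 0, 0, 1)), 0.25)
  expect_equal(minor_allele_frequency(c(1, 1, 1, 0)), 0.25)
  expect_equal(minor_allele_frequency(c(0, 1, NA, NA)), 0.5)
  expect_error(minor_allele_frequency(c(NA, NA)), "all calls missing")
})

test_that("MAF filter is strict and order-preserving", {
  calls <- rbind(c(0L, 0L, 0L, 1L),   # MAF exactly 0.25
                 c(0L, 0L, 0L, 0L),   # monomorphic
                 c(0L, 0L, 1L, 1L),   # MAF 0.5
                 c(1L, 1L, 1L, 0L))   # MAF 0.25 after folding
  panel <- toy_panel(calls)
  ids <- rownames(panel$calls)
  kept <- filter_markers(panel, 0.25)
  expect_identical(rownames(kept$calls), ids[3L])
  all_poly <- filter_markers(panel, 0)
  expect_identical(rownames(all_poly$calls), ids[c(1, 3, 4)])
  expect_equal(nrow(filter_markers(panel, 0.49)$calls), 1L)
})

test_that("saturated cell-means identity recovers exact coefficients", {
  # cells (G,D) = (0,0):0.1  (0,1):0.3  (1,0):0.1  (1,1):0.6
  lines <- sprintf("l%02d", 1:12)
  g <- rep(c(0L, 1L), each = 6)
  phen <- toy_phen(lines, smurf0 = rep(10L, 12),
                   smurf100 = c(rep(30L, 6), rep(60L, 6)), n_total = 100L)
  fit <- fit_marker_model(setNames(g, lines), phen)
  expect_equal(unname(fit$coefficients), c(0.1, 0, 0.2, 0.3), tolerance = 1e-12)
  expect_true(fit$degenerate)   # zero residual variance: p undefined
  expect_true(all(is.na(fit$p_values)))

  # same cell means with within-cell spread: exact betas, finite p
  phen2 <- toy_phen(lines,
                    smurf0 = rep(c(8L, 12L), 6),
                    smurf100 = c(rep(c(28L, 32L), 3), rep(c(58L, 62L), 3)))
  fit2 <- fit_marker_model(setNames(g, lines), phen2)
  expect_equal(unname(fit2$coefficients), c(0.1, 0, 0.2, 0.3), tolerance = 1e-12)
  expect_false(fit2$degenerate)
  expect_true(all(fit2$p_values >= 0 & fit2$p_values <= 1))
})

test_that("constant response yields zero slopes and a degenerate fit", {
  lines <- sprintf("l%02d", 1:10)
  phen <- toy_phen(lines, rep(20L, 10), rep(20L, 10))
  fit <- fit_marker_model(setNames(rep(c(0L, 1L), 5), lines), phen)
  expect_equal(unname(fit$coefficients), c(0.2, 0, 0, 0), tolerance = 1e-12)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$p))
})

test_that("single fit matches the normal-equation and t-tail oracles", {
  set.seed(101)
  lines <- sprintf("l%02d", seq_len(6))
  g <- rep(c(0L, 1L), each = 3)
  y0 <- round(100 * (0.1 + 0.05 * g + rnorm(6, 0, 0.03)))
  y1 <- round(100 * (0.2 + 0.13 * g + rnorm(6, 0, 0.03)))
  phen <- toy_phen(lines, y0, y1)
  fit <- fit_marker_model(setNames(g, lines), phen)
  X <- cbind(1, rep(g, 2), rep(c(0, 1), each = 6), rep(g, 2) * rep(c(0, 1), each = 6))
  oracle <- ols_oracle(X, c(y0, y1) / 100)
  expect_equal(unname(fit$coefficients), unname(oracle$beta), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
  expect_equal(unname(fit$p_values), unname(oracle$p), tolerance = 1e-8)
})

test_that("closed-form least squares agrees with brute-force SSE minimisation", {
  set.seed(202)
  for (r in 1:20) {
    ds <- random_cell_dataset(sample(3:8, 1))
    beta_opt <- ols_sse_oracle(ds$X, ds$y)
    beta_ne <- unname(drop(solve(crossprod(ds$X), crossprod(ds$X, ds$y))))
    expect_equal(beta_ne, beta_opt, tolerance = 1e-6)
  }
})

test_that("vectorised scan equals the per-marker QR fit on every field", {
  set.seed(303)
  calls <- matrix(rbinom(30 * 16, 1, runif(30, 0.2, 0.5)), nrow = 30)
  calls[sample(length(calls), 20)] <- NA
  panel <- toy_panel(calls)
  phen <- toy_phen(panel$line_ids, rbinom(16, 100, 0.1), rbinom(16, 100, 0.3))
  cfg <- scan_config(maf_min = 0.1, reorient = FALSE)
  sc <- suppressWarnings(gxe_scan(panel, phen, cfg))
  for (i in seq_len(nrow(sc))) {
    cl <- setNames(panel$calls[match(sc$marker[i], rownames(panel$calls)), ],
                   panel$line_ids)
    fit <- tryCatch(fit_marker_model(cl, phen, cfg), error = function(e) NULL)
    if (is.null(fit)) next
    expect_equal(unname(fit$coefficients),
                 unname(unlist(sc[i, c("beta_intercept", "beta_genotype",
                                       "beta_dose", "beta_interaction")])),
                 tolerance = 1e-10)
    expect_equal(fit$degenerate, sc$degenerate[i])
    if (!fit$degenerate) {
      expect_equal(unname(fit$se),
                   unname(unlist(sc[i, c("se_intercept", "se_genotype",
                                         "se_dose", "se_interaction")])),
                   tolerance = 1e-10)
      expect_equal(fit$p, sc$p[i], tolerance = 1e-10)
    }
  }
})

test_that("scan is invariant to marker order and observation row order", {
  set.seed(404)
  calls <- matrix(rbinom(20 * 12, 1, 0.4), nrow = 20)
  panel <- toy_panel(calls)
  phen <- toy_phen(panel$line_ids, rbinom(12, 100, 0.1), rbinom(12, 100, 0.3))
  cfg <- scan_config(maf_min = 0)
  sc <- suppressWarnings(gxe_scan(panel, phen, cfg))

  perm <- sample(nrow(calls))
  sc_perm <- suppressWarnings(gxe_scan(panel[perm, ], phen, cfg))
  expect_equal(as.data.frame(sc_perm), as.data.frame(sc)[match(sc_perm$marker, sc$marker), ],
               ignore_attr = TRUE)

  phen_shuf <- phenotype_table(as.data.frame(phen)[sample(nrow(phen)), ])
  sc_shuf <- suppressWarnings(gxe_scan(panel, phen_shuf, cfg))
  expect_equal(as.data.frame(sc_shuf), as.data.frame(sc), ignore_attr = TRUE)
})

test_that("a strongly planted interaction marker attains the minimum p", {
  hits <- 0L
  for (r in 1:20) {
    cfg <- sim_config(n_lines = 80, n_markers = 150, maf_range = c(0.3, 0.45),
                      causal = data.frame(index = 42, b_g = 0.02, b_gxd = 0.2),
                      line_sd = 0, seed = 7000 + r)
    st <- simulate_smurf_study(cfg)
    sc <- suppressWarnings(gxe_scan(st$panel, st$phenotypes))
    top <- sc$marker[which.min(sc$p)]
    if (identical(top, st$truth$causal$marker)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("markers are re-oriented when call 1 is the major allele", {
  set.seed(505)
  calls <- matrix(rbinom(6 * 12, 1, 0.8), nrow = 6)  # allele 1 is major
  panel <- toy_panel(calls)
  phen <- toy_phen(panel$line_ids, rbinom(12, 100, 0.1), rbinom(12, 100, 0.3))
  cfg <- scan_config(maf_min = 0)
  expect_warning(sc <- gxe_scan(panel, phen, cfg), "re-oriented")
  expect_true(all(sc$flipped))
  # flipping is equivalent to scanning the manually recoded panel
  panel_flip <- toy_panel(1L - calls)
  sc_manual <- gxe_scan(panel_flip, phen,
                        scan_config(maf_min = 0, reorient = FALSE))
  expect_equal(sc$beta_interaction, sc_manual$beta_interaction, tolerance = 1e-12)
  expect_equal(sc$p, sc_manual$p, tolerance = 1e-12)
  # p unchanged by orientation; interaction coefficient negated
  sc_raw <- gxe_scan(panel, phen, scan_config(maf_min = 0, reorient = FALSE))
  expect_equal(sc$p, sc_raw$p, tolerance = 1e-12)
  expect_equal(sc$beta_interaction, -sc_raw$beta_interaction, tolerance = 1e-12)
})

test_that("logit response guards 0% and 100% vials and scan contracts hold", {
  lines <- sprintf("l%02d", 1:10)
  phen <- toy_phen(lines, smurf0 = rep(0L, 10), smurf100 = rep(100L, 10))
  g <- setNames(rep(c(0L, 1L), 5), lines)
  fit <- fit_marker_model(g, phen, scan_config(response = "logit_proportion"))
  expect_true(all(is.finite(fit$coefficients)))

  calls <- matrix(rep(c(0L, 1L), each = 5), nrow = 1)
  panel <- toy_panel(calls, line_ids = sprintf("other_%d", 1:10))
  expect_error(gxe_scan(panel, phen), "no overlapping line ids")

  # all markers below the MAF threshold: empty result, no error
  mono <- toy_panel(matrix(0L, nrow = 3, ncol = 10), line_ids = lines)
  sc <- gxe_scan(mono, phen)
  expect_equal(nrow(sc), 0L)

  # a single dose level cannot support the model
  one_dose <- phenotype_table(data.frame(line_id = lines, dose_gy = 100,
                                         n_total = 100, n_smurf = 10))
  pan <- toy_panel(matrix(rep(c(0L, 1L), each = 5), nrow = 1), line_ids = lines)
  expect_error(gxe_scan(pan, one_dose), "two distinct dose levels")
})
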