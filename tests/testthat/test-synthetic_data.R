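test_that("panel simulation is seed-reproducible with the stated shape and alphabet", {
  cfg <- sim_config(n_lines = 156, n_markers = 100, seed = 7)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$calls, b$panel$calls)
  expect_identical(a$truth$maf, b$truth$maf)
  expect_equal(dim(a$panel$calls), c(100L, 156L))
  expect_true(all(a$panel$calls %in% c(0L, 1L)))

  # default line_sd can push a few latent values past the bounds; the clamp
  # warning is part of the generator's contract
  ph1 <- suppressWarnings(simulate_phenotypes(a$panel, cfg))
  ph2 <- suppressWarnings(simulate_phenotypes(b$panel, cfg))
  expect_identical(as.data.frame(ph1), as.data.frame(ph2))
})

test_that("point-mass maf_range concentrates empirical MAFs at the target", {
  # binomial sampling oracle: per-marker empirical MAF has SE
  # sqrt(p(1-p)/L); the mean over M markers has SE/sqrt(M)
  L <- 500L; M <- 400L
  sim <- simulate_panel(sim_config(n_lines = L, n_markers = M,
                                   maf_range = c(0.3, 0.3), seed = 21))
  emp <- rowMeans(sim$panel$calls == 1L)
  se_line <- sqrt(0.3 * 0.7 / L)
  expect_lt(abs(mean(emp) - 0.3), 3 * se_line / sqrt(M))
  expect_true(all(abs(emp - 0.3) < 5 * se_line))
})

test_that("config contract violations are rejected", {
  expect_error(sim_config(maf_range = c(0.4, 0.3)), "degenerate maf_range")
  expect_error(sim_config(maf_range = c(0, 0.3)), "\\(0, 0.5\\]")
  expect_error(sim_config(baseline_p = 0), "baseline_p")
  expect_error(sim_config(causal = data.frame(index = 50, b_g = 0, b_gxd = 0),
                          n_markers = 10), "out of range")
  cfg <- sim_config(n_lines = 10, n_markers = 5, n_flies_per_line = 0, seed = 1)
  sim <- simulate_panel(cfg)
  expect_error(simulate_phenotypes(sim$panel, cfg), "n_flies_per_line")
})

test_that("null generative model reproduces the baseline proportion at both doses", {
  cfg <- sim_config(n_lines = 200, n_markers = 10, baseline_p = 0.1,
                    dose_effect = 0, line_sd = 0, n_flies_per_line = 400,
                    seed = 13)
  st <- simulate_smurf_study(cfg)
  phen <- as.data.frame(st$phenotypes)
  for (d in c(0, 100)) {
    props <- with(phen[phen$dose_gy == d, ], n_smurf / n_total)
    se <- sqrt(0.1 * 0.9 / 400) / sqrt(length(props))
    expect_lt(abs(mean(props) - 0.1), 3 * se)
  }
})

test_that("a planted interaction shifts the carrier dose response by b_GxD", {
  # Monte-Carlo oracle: mean (irradiated - control) difference between
  # carrier and non-carrier lines estimates b_GxD directly
  b_gxd <- 0.12
  reps <- 120
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_lines = 60, n_markers = 20, maf_range = c(0.4, 0.5),
                      causal = data.frame(index = 3, b_g = 0.02, b_gxd = b_gxd),
                      line_sd = 0, seed = 5000 + r)
    st <- simulate_smurf_study(cfg)
    g <- st$panel$calls[3, ]
    phen <- as.data.frame(st$phenotypes)
    prop <- with(phen, tapply(n_smurf / n_total, list(line_id, dose_gy), mean))
    diff <- prop[, "100"] - prop[, "0"]
    est[r] <- mean(diff[g[rownames(prop)] == 1]) - mean(diff[g[rownames(prop)] == 0])
  }
  expect_lt(abs(mean(est) - b_gxd), 3 * sd(est) / sqrt(reps))
})

test_that("latent probabilities outside [0,1] are clamped with a counter", {
  cfg <- sim_config(n_lines = 30, n_markers = 5, baseline_p = 0.9,
                    dose_effect = 0.5, line_sd = 0, seed = 3)
  sim <- simulate_panel(cfg)
  expect_warning(phen <- simulate_phenotypes(sim$panel, cfg), "clamped")
  expect_equal(attr(phen, "n_clamped"), 30L)
  expect_true(all(attr(phen, "truth_prob") >= 0 & attr(phen, "truth_prob") <= 1))
})

test_that("vial layout splits flies into per-vial records", {
  cfg <- sim_config(n_lines = 8, n_markers = 4, n_flies_per_line = 100,
                    vial_size = 25, seed = 9)
  st <- simulate_smurf_study(cfg)
  phen <- as.data.frame(st$phenotypes)
  expect_equal(nrow(phen), 8 * 2 * 4)
  expect_true(all(phen$n_total == 25))
  expect_true("vial_id" %in% names(phen))
})

test_that("survival generator follows the stated laws and censors at study end", {
  tab <- simulate_survival(c(ctrl = 200, irr = 200), rate = c(ctrl = 0.02, irr = 0.08),
                           law = "exponential", censor_day = 60, seed = 17)
  expect_s3_class(tab, "survival_table")
  expect_true(all(tab$time <= 60))
  expect_true(any(tab$event == 0))
  # irradiated group dies faster
  expect_lt(mean(tab$time[tab$group == "irr"]), mean(tab$time[tab$group == "ctrl"]))

  # Gompertz inverse-CDF sampler against the independent flexsurv CDF
  g <- simulate_survival(c(a = 3000), rate = 0.01, shape = 0.15,
                         law = "gompertz", seed = 23)
  ks <- suppressWarnings(stats::ks.test(g$time, function(q)
    flexsurv::pgompertz(q, shape = 0.15, rate = 0.01)))
  expect_gt(ks$p.value, 0.01)
})

test_that("log-rank p-values are uniform when group hazards are equal", {
  reps <- 150
  pv <- numeric(reps)
  for (r in seq_len(reps)) {
    tab <- simulate_survival(c(a = 40, b = 40), rate = 0.05,
                             law = "exponential", seed = 900 + r)
    pv[r] <- logrank_test(tab)$p_value
  }
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("UTR generator plants exact motif counts and honours capacity limits", {
  su <- simulate_utrs(4, 200, planted_counts = c(0, 1, 4, 6), seed = 31)
  rep <- shortlist_genes(su$utrs)
  expect_identical(rep$n_sites, c(0L, 1L, 4L, 6L))
  expect_error(simulate_utrs(1, 20, planted_counts = 5, seed = 1),
               "cannot fit")
})
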