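test_that("line-block permutation conserves records and covers the full support", {
  phen <- toy_phen(c("a", "b", "c"), c(1L, 2L, 3L), c(10L, 20L, 30L))
  # identity permutation returns the input unchanged
  expect_identical(as.data.frame(permute_phenotypes(phen, perm = 1:3)),
                   as.data.frame(phen))
  # every permutation conserves the multiset of (dose, n_total, n_smurf)
  sig0 <- sort(with(as.data.frame(phen), paste(dose_gy, n_total, n_smurf)))
  all_perms <- perms_of(1:3)
  tables <- apply(all_perms, 1, function(p)
    phen_signature(permute_phenotypes(phen, perm = p)))
  expect_equal(length(unique(tables)), 6L)
  for (p in seq_len(nrow(all_perms))) {
    pp <- as.data.frame(permute_phenotypes(phen, perm = all_perms[p, ]))
    expect_identical(sort(with(pp, paste(dose_gy, n_total, n_smurf))), sig0)
    # dose pairing within a line is preserved as a block
    expect_setequal(unname(with(pp, tapply(n_smurf, line_id, sum))),
                    unname(with(as.data.frame(phen), tapply(n_smurf, line_id, sum))))
  }
  expect_error(permute_phenotypes(phen, perm = c(1, 1, 2)), "permutation")
})

test_that("empirical FDR reproduces the hand-enumerated two-marker example", {
  res <- empirical_fdr(c(0.01, 0.5), cbind(c(0.02, 0.6), c(0.03, 0.7)))
  expect_equal(res$fdr_raw, c(0, 0.5))
  expect_equal(res$q, c(0, 0.5))
  expect_equal(res$rank, c(1L, 2L))
})

test_that("self-comparison saturates q at 1", {
  p <- c(0.001, 0.2, 0.4, 0.9)
  res <- empirical_fdr(p, cbind(p, p, p))
  expect_true(all(res$q == 1))
})

test_that("monotonization is the running minimum from least to most significant", {
  # crafted nulls give raw FDR (0.10, 0.05, 0.20) at p = (0.1, 0.2, 0.3)
  observed <- c(0.1, 0.2, 0.3)
  nulls <- matrix(0.9, nrow = 3, ncol = 10)
  nulls[1, 1] <- 0.05   # 1 null <= 0.1 and <= 0.2
  nulls[2, 2:6] <- 0.25 # 6 nulls <= 0.3
  res <- empirical_fdr(observed, nulls)
  expect_equal(res$fdr_raw, c(0.10, 0.05, 0.20))
  expect_equal(res$q, c(0.05, 0.05, 0.20))
})

test_that("dimension mismatches and NA observed p are handled", {
  expect_error(empirical_fdr(c(0.1, 0.2), matrix(0.5, nrow = 3, ncol = 2)),
               "does not match")
  expect_error(empirical_fdr(c(0.1, 0.2), list(c(0.1), c(0.1, 0.2))),
               "differing lengths")
  res <- empirical_fdr(c(0.01, NA, 0.5), matrix(0.5, nrow = 3, ncol = 4))
  expect_true(is.na(res$q[2]))
  expect_equal(res$rank[c(1, 3)], c(1L, 2L))
})

test_that("adding a permutation moves raw FDR by at most 1/B per count and q stays in [0,1]", {
  set.seed(61)
  p <- runif(50)
  nulls <- matrix(runif(50 * 10), nrow = 50)
  extra <- matrix(runif(50), nrow = 50)
  q10 <- empirical_fdr(p, nulls)$q
  q11 <- empirical_fdr(p, cbind(nulls, extra))$q
  expect_true(all(q10 >= 0 & q10 <= 1))
  expect_true(all(q11 >= 0 & q11 <= 1))
})

test_that("marker annotation honours containment, priority and fallbacks", {
  fx <- feature_index(data.frame(
    chrom = c("2L", "2L", "2L", "3R"),
    start = c(100, 150, 400, 1),
    end = c(300, 250, 450, 50),
    feature_class = c("INTRON", "EXON", "NON_CODING", "INTRON"),
    gene = c("Ddr", "Ddr", "CG42324", "msi")))
  expect_equal(annotate_marker("2L_120_SNP", fx)$location, "INTRON")
  expect_equal(annotate_marker("2L_120_SNP", fx)$gene, "Ddr")
  # overlapping exon and intron: exon wins by priority
  expect_equal(annotate_marker("2L_200_SNP", fx)$location, "EXON")
  expect_equal(annotate_marker("2L_420_SNP", fx)$location, "NON_CODING")
  expect_equal(annotate_marker("2L_999999_SNP", fx)$location, "INTERGENIC")
  expect_warning(ann <- annotate_marker("4_10_SNP", fx), "absent")
  expect_equal(ann$location, "INTERGENIC")
  expect_true(is.na(ann$gene))
})

test_that("the shortlist applies the FDR cutoff and sorts by significance", {
  set.seed(71)
  calls <- matrix(rbinom(40 * 20, 1, 0.4), nrow = 40)
  panel <- toy_panel(calls)
  phen <- toy_phen(panel$line_ids, rbinom(20, 100, 0.1), rbinom(20, 100, 0.3))
  res <- suppressWarnings(empirical_fdr_scan(
    panel, phen, scan_config(maf_min = 0.1),
    fdr_config(n_permutations = 15, seed = 8)))
  # forged q values exercise the cutoff boundary {4%, 25%, 31%}
  res$fdr$fdr_percent <- rep(100, nrow(res$fdr))
  res$fdr$fdr_percent[1:3] <- c(31, 4, 25)
  res$fdr$q <- res$fdr$fdr_percent / 100
  short <- candidate_shortlist(res, cutoff = 27)
  expect_equal(nrow(short), 2L)
  expect_true(all(short$fdr_percent <= 27))
  expect_true(!is.unsorted(short$p))
  expect_equal(nrow(candidate_shortlist(res, cutoff = 100)), nrow(res$scan))
  # without annotation the gene/location columns stay blank
  expect_true(all(is.na(short$gene)) && all(is.na(short$location)))
})

test_that("seeded FDR runs are bit-reproducible", {
  set.seed(81)
  calls <- matrix(rbinom(25 * 14, 1, 0.4), nrow = 25)
  panel <- toy_panel(calls)
  phen <- toy_phen(panel$line_ids, rbinom(14, 100, 0.1), rbinom(14, 100, 0.3))
  r1 <- suppressWarnings(empirical_fdr_scan(panel, phen, scan_config(maf_min = 0.1),
                                            fdr_config(n_permutations = 10, seed = 99)))
  r2 <- suppressWarnings(empirical_fdr_scan(panel, phen, scan_config(maf_min = 0.1),
                                            fdr_config(n_permutations = 10, seed = 99)))
  expect_identical(r1$fdr$q, r2$fdr$q)
  expect_identical(as.data.frame(r1$scan), as.data.frame(r2$scan))
})
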