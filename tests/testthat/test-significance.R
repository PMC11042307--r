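test_that("extremum partition matches hand enumeration on anchored paths", {
  # [+1,+1,-1,-1]: delta = theta = 0,1,2,1,0; max at 2, min at 4
  p <- path_partition(c(1L, 1L, -1L, -1L))
  expect_identical(p$boundaries, c(2L, 4L))
  expect_identical(p$lengths, c(2L, 2L, 0L))
  expect_identical(unname(p$region_counts[1, ]), c(2L, 0L, 0L))
  expect_identical(unname(p$region_counts[2, ]), c(0L, 0L, 2L))
  expect_identical(unname(p$region_counts[3, ]), c(0L, 0L, 0L))
  expect_gte(p$phi[["phi1"]], 0)
  expect_lte(p$phi[["phi2"]], 0)

  # mirror case
  pm <- path_partition(c(-1L, -1L, 1L, 1L))
  expect_identical(pm$boundaries, c(2L, 4L))
  expect_identical(unname(pm$region_counts[1, ]), c(0L, 0L, 2L))
  expect_identical(unname(pm$region_counts[2, ]), c(2L, 0L, 0L))

  # flat path: tie rule sends both extrema to position 1
  pf <- path_partition(rep(0L, 6))
  expect_identical(pf$i_max, 1L)
  expect_identical(pf$i_min, 1L)
  expect_identical(pf$lengths, c(1L, 0L, 5L))
})

test_that("region lengths and counts conserve the totals", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(4:80, 1)
    m <- sample(c(1L, 0L, -1L), n, replace = TRUE)
    p <- path_partition(m)
    expect_identical(sum(p$lengths), n)
    expect_identical(as.integer(colSums(p$region_counts)),
                     c(sum(m == 1L), sum(m == 0L), sum(m == -1L)))
  }
})

test_that("log multinomial counts match direct and arbitrary-precision values", {
  expect_equal(log_multinomial(3, c(1, 1, 1)), log(6))
  expect_equal(log_multinomial(4, c(4, 0, 0)), 0)
  expect_equal(log_multinomial(0, c(0, 0, 0)), 0)
  # frozen from a 60-digit arbitrary-precision factorial computation
  expect_equal(log_multinomial(565, c(25, 25, 515)), 198.5996889055279,
               tolerance = 1e-10)
  # independent route: plain sums of logs
  expect_equal(log_multinomial(565, c(25, 25, 515)),
               sum(log(seq_len(565))) - sum(log(seq_len(25))) * 2 -
                 sum(log(seq_len(515))),
               tolerance = 1e-9)
  expect_error(log_multinomial(3, c(-1, 2, 2)), "negative")
  expect_error(log_multinomial(3, c(1, 1, 2)), "sum")
})

test_that("path p-value matches hand computation and degenerate contracts", {
  expect_equal(gift_pvalue(c(1L, 1L, -1L, -1L))$p_hat, 1 / 6)
  # monomorphic: one arrangement, p = 1
  expect_equal(gift_pvalue(rep(0L, 12))$p_hat, 1)
  expect_equal(gift_pvalue(rep(1L, 5))$p_hat, 1)
  pv <- gift_pvalue(c(1L, -1L, 1L, -1L, 0L))
  expect_equal(pv$mlog10_p_hat, -log10(pv$p_hat), tolerance = 1e-9)
  expect_lte(pv$p_hat, 1)
})

test_that("pipeline p-value equals the exhaustive counting oracle", {
  for (cnt in list(c(1, 1, 1), c(2, 0, 2), c(2, 2, 2), c(3, 1, 2))) {
    oc <- exhaustive_pvalue_oracle(cnt)
    expect_equal(oc$p_hat, oc$p_count, tolerance = 1e-12)
  }
  # (2,0,2): the fully segregated arrangement has p = 1/6
  oc <- exhaustive_pvalue_oracle(c(2, 0, 2))
  expect_equal(oc$p_hat[oc$arrangement == "1,1,-1,-1"], 1 / 6)
  # (N,0,0): single arrangement, p = 1
  oc1 <- exhaustive_pvalue_oracle(c(5, 0, 0))
  expect_identical(nrow(oc1), 1L)
  expect_equal(oc1$p_hat, 1)
  expect_error(exhaustive_pvalue_oracle(c(4, 4, 4)), "N <= 8")
})

test_that("relabelling + and - flips the path but not the p-value", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    m <- sample(c(1L, 0L, -1L), n, replace = TRUE)
    p1 <- gift_pvalue(m)
    p2 <- gift_pvalue(-m)
    expect_equal(p1$p_hat, p2$p_hat, tolerance = 1e-12)
    pa <- path_partition(m); pb <- path_partition(-m)
    expect_equal(unname(pa$phi), -unname(rev(pb$phi)))
  }
})

test_that("threshold calibration pools null paths reproducibly", {
  th1 <- calibrate_thresholds(theoretic_snp_presets()[1:3, ], K = 150, seed = 5)
  th2 <- calibrate_thresholds(theoretic_snp_presets()[1:3, ], K = 150, seed = 5)
  expect_identical(th1$levels, th2$levels)
  expect_gte(th1$level99, th1$level95)
  expect_gt(th1$level95, 0)
  expect_identical(length(th1$pooled_mlog10), 3L * 150L)
  # per-SNP order must not matter (per-SNP derived seeds)
  th3 <- calibrate_thresholds(theoretic_snp_presets()[3:1, ], K = 150, seed = 5)
  expect_equal(sort(th3$pooled_mlog10), sort(th1$pooled_mlog10))
  expect_warning(calibrate_thresholds(theoretic_snp_presets()[1, ], K = 50,
                                      seed = 1), "unstable")
})

test_that("a monomorphic theoretic SNP degenerates to threshold zero", {
  expect_warning(
    th <- calibrate_thresholds(list(c(0, 12, 0)), K = 100, seed = 2),
    "monomorphic"
  )
  expect_equal(th$level95, 0)
  expect_true(all(th$pooled_mlog10 == 0))
})

test_that("calibrated empirical p-values are null-uniform enough for BH", {
  th <- calibrate_thresholds(theoretic_snp_presets()[c(1, 4, 6), ],
                             K = 300, seed = 8)
  # fresh nulls from the same mixture -> approximately uniform p_emp
  set.seed(31)
  fresh <- unlist(lapply(c(1, 4, 6), function(k) {
    cnt <- unlist(theoretic_snp_presets()[k, c("n_plus", "n_zero", "n_minus")])
    vals <- giftpath:::.counts_to_values(cnt)
    replicate(100, -log10(giftpath:::.p_hat(sample(vals))))
  }))
  p_emp <- null_calibrated_pvalues(fresh, th)
  expect_true(all(p_emp > 0 & p_emp <= 1))
  ks <- suppressWarnings(stats::ks.test(p_emp, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.05), 0.05)
  # hand-derived: q_(k) = min_{j>=k} m p_(j) / j
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.03, 0.01)), c(0.03, 0.02))
  set.seed(29)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) > -1e-12))  # monotone in raw ranks
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})
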