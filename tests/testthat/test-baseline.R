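test_that("group means are per-microstate arithmetic means", {
  gm <- group_means(c(1, 2, 3), c(1L, 1L, -1L))
  expect_equal(gm$mu_plus, 1.5)
  expect_equal(gm$mu_minus, 3)
  expect_true(is.na(gm$mu_zero))
  gm2 <- group_means(rep(2, 6), c(1L, 1L, 0L, 0L, -1L, -1L))
  expect_equal(c(gm2$mu_plus, gm2$mu_zero, gm2$mu_minus), rep(2, 3))
})

test_that("gene effect and dominance follow the chosen convention", {
  m <- tibble::tibble(mu_plus = 1, mu_zero = 0, mu_minus = -1)
  ad <- gene_effect_dominance(m)
  expect_equal(ad$a, 1)
  expect_equal(ad$d, 0)       # pure additive
  m2 <- tibble::tibble(mu_plus = 2, mu_zero = 2, mu_minus = 0)
  ad2 <- gene_effect_dominance(m2)
  expect_equal(ad2$a, 1)
  expect_equal(ad2$d, 1)      # complete dominance
  ad2b <- gene_effect_dominance(m2, convention = "a_minus_mu0")
  expect_equal(ad2b$d, 1 - 2)
  # empty homozygote group: undefined, not an error
  m3 <- tibble::tibble(mu_plus = 1, mu_zero = 0, mu_minus = NA_real_)
  ad3 <- gene_effect_dominance(m3)
  expect_false(ad3$defined)
  expect_true(is.na(ad3$a))
})

test_that("gene effect is shift-invariant and scale-equivariant", {
  set.seed(37)
  r <- rnorm(120)
  m <- sample(c(1L, 0L, -1L), 120, replace = TRUE)
  base <- gene_effect_dominance(group_means(r, m))
  shifted <- gene_effect_dominance(group_means(r + 57, m))
  scaled <- gene_effect_dominance(group_means(r * 3, m))
  expect_equal(shifted$a, base$a)
  expect_equal(shifted$d, base$d)
  expect_equal(scaled$a, 3 * base$a)
  expect_equal(scaled$d, 3 * base$d)
})

test_that("two-group t-test matches its contracts", {
  same <- two_group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # p decreases monotonically in the group shift
  set.seed(41)
  x <- rnorm(20)
  ps <- sapply(c(0.5, 1, 2, 4), function(s) two_group_ttest(x, x + s)$p_value)
  expect_true(all(diff(ps) < 0))
  expect_true(is.na(two_group_ttest(1, c(1, 2))$statistic))
})

test_that("OLS slope test reduces to the two-group t-test when N0 = 0", {
  set.seed(43)
  m <- rep(c(1L, -1L), each = 15)
  y <- rnorm(30) + 0.8 * m
  ols <- ols_marker_test(y, m)
  tt <- two_group_ttest(y[m == 1L], y[m == -1L])
  expect_equal(ols$p_value, tt$p_value, tolerance = 1e-12)
})

test_that("OLS marker test handles exact fits, nulls and monomorphic markers", {
  m <- rep(c(-1L, 0L, 1L), 10)
  exact <- suppressWarnings(ols_marker_test(2.5 * m + 7, m))
  expect_equal(exact$beta, 2.5)
  expect_lt(exact$p_value, 1e-20)
  mono <- ols_marker_test(rnorm(10), rep(1L, 10))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$p_value))
  # null calibration: p approximately uniform
  set.seed(47)
  ps <- replicate(400, {
    mm <- sample(c(1L, 0L, -1L), 60, replace = TRUE, prob = c(.25, .5, .25))
    ols_marker_test(rnorm(60), mm)$p_value
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("fixed-effect adjustment is idempotent and recovers noise variance", {
  set.seed(53)
  n <- 360
  farm <- sample(paste0("farm", 1:11), n, replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  farm_eff <- stats::setNames(rnorm(11, sd = 2), paste0("farm", 1:11))
  y <- 10 + farm_eff[farm] + ifelse(sex == "M", 1.5, 0) + rnorm(n, sd = 1)
  df <- tibble::tibble(y = as.numeric(y), farm = farm, sex = sex)
  adj <- adjust_fixed_effects(df, "y", c("farm", "sex"))
  expect_lt(abs(mean(adj$residual)), 1e-9)
  expect_lt(abs(stats::var(adj$residual) - 1), 0.1)
  # idempotence
  adj2 <- adjust_fixed_effects(adj, "residual", c("farm", "sex"))
  expect_equal(adj2$residual, adj$residual, tolerance = 1e-9)
  # single two-level factor = within-group mean deviations
  df2 <- tibble::tibble(y = c(1, 2, 3, 10, 12), g = c("a", "a", "a", "b", "b"))
  adj3 <- adjust_fixed_effects(df2, "y", "g")
  expect_equal(adj3$residual, c(1 - 2, 2 - 2, 3 - 2, 10 - 11, 12 - 11))
})

test_that("natural-log option transforms before adjustment", {
  df <- tibble::tibble(y = exp(c(1, 2, 3)))
  adj <- adjust_fixed_effects(df, "y", character(), log_transform = TRUE)
  expect_equal(adj$residual, c(1, 2, 3) - 2)
  expect_error(adjust_fixed_effects(tibble::tibble(y = c(-1, 2)), "y",
                                    log_transform = TRUE), "positive")
})

test_that("Hardy-Weinberg exact test matches enumeration landmarks", {
  # balanced HW counts are maximally compatible
  expect_gte(hwe_exact_test(25, 50, 25), 0.99)
  expect_equal(hwe_exact_test(10, 0, 0), 1)  # monomorphic
  # gross heterozygote deficit at large n is vanishingly unlikely
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  # tiny case checked by hand: n=2, allele counts 2/2
  # het in {0, 2}: P(0) = 1/3, P(2) = 2/3 -> observing het=0 gives p = 1/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
})

test_that("SNP filters drop by MAF, call rate and HWE, idempotently", {
  geno <- tibble::tibble(
    snp_id = rep(c("mono", "gappy", "hwe_bad", "good"), each = 10),
    id = rep(sprintf("i%02d", 1:10), times = 4),
    call = c(
      rep("AA", 10),                              # MAF 0 -> dropped
      c(rep("NN", 2), rep("AG", 4), rep("AA", 4)),  # 20% missing -> dropped
      c(rep("AA", 5), rep("GG", 5)),              # no hets at n=5/5
      c(rep("AA", 3), rep("AG", 5), rep("GG", 2))
    )
  )
  res <- snp_filters(geno)
  expect_true("good" %in% res$kept)
  expect_false("mono" %in% res$kept)
  expect_false("gappy" %in% res$kept)
  expect_identical(res$qc$reason[res$qc$snp_id == "mono"], "maf")
  expect_identical(res$qc$reason[res$qc$snp_id == "gappy"], "call_rate")
  # hwe_bad: p = hwe_exact_test(5,0,5) ~ 4e-3 > 1e-6 -> kept by default,
  # dropped under a stricter threshold
  strict <- snp_filters(geno, hwe_p_min = 0.01)
  expect_false("hwe_bad" %in% strict$kept)
  # idempotence on the kept subset
  kept_geno <- geno[geno$snp_id %in% res$kept, ]
  res2 <- snp_filters(kept_geno)
  expect_identical(sort(res2$kept), sort(res$kept))
})

test_that("LD pruning keeps one SNP per correlated block", {
  set.seed(59)
  n <- 500
  m1 <- sample(c(1L, 0L, -1L), n, replace = TRUE, prob = c(.25, .5, .25))
  flip <- function(m, rate) ifelse(runif(n) < rate,
                                   sample(c(1L, 0L, -1L), n, TRUE), m)
  geno <- tibble::tibble(
    snp_id = rep(c("s1", "s2", "s3", "s4"), each = n),
    chrom = "1",
    pos = rep(c(1L, 2L, 3L, 4L), each = n),
    id = rep(sprintf("i%03d", 1:n), times = 4),
    call = unname(giftpath:::.microstate_to_call(c(
      m1, m1, flip(m1, 0.05),                    # duplicate + near-duplicate
      sample(c(1L, 0L, -1L), n, TRUE, c(.25, .5, .25))  # independent
    )))
  )
  kept <- ld_prune(geno, r2_threshold = 0.1)
  expect_identical(kept, c("s1", "s4"))
  # independent random SNPs survive pruning
  set.seed(61)
  geno2 <- tibble::tibble(
    snp_id = rep(sprintf("r%02d", 1:12), each = 200),
    chrom = "1",
    pos = rep(1:12, each = 200),
    id = rep(sprintf("i%03d", 1:200), times = 12),
    call = unname(giftpath:::.microstate_to_call(
      sample(c(1L, 0L, -1L), 2400, TRUE, c(.25, .5, .25))
    ))
  )
  expect_gte(length(ld_prune(geno2, 0.1)), 11)
})

test_that("Bonferroni thresholds match the closed form", {
  expect_equal(bonferroni_threshold(1, 0.05), 1.301, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(10433, 0.01), 6.0184, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(10433, 0.05), 5.3194, tolerance = 1e-4)
})
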