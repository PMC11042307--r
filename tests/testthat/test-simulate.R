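test_that("theoretic presets carry the six null count patterns", {
  pre <- theoretic_snp_presets()
  expect_identical(nrow(pre), 6L)
  expect_true(all(pre$n_plus + pre$n_zero + pre$n_minus == 565L))
  expect_identical(pre$n_plus[1], 25L)
  expect_identical(pre$n_zero[1], 25L)
  expect_identical(pre$n_minus[1], 515L)
  expect_identical(pre$n_minus[6], 15L)
  # consecutive presets transfer 100 microstates from '-1' to '0'
  expect_true(all(diff(pre$n_zero) == 100L))
  expect_true(all(diff(pre$n_minus) == -100L))
  expect_true(all(diff(pre$n_plus) == 0L))
})

test_that("theoretic SNP simulation preserves exact counts across seeds", {
  s1 <- simulate_theoretic_snp("SNP1", seed = 1)
  expect_identical(
    unlist(microstate_counts(s1)),
    c(n_plus = 25L, n_zero = 25L, n_minus = 515L, n = 565L)
  )
  s2 <- simulate_theoretic_snp("SNP1", seed = 2)
  expect_false(identical(s1, s2))
  expect_identical(microstate_counts(s1), microstate_counts(s2))
  expect_identical(simulate_theoretic_snp(c(3, 2, 1), seed = 7),
                   simulate_theoretic_snp(c(3, 2, 1), seed = 7))
  expect_error(simulate_theoretic_snp("SNP9"), "unknown preset")
})

test_that("additive cohorts are seed-deterministic and HW-consistent", {
  c1 <- simulate_fisher_cohort(n = 300, seed = 12)
  c2 <- simulate_fisher_cohort(n = 300, seed = 12)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$phenotypes, c2$phenotypes)
  # genotype letters round-trip the microstate truth
  enc <- encode_genotypes(c1$genotypes)
  expect_true(all(enc$microstate %in% c(-1L, 0L, 1L)))
  # simulated HW genotypes pass the HWE exact filter
  res <- snp_filters(c1$genotypes, maf_min = 0, hwe_p_min = 1e-6)
  expect_identical(res$kept, "sim1")
})

test_that("additive cohorts recover the generating effect", {
  set.seed(67)
  ests <- replicate(60, {
    co <- simulate_fisher_cohort(n = 1000, a_true = 2)
    enc <- encode_genotypes(co$genotypes)
    gene_effect_dominance(group_means(co$phenotypes$phenotype,
                                      enc$microstate))$a
  })
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 2), 3 * se)
})

test_that("sign-flip cohorts hide the effect from group means", {
  co <- simulate_sign_flip_cohort(n = 600, a_true = 2, seed = 71)
  enc <- encode_genotypes(co$genotypes)
  gm <- group_means(co$phenotypes$phenotype, enc$microstate)
  # homozygote means nearly coincide relative to the subpopulation spread
  expect_lt(abs(gm$mu_plus - gm$mu_minus),
            0.2 * diff(range(co$phenotypes$phenotype)))
  ols <- ols_marker_test(co$phenotypes$phenotype, enc$microstate)
  expect_gt(ols$p_value, 0.01)
  # ...but the ranked path is strongly ordered
  gp <- genetic_path(co$phenotypes$phenotype, enc$microstate)
  expect_gt(gift_pvalue(path_partition(gp$ordered))$mlog10_p_hat, 10)
})

test_that("sign-flip difference paths carry the sigmoid signature", {
  # interior sign change of delta: near one for detected sign-flip SNPs
  set.seed(73)
  changes <- replicate(25, {
    co <- simulate_sign_flip_cohort(n = 400, a_true = 2)
    enc <- encode_genotypes(co$genotypes)
    gp <- genetic_path(co$phenotypes$phenotype, enc$microstate)
    d <- gp$path$delta[2:(nrow(gp$path) - 1)]
    d <- d[abs(d) > 1e-9]
    sum(diff(sign(d)) != 0)
  })
  expect_gte(mean(changes >= 1), 0.9)
  expect_lt(stats::median(changes), 4)
})

test_that("a zero-effect sign-flip cohort reduces to a null cohort", {
  co <- simulate_sign_flip_cohort(n = 400, a_true = 0, seed = 79)
  expect_identical(co$truth$architecture, "null")
  enc <- encode_genotypes(co$genotypes)
  ols <- ols_marker_test(co$phenotypes$phenotype, enc$microstate)
  expect_gt(ols$p_value, 1e-3)
})

test_that("genome panels join losslessly to their truth table", {
  panel <- simulate_genome_panel(m_snps = 40, n = 120, fraction_causal = 0.1,
                                 seed = 83)
  expect_identical(dplyr::n_distinct(panel$genotypes$snp_id), 40L)
  expect_identical(nrow(panel$truth), 40L)
  scan <- gift_scan(panel)
  expect_identical(nrow(scan), 40L)
  joined <- dplyr::inner_join(scan, panel$truth,
                              by = c("snp_id", "chrom", "pos"))
  expect_identical(nrow(joined), 40L)
  expect_identical(sum(joined$architecture != "null"), 4L)
})

test_that("cohort files round-trip through the TSV writers", {
  co <- simulate_fisher_cohort(n = 25, seed = 89)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  geno <- read_genotypes(paths[["genotypes"]], format = "tsv")
  expect_identical(geno$call, co$genotypes$call)
  ph <- read_phenotypes(paths[["phenotypes"]])
  expect_equal(ph$phenotype, co$phenotypes$phenotype)
})
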