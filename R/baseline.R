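# Conventional single-marker quantities for comparison with the path
# statistic: per-microstate group means, Falconer gene effect and dominance,
# t-test diagnosis, OLS marker regression, fixed-effect residual adjustment,
# SNP QC filters (MAF / call rate / Hardy-Weinberg exact test), greedy LD
# pruning and Bonferroni thresholds.

#' Mean phenotypic residual per microstate group
#'
#' @param residuals Numeric residuals.
#' @param microstate Integer microstates (`NA` = missing, dropped pairwise).
#' @return One-row tibble `mu_plus`, `mu_zero`, `mu_minus` (NA for an empty
#'   group) and the group sizes.
#' @export
group_means <- function(residuals, microstate) {
  keep <- !is.na(microstate)
  residuals <- residuals[keep]
  microstate <- microstate[keep]
  mu <- function(q) if (any(microstate == q)) mean(residuals[microstate == q]) else NA_real_
  tibble::tibble(
    mu_plus = mu(1L), mu_zero = mu(0L), mu_minus = mu(-1L),
    n_plus = sum(microstate == 1L),
    n_zero = sum(microstate == 0L),
    n_minus = sum(microstate == -1L)
  )
}

#' Gene effect and dominance from group means
#'
#' Falconer-style single-locus effects: the gene (size) effect is half the
#' distance between the homozygote group means,
#' \eqn{a = (\mu_+ - \mu_-)/2}, and the dominance is the displacement of the
#' heterozygote mean from the homozygote midpoint,
#' \eqn{d = \mu_0 - (\mu_+ + \mu_-)/2}. An alternative reading (`convention =
#' "a_minus_mu0"`, \eqn{d = a - \mu_0}) is available for cross-checking
#' published tables. Undefined (an empty homozygote group) yields `NA`, not
#' an error.
#'
#' @param means One-row tibble from [group_means()] (or named list with
#'   `mu_plus`, `mu_zero`, `mu_minus`).
#' @param convention `"falconer"` (default) or `"a_minus_mu0"`.
#' @return One-row tibble with `a`, `d` and a logical `defined` flag.
#' @export
gene_effect_dominance <- function(means, convention = c("falconer", "a_minus_mu0")) {
  convention <- match.arg(convention)
  mu_p <- means$mu_plus[1]
  mu_0 <- means$mu_zero[1]
  mu_m <- means$mu_minus[1]
  defined <- is.finite(mu_p) && is.finite(mu_m)
  if (!defined) {
    return(tibble::tibble(a = NA_real_, d = NA_real_, defined = FALSE))
  }
  a <- (mu_p - mu_m) / 2
  d <- if (!is.finite(mu_0)) {
    NA_real_
  } else if (convention == "falconer") {
    mu_0 - (mu_p + mu_m) / 2
  } else {
    a - mu_0
  }
  tibble::tibble(a = a, d = d, defined = TRUE)
}

#' Two-group Student t-test of phenotypic means
#'
#' Two-sided t-test comparing the mean residual of two microstate groups
#' (pooled-variance Student by default, Welch selectable) -- the diagnosis
#' used to expose mean-comparison false positives.
#'
#' @param x,y Numeric residuals of the two groups, each `n >= 2`.
#' @param var_equal Pooled variance (default `TRUE`).
#' @return One-row tibble `statistic`, `p_value`, `df`.
#' @export
two_group_ttest <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_, df = NA_real_))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter)
  )
}

#' Single-marker ordinary-least-squares test
#'
#' Regresses the residual phenotype on microstate dosage coded `-1/0/+1` and
#' returns the slope, its standard error and the two-sided p-value of the
#' slope t-statistic. This is the plain mean-comparison baseline the path
#' statistic is contrasted against.
#'
#' @param residuals Numeric residuals.
#' @param microstate Integer microstates (`NA` dropped pairwise).
#' @return One-row tibble `beta`, `se`, `p_value`, `n` and a `monomorphic`
#'   flag (`p_value` is `NA` when the marker does not vary).
#' @export
ols_marker_test <- function(residuals, microstate) {
  keep <- !is.na(microstate) & is.finite(residuals)
  y <- residuals[keep]
  m <- as.numeric(microstate[keep])
  mono <- length(unique(m)) < 2L
  if (length(y) < 3L || mono) {
    return(tibble::tibble(beta = NA_real_, se = NA_real_, p_value = NA_real_,
                          n = length(y), monomorphic = mono))
  }
  fit <- stats::lm(y ~ m)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    beta = sm["m", "Estimate"],
    se = sm["m", "Std. Error"],
    p_value = sm["m", "Pr(>|t|)"],
    n = length(y),
    monomorphic = FALSE
  )
}

#' Remove fixed effects from a phenotype
#'
#' Least-squares adjustment `y = mu + factor effects + e`: fits an additive
#' model of the supplied categorical factors (e.g. farm and sex) and returns
#' the residuals `e`, optionally after a natural-log transform of `y`. The
#' operation is idempotent: adjusting the residuals again changes nothing.
#'
#' @param data A data frame with the phenotype and factor columns.
#' @param response Name of the phenotype column.
#' @param factors Character vector of factor column names (may be empty, in
#'   which case only the mean is removed).
#' @param log_transform Natural-log the response first (default `FALSE`).
#' @return The input tibble with a `residual` column appended.
#' @export
adjust_fixed_effects <- function(data, response, factors = character(),
                                 log_transform = FALSE) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (!all(factors %in% names(data))) {
    stop("missing factor column(s): ",
         paste(setdiff(factors, names(data)), collapse = ", "), call. = FALSE)
  }
  y <- data[[response]]
  if (log_transform) {
    if (any(y <= 0)) stop("log transform requires strictly positive phenotype",
                          call. = FALSE)
    y <- log(y)
  }
  df <- data.frame(.y = y)
  for (f in factors) {
    fac <- factor(data[[f]])
    if (any(table(fac) == 1L)) {
      warning("factor '", f, "' has level(s) with a single observation",
              call. = FALSE)
    }
    df[[f]] <- fac
  }
  form <- if (length(factors)) {
    stats::as.formula(paste(".y ~", paste(factors, collapse = " + ")))
  } else {
    .y ~ 1
  }
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    message("collinear fixed effects: dropped ",
            sum(is.na(stats::coef(fit))), " redundant column(s)")
  }
  dplyr::mutate(tibble::as_tibble(data), residual = unname(stats::residuals(fit)))
}

#' Hardy-Weinberg exact test for a bi-allelic SNP
#'
#' Exact two-sided test by full enumeration of heterozygote counts
#' conditional on the allele counts: every heterozygote count of the right
#' parity gets its exact probability, and the p-value is the total
#' probability of outcomes no more likely than the observed one.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (either homozygote first).
#' @return The exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  n_a <- 2 * min(n_hom1, n_hom2) + n_het   # rare allele count
  if (n_a == 0L) return(1)
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  # log P(het = h | allele counts) up to a shared constant
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_a - h) / 2
    hom_common <- n - h - hom_rare
    h * log(2) - lgamma(h + 1) - lgamma(hom_rare + 1) - lgamma(hom_common + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' SNP quality-control filters
#'
#' Drops SNPs failing any of: minor allele frequency below `maf_min`
#' (computed from called genotypes only), missing-call rate above
#' `max_missing`, or Hardy-Weinberg exact-test p-value below `hwe_p_min`.
#' Defaults mirror the usual array-QC settings (MAF 5%, call rate 10%,
#' HWE 1e-6). The filter is idempotent.
#'
#' @param genotypes Long genotype tibble (`snp_id`, `id`, `call`).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param max_missing Maximum missing-call fraction (default 0.10).
#' @param hwe_p_min Minimum HWE exact p-value (default 1e-6).
#' @return A list with `kept` (character vector of SNP ids) and `qc`, a
#'   per-SNP tibble of `maf`, `missing_rate`, `hwe_p`, `kept`, `reason`.
#' @export
snp_filters <- function(genotypes, maf_min = 0.05, max_missing = 0.10,
                        hwe_p_min = 1e-6) {
  stopifnot(all(c("snp_id", "id", "call") %in% names(genotypes)))
  qc <- genotypes |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(.qc = list(.snp_qc_row(.data$call)), .groups = "drop") |>
    tidyr::unnest(".qc")
  qc <- qc |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$n_called == 0L ~ "all_missing",
        .data$missing_rate > max_missing ~ "call_rate",
        .data$maf < maf_min ~ "maf",
        .data$hwe_p < hwe_p_min ~ "hwe",
        TRUE ~ NA_character_
      ),
      kept = is.na(.data$reason)
    )
  list(kept = qc$snp_id[qc$kept], qc = qc)
}

# Internal: per-SNP QC summary from raw calls.
.snp_qc_row <- function(call) {
  call <- toupper(as.character(call))
  missing <- is.na(call) | call == .MISSING_CALL
  called <- call[!missing]
  n_total <- length(call)
  n_called <- length(called)
  if (n_called == 0L) {
    return(tibble::tibble(n_called = 0L, missing_rate = 1, maf = NA_real_,
                          hwe_p = NA_real_))
  }
  alleles <- c(substr(called, 1, 1), substr(called, 2, 2))
  tab <- sort(table(alleles), decreasing = TRUE)
  maf <- if (length(tab) < 2L) 0 else as.numeric(tab[2] / sum(tab))
  if (length(tab) >= 2L) {
    a1 <- names(tab)[1]; a2 <- names(tab)[2]
    n_hom1 <- sum(called == paste0(a1, a1))
    n_hom2 <- sum(called == paste0(a2, a2))
    n_het <- sum(called %in% c(paste0(a1, a2), paste0(a2, a1)))
    hwe_p <- hwe_exact_test(n_hom1, n_het, n_hom2)
  } else {
    hwe_p <- 1
  }
  tibble::tibble(
    n_called = n_called,
    missing_rate = 1 - n_called / n_total,
    maf = maf,
    hwe_p = hwe_p
  )
}

#' Greedy linkage-disequilibrium pruning
#'
#' Positional scan within each chromosome: a SNP is kept unless its squared
#' Pearson correlation (on microstate dosage, pairwise-complete) with any
#' previously kept SNP on the same chromosome exceeds `r2_threshold`.
#' Deterministic given input order; zero-variance SNPs are skipped from the
#' correlation but kept.
#'
#' @param genotypes Long genotype tibble with `snp_id`, `id`, `call` and
#'   optionally `chrom` (a single chromosome is assumed when absent).
#' @param r2_threshold Squared-correlation threshold (default 0.1).
#' @return Character vector of independent SNP ids.
#' @export
ld_prune <- function(genotypes, r2_threshold = 0.1) {
  enc <- encode_genotypes(genotypes)
  if (!"chrom" %in% names(enc)) enc$chrom <- "0"
  wide <- enc |>
    dplyr::select("id", "snp_id", "microstate") |>
    tidyr::pivot_wider(names_from = "snp_id", values_from = "microstate")
  snp_meta <- dplyr::distinct(enc, .data$snp_id, .data$chrom)
  if ("pos" %in% names(enc)) {
    snp_meta <- dplyr::distinct(enc, .data$snp_id, .data$chrom, .data$pos) |>
      dplyr::arrange(.data$chrom, .data$pos)
  }
  kept <- character(0)
  for (ch in unique(snp_meta$chrom)) {
    snps <- snp_meta$snp_id[snp_meta$chrom == ch]
    kept_ch <- character(0)
    for (s in snps) {
      x <- wide[[s]]
      if (length(unique(x[!is.na(x)])) < 2L) {
        kept_ch <- c(kept_ch, s)   # zero variance: no correlation defined
        next
      }
      indep <- TRUE
      for (k in kept_ch) {
        y <- wide[[k]]
        if (length(unique(y[!is.na(y)])) < 2L) next
        r <- suppressWarnings(stats::cor(x, y, use = "pairwise.complete.obs"))
        if (is.finite(r) && r^2 > r2_threshold) {
          indep <- FALSE
          break
        }
      }
      if (indep) kept_ch <- c(kept_ch, s)
    }
    kept <- c(kept, kept_ch)
  }
  kept
}

#' Bonferroni significance threshold
#'
#' `-log10(level / n_independent)`: the genome-wide line drawn on
#' mean-comparison Manhattan plots, computed on the LD-pruned (independent)
#' SNP count.
#'
#' @param n_independent Number of independent SNPs (`>= 1`).
#' @param level Family-wise error level (e.g. 0.05 or 0.01).
#' @return The threshold on the `-log10 p` scale.
#' @examples
#' bonferroni_threshold(10433, 0.01)
#' @export
bonferroni_threshold <- function(n_independent, level) {
  stopifnot(n_independent >= 1, level > 0, level < 1)
  -log10(level / n_independent)
}
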