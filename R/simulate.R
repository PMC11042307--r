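# Seeded cohort simulators with known genetic architecture.
#
# Three architectures cover the phenomenology the path statistic is built
# for:
#   * "linear"   -- a constant (Fisher-type) allelic effect: microstates +1
#                   and -1 migrate to opposite ends of the residual ranking,
#                   giving a paraboloid difference path; visible to
#                   mean-comparison tests.
#   * "null"     -- genotype independent of phenotype.
#   * "sign_flip"-- a scale-dependent effect: the allelic effect has opposite
#                   sign in two latent subpopulations occupying the lower and
#                   upper residual ranges, so homozygote group means nearly
#                   coincide (mean tests are blind) while the ranked path is
#                   sigmoid.
# Every generator is a pure function of (parameters, seed).

#' Theoretic SNP count presets
#'
#' The six microstate-count presets used to capture the permutation null
#' hypothesis: `N+` fixed at 25 and 100 microstates transferred from the
#' `-1` class to the `0` class between consecutive presets, at `N = 565`.
#'
#' @return Tibble with columns `snp_id`, `n_plus`, `n_zero`, `n_minus`, `n`.
#' @export
theoretic_snp_presets <- function() {
  tibble::tibble(
    snp_id = paste0("SNP", 1:6),
    n_plus = rep(25L, 6),
    n_zero = c(25L, 125L, 225L, 325L, 425L, 525L),
    n_minus = c(515L, 415L, 315L, 215L, 115L, 15L),
    n = 565L
  )
}

#' Simulate a pure-null theoretic SNP
#'
#' Uniformly random arrangement of an exact microstate multiset -- a null
#' path with no phenotype attached.
#'
#' @param counts Counts spec `(n_plus, n_zero, n_minus)`, or a preset name
#'   `"SNP1"`..`"SNP6"` from [theoretic_snp_presets()].
#' @param seed Optional integer seed.
#' @return Integer microstate string with exactly the requested counts.
#' @export
simulate_theoretic_snp <- function(counts, seed = NULL) {
  if (is.character(counts)) {
    presets <- theoretic_snp_presets()
    row <- presets[presets$snp_id == counts, ]
    if (nrow(row) != 1L) stop("unknown preset '", counts, "'", call. = FALSE)
    counts <- c(row$n_plus, row$n_zero, row$n_minus)
  }
  values <- .counts_to_values(counts)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  sample(values)
}

# Internal: draw n microstates from Hardy-Weinberg proportions.
# allele_freq p is the frequency of the allele whose homozygote encodes +1,
# so the class frequencies are (p^2, 2pq, q^2) for (+1, 0, -1).
.hw_microstates <- function(n, allele_freq) {
  if (allele_freq <= 0 || allele_freq >= 1) {
    stop("allele_freq must lie strictly inside (0, 1)", call. = FALSE)
  }
  p <- allele_freq
  sample(c(1L, 0L, -1L), n, replace = TRUE,
         prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
}

# Internal: emit letter calls that round-trip the microstate truth
# (+1 -> "AA", 0 -> "AG", -1 -> "GG").
.microstate_to_call <- function(m) {
  c(`-1` = "GG", `0` = "AG", `1` = "AA")[as.character(m)]
}

# Internal: assemble the standard cohort object.
.new_cohort <- function(genotypes, phenotypes, truth, seed) {
  structure(
    list(genotypes = genotypes, phenotypes = phenotypes, truth = truth,
         seed = seed),
    class = "gift_cohort"
  )
}

#' @export
print.gift_cohort <- function(x, ...) {
  cat("<gift_cohort>", dplyr::n_distinct(x$genotypes$snp_id), "SNP(s) x",
      dplyr::n_distinct(x$genotypes$id), "individuals\n")
  print(x$truth, n = 5)
  invisible(x)
}

#' Simulate an additive (Fisher-model) cohort
#'
#' One bi-allelic SNP in Hardy-Weinberg proportions and a continuous
#' phenotype with a constant allelic effect:
#' `phenotype = phen_mean + a_true * m + d_true * [m == 0] + noise`,
#' each microstate class normally distributed around its own mean with
#' standard deviation `phen_sd`. Defaults emulate the reference simulation
#' conditions: `n = 1000`, genotype class frequencies
#' `(0.64, 0.32, 0.04)` (allele frequency 0.8), phenotype mean 68 and
#' standard deviation 2 units, gene effect equal to the phenotype standard
#' deviation, no dominance.
#'
#' @param n Cohort size.
#' @param allele_freq Frequency of the `+1`-encoding allele.
#' @param phen_mean,phen_sd Phenotype location and per-class noise sd.
#' @param a_true Additive gene effect (defaults to `phen_sd`).
#' @param d_true Dominance deviation (default 0).
#' @param seed Optional integer seed.
#' @param snp_id SNP label (default `"sim1"`).
#' @return A `"gift_cohort"`: list with long `genotypes`
#'   (`snp_id, chrom, pos, id, call`), `phenotypes` (`id, phenotype`), and a
#'   per-SNP `truth` tibble (`snp_id, architecture, a_true, d_true`).
#' @export
simulate_fisher_cohort <- function(n = 1000L, allele_freq = 0.8,
                                   phen_mean = 68, phen_sd = 2,
                                   a_true = phen_sd, d_true = 0,
                                   seed = NULL, snp_id = "sim1") {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  m <- .hw_microstates(n, allele_freq)
  phenotype <- phen_mean + a_true * m + d_true * (m == 0L) +
    stats::rnorm(n, 0, phen_sd)
  ids <- sprintf("ind%04d", seq_len(n))
  .new_cohort(
    genotypes = tibble::tibble(
      snp_id = snp_id, chrom = "1", pos = 1L,
      id = ids, call = unname(.microstate_to_call(m))
    ),
    phenotypes = tibble::tibble(id = ids, phenotype = phenotype),
    truth = tibble::tibble(
      snp_id = snp_id,
      architecture = if (a_true == 0 && d_true == 0) "null" else "linear",
      a_true = a_true, d_true = d_true
    ),
    seed = seed
  )
}

#' Simulate a scale-dependent (sign-flipping) cohort
#'
#' Each individual belongs to one of two equally likely latent
#' subpopulations occupying the lower and upper residual ranges; the allelic
#' effect is `+a_true` in one and `-a_true` in the other:
#' `phenotype = s * separation + s * a_true * m + noise`, `s = +/-1`.
#' Averaged over subpopulations the homozygote group means nearly coincide,
#' so mean-comparison tests see nothing, while the phenotype-ranked path is
#' sigmoid -- the minimal mechanism producing scale-dependent association.
#'
#' @param n Cohort size (even recommended).
#' @param allele_freq Frequency of the `+1`-encoding allele (default 0.5).
#' @param a_true Within-subpopulation allelic effect.
#' @param noise_sd Residual noise sd (default 1).
#' @param separation Half-distance between subpopulation centres; the
#'   default `4 * noise_sd + 2 * abs(a_true)` keeps the ranges disjoint.
#' @param seed Optional integer seed.
#' @param snp_id SNP label.
#' @return A `"gift_cohort"` (architecture `"sign_flip"`); the truth tibble
#'   records `a_true` and the subpopulation assignment is returned in
#'   `phenotypes$subpop`.
#' @export
simulate_sign_flip_cohort <- function(n = 500L, allele_freq = 0.5, a_true = 2,
                                      noise_sd = 1,
                                      separation = 4 * noise_sd + 2 * abs(a_true),
                                      seed = NULL, snp_id = "sim1") {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  m <- .hw_microstates(n, allele_freq)
  s <- sample(c(-1, 1), n, replace = TRUE)
  phenotype <- s * separation + s * a_true * m + stats::rnorm(n, 0, noise_sd)
  ids <- sprintf("ind%04d", seq_len(n))
  .new_cohort(
    genotypes = tibble::tibble(
      snp_id = snp_id, chrom = "1", pos = 1L,
      id = ids, call = unname(.microstate_to_call(m))
    ),
    phenotypes = tibble::tibble(id = ids, phenotype = phenotype, subpop = s),
    truth = tibble::tibble(
      snp_id = snp_id,
      architecture = if (a_true == 0) "null" else "sign_flip",
      a_true = a_true, d_true = 0
    ),
    seed = seed
  )
}

#' Simulate a mixed genome panel
#'
#' Multi-SNP cohort across fake chromosomes: a fraction of SNPs carry a
#' linear effect, a fraction a sign-flipping effect, the rest are null. The
#' phenotype sums all causal contributions plus noise; sign-flip SNPs share
#' one latent subpopulation indicator. Used as the end-to-end fixture for
#' Manhattan-style scans and ROC experiments.
#'
#' @param m_snps Number of SNPs.
#' @param n Cohort size.
#' @param fraction_causal Fraction of causal SNPs (default 0.05), split
#'   between the requested architectures.
#' @param architectures Causal architectures to include, subset of
#'   `c("linear", "sign_flip")`.
#' @param a_true Effect size of every causal SNP (default 2).
#' @param noise_sd Residual noise sd (default 1).
#' @param allele_freq Allele frequency of all SNPs (default 0.5).
#' @param n_chrom Number of fake chromosomes (default 3).
#' @param seed Optional integer seed.
#' @return A `"gift_cohort"` with one truth row per SNP.
#' @export
simulate_genome_panel <- function(m_snps, n = 500L, fraction_causal = 0.05,
                                  architectures = c("linear", "sign_flip"),
                                  a_true = 2, noise_sd = 1, allele_freq = 0.5,
                                  n_chrom = 3L, seed = NULL) {
  stopifnot(m_snps >= 1L)
  architectures <- match.arg(architectures, several.ok = TRUE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  n_causal <- round(m_snps * fraction_causal)
  arch <- rep("null", m_snps)
  if (n_causal > 0L) {
    causal_idx <- sample(m_snps, n_causal)
    arch[causal_idx] <- rep_len(architectures, n_causal)
  }
  ids <- sprintf("ind%04d", seq_len(n))
  geno <- matrix(0L, nrow = n, ncol = m_snps)
  for (j in seq_len(m_snps)) geno[, j] <- .hw_microstates(n, allele_freq)
  s <- sample(c(-1, 1), n, replace = TRUE)
  y <- stats::rnorm(n, 0, noise_sd)
  if (any(arch == "sign_flip")) {
    y <- y + s * (3 * noise_sd)
    for (j in which(arch == "sign_flip")) y <- y + s * a_true * geno[, j]
  }
  for (j in which(arch == "linear")) y <- y + a_true * geno[, j]
  snp_ids <- sprintf("snp%04d", seq_len(m_snps))
  chrom <- as.character(((seq_len(m_snps) - 1L) %% n_chrom) + 1L)
  pos <- ((seq_len(m_snps) - 1L) %/% n_chrom + 1L) * 1000L
  genotypes <- tibble::tibble(
    snp_id = rep(snp_ids, each = n),
    chrom = rep(chrom, each = n),
    pos = rep(pos, each = n),
    id = rep(ids, times = m_snps),
    call = unname(.microstate_to_call(as.vector(geno)))
  )
  .new_cohort(
    genotypes = genotypes,
    phenotypes = tibble::tibble(id = ids, phenotype = y, subpop = s),
    truth = tibble::tibble(
      snp_id = snp_ids, chrom = chrom, pos = pos, architecture = arch,
      a_true = ifelse(arch == "null", 0, a_true),
      d_true = 0
    ),
    seed = seed
  )
}

#' Write a simulated cohort to disk
#'
#' Emits the genotype TSV dialect, a phenotype TSV and the truth TSV.
#'
#' @param cohort A `"gift_cohort"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"cohort"`).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "gift_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, paste0(prefix, "_genotypes.tsv")),
    phenotypes = file.path(dir, paste0(prefix, "_phenotypes.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_genotypes_tsv(cohort$genotypes, paths["genotypes"])
  readr::write_tsv(cohort$phenotypes, paths["phenotypes"])
  readr::write_tsv(cohort$truth, paths["truth"])
  invisible(paths)
}
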