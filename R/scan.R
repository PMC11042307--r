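# Genome scan: the full per-SNP pipeline plus the method comparison.

#' Genome scan with genetic paths
#'
#' Runs the full per-SNP pipeline -- encode, pairwise-delete missing calls,
#' rank by residual, build the path, partition at the extrema, compute the
#' combinatorial p-value -- then Benjamini-Hochberg adjusts `p_hat` across
#' all scanned SNPs. Alongside, the conventional single-marker quantities
#' are computed: group means, gene effect and dominance, and the OLS
#' marker-regression p-value.
#'
#' @param genotypes Long genotype tibble (`snp_id`, `id`, `call`, optional
#'   `chrom`, `pos`) or a `"gift_cohort"`.
#' @param phenotypes Tibble with `id` and the phenotype column. Ignored when
#'   `genotypes` is a cohort and `phenotypes` is `NULL`.
#' @param phenotype_col Name of the phenotype column (default
#'   `"phenotype"`); values are used as the residuals to rank.
#' @param dominance_convention Passed to [gene_effect_dominance()].
#'
#' @return A tibble of class `"gift_scan"`, one row per SNP:
#'   `chrom`, `snp_id`, `pos`, `n_plus`, `n_zero`, `n_minus`, `n`,
#'   `p_hat`, `mlog10_p_hat`, `p_gift` (BH-adjusted), `mlog10_p_gift`,
#'   `a`, `d`, `p_gwas` (OLS), `mlog10_p_gwas`, `flags`.
#'   Deterministic: a pure function of its inputs.
#'
#' @examples
#' co <- simulate_fisher_cohort(n = 200, seed = 1)
#' gift_scan(co)
#' @export
gift_scan <- function(genotypes, phenotypes = NULL,
                      phenotype_col = "phenotype",
                      dominance_convention = "falconer") {
  if (inherits(genotypes, "gift_cohort")) {
    phenotypes <- phenotypes %||% genotypes$phenotypes
    genotypes <- genotypes$genotypes
  }
  stopifnot(is.data.frame(genotypes), is.data.frame(phenotypes))
  if (!phenotype_col %in% names(phenotypes)) {
    stop("phenotype column '", phenotype_col, "' not found", call. = FALSE)
  }
  ph <- dplyr::select(phenotypes, "id", residual = dplyr::all_of(phenotype_col))
  common <- intersect(unique(genotypes$id), ph$id)
  if (!length(common)) stop("no overlapping individuals between genotypes and phenotypes",
                            call. = FALSE)
  dropped <- dplyr::n_distinct(genotypes$id) - length(common)
  if (dropped > 0) {
    warning(dropped, " genotyped individual(s) without phenotype dropped",
            call. = FALSE)
  }
  enc <- encode_genotypes(genotypes) |>
    dplyr::inner_join(ph, by = "id")
  if (!"chrom" %in% names(enc)) enc$chrom <- "0"
  if (!"pos" %in% names(enc)) enc$pos <- NA_integer_
  # canonical individual order = genotype input order, per SNP
  snp_order <- unique(genotypes$snp_id)
  res <- enc |>
    dplyr::group_by(.data$chrom, .data$snp_id, .data$pos) |>
    dplyr::summarise(
      .row = list(.scan_one(.data$residual, .data$microstate,
                            dominance_convention)),
      .groups = "drop"
    ) |>
    tidyr::unnest(".row") |>
    dplyr::arrange(match(.data$snp_id, snp_order))
  testable <- !is.na(res$p_hat)
  res$p_gift <- NA_real_
  res$p_gift[testable] <- bh_adjust(res$p_hat[testable])
  res$mlog10_p_gift <- -log10(res$p_gift)
  res <- dplyr::relocate(res, "p_gift", "mlog10_p_gift",
                         .after = "mlog10_p_hat")
  class(res) <- c("gift_scan", class(res))
  res
}

# Internal: all per-SNP statistics for one SNP.
.scan_one <- function(residual, microstate, dominance_convention) {
  keep <- !is.na(microstate)
  counts <- microstate_counts(microstate)
  flags <- character(0)
  if (counts$n == 0L) {
    return(tibble::tibble(
      n_plus = 0L, n_zero = 0L, n_minus = 0L, n = 0L,
      p_hat = NA_real_, mlog10_p_hat = NA_real_,
      a = NA_real_, d = NA_real_,
      p_gwas = NA_real_, mlog10_p_gwas = NA_real_,
      flags = "all_missing"
    ))
  }
  mono <- sum(c(counts$n_plus, counts$n_zero, counts$n_minus) > 0L) <= 1L
  ordered <- rank_by_phenotype(residual[keep], microstate[keep])
  pv <- gift_pvalue(path_partition(ordered))
  gm <- group_means(residual, microstate)
  ad <- gene_effect_dominance(gm, convention = dominance_convention)
  ols <- ols_marker_test(residual, microstate)
  if (mono) flags <- c(flags, "monomorphic")
  if (!ad$defined) flags <- c(flags, "undefined_ad")
  dplyr::bind_cols(
    counts,
    tibble::tibble(
      p_hat = pv$p_hat, mlog10_p_hat = pv$mlog10_p_hat,
      a = ad$a, d = ad$d,
      p_gwas = ols$p_value, mlog10_p_gwas = -log10(ols$p_value),
      flags = paste(flags, collapse = ";")
    )
  )
}

#' Scan summary
#'
#' @param x A `"gift_scan"` tibble.
#' @param thresholds Optional `"gift_thresholds"` used to count significant
#'   SNPs.
#' @param ... Unused.
#' @return One-row tibble: SNP counts, monomorphic count, and (when
#'   thresholds are supplied) the numbers of SNPs beyond the 95%/99% lines.
#' @export
glance.gift_scan <- function(x, thresholds = NULL, ...) {
  out <- tibble::tibble(
    n_snps = nrow(x),
    n_tested = sum(!is.na(x$p_hat)),
    n_monomorphic = sum(grepl("monomorphic", x$flags))
  )
  if (!is.null(thresholds)) {
    out$n_beyond_95 <- sum(x$mlog10_p_hat > thresholds$level95, na.rm = TRUE)
    out$n_beyond_99 <- sum(x$mlog10_p_hat > thresholds$level99, na.rm = TRUE)
  }
  out
}

#' Write scan results as TSV
#'
#' Column layout:
#' `chrom snp pos N+ N0 N- p_hat mlog10_p_hat p_gift mlog10_p_gift a d
#' p_gwas mlog10_p_gwas flags` -- the Manhattan-plot input for both methods.
#'
#' @param x A `"gift_scan"` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' Compare path-based and mean-based rankings
#'
#' Joins the two p-value columns of a scan, ranks SNPs under each method,
#' and summarises the overlap of the top-`k` sets (plus a quadrant
#' classification against the supplied thresholds).
#'
#' @param scan A `"gift_scan"` tibble.
#' @param top_k Size of the head-to-head top list (default 100).
#' @param gift_threshold,gwas_threshold Optional `-log10 p` significance
#'   lines used for the quadrant labels.
#' @return A list with `table` (per-SNP ranks and quadrant), `overlap`
#'   (one-row tibble: `top_k`, `n_both`, `n_gift_only`, `n_gwas_only`).
#' @export
compare_methods <- function(scan, top_k = 100L, gift_threshold = NULL,
                            gwas_threshold = NULL) {
  tb <- scan |>
    dplyr::filter(!is.na(.data$p_hat), !is.na(.data$p_gwas)) |>
    dplyr::mutate(
      rank_gift = rank(.data$p_hat, ties.method = "first"),
      rank_gwas = rank(.data$p_gwas, ties.method = "first"),
      top_gift = .data$rank_gift <= top_k,
      top_gwas = .data$rank_gwas <= top_k
    )
  if (!is.null(gift_threshold) && !is.null(gwas_threshold)) {
    tb <- dplyr::mutate(
      tb,
      quadrant = dplyr::case_when(
        .data$mlog10_p_hat <= gift_threshold & .data$mlog10_p_gwas > gwas_threshold ~ "Q1_gwas_only",
        .data$mlog10_p_hat > gift_threshold & .data$mlog10_p_gwas > gwas_threshold ~ "Q2_both",
        .data$mlog10_p_hat <= gift_threshold & .data$mlog10_p_gwas <= gwas_threshold ~ "Q3_neither",
        TRUE ~ "Q4_gift_only"
      )
    )
  }
  overlap <- tibble::tibble(
    top_k = top_k,
    n_both = sum(tb$top_gift & tb$top_gwas),
    n_gift_only = sum(tb$top_gift & !tb$top_gwas),
    n_gwas_only = sum(!tb$top_gift & tb$top_gwas)
  )
  list(table = tb, overlap = overlap)
}
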