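# Combinatorial significance of a genetic path.
#
# The anchored difference path delta(i) attains a maximum Phi1 >= 0 and a
# minimum Phi2 <= 0 over positions 1..N. The two (first-occurring) extremum
# positions split 1..N into three blocks of lengths di1, di2, di3. Writing
# n_q^p for the number of microstates of type q in block p, the number of
# arrangements that reproduce the block compositions is the product of three
# multinomial coefficients, and
#
#   p_hat = N1 * N2 * N3 / N0_path,   N0_path = N! / (N+! N0! N-!)
#
# is the fraction of all arrangements of the multiset sharing those
# compositions. Small p_hat = a strongly ordered path. p_hat is treated as a
# score calibrated empirically (null-ensemble thresholds plus
# Benjamini-Hochberg across SNPs), not as a uniform p-value.

#' Partition a difference path at its extrema
#'
#' Finds the first position of the maximum and of the minimum of `delta`
#' over `1..N` (ties to the smallest index, decided in exact integer
#' arithmetic), sorts them into boundaries `(i1, i2)`, and tallies the
#' microstates of `ordered` within the half-open blocks `(0, i1]`,
#' `(i1, i2]`, `(i2, N]`.
#'
#' @param ordered Integer microstate string in residual order.
#' @param delta Optional difference path (length `N + 1`, `delta[1] = 0`);
#'   computed from `ordered` when omitted.
#' @param boundary Region-boundary convention. `"closed"` (default): the
#'   extremum's microstate terminates its region, blocks `(0, i1]`,
#'   `(i1, i2]`, `(i2, N]`. `"open"`: the extremum's microstate opens the
#'   next region, blocks `(0, i1 - 1]`, `(i1 - 1, i2 - 1]`, `(i2 - 1, N]`.
#'
#' @return An object of class `"gift_partition"`: list with `i_max`, `i_min`,
#'   `boundaries` (`c(i1, i2)`), `lengths` (`c(di1, di2, di3)`),
#'   `region_counts` (3x3 integer matrix, rows = regions, columns
#'   `n_plus`, `n_zero`, `n_minus`), `phi` (`c(max delta, min delta)`) and the
#'   total `counts`.
#' @export
path_partition <- function(ordered, delta = NULL,
                           boundary = c("closed", "open")) {
  boundary <- match.arg(boundary)
  ordered <- as.integer(ordered)
  counts <- microstate_counts(ordered)
  n <- counts$n
  theta <- cumulative_path(ordered)
  # integer-scaled delta: exact, so argmax/argmin ties are deterministic
  dsc <- .delta_scaled(theta, counts)
  interior <- dsc[-1L]                      # positions 1..N
  i_max <- which.max(interior)              # first maximum
  i_min <- which.min(interior)              # first minimum
  b <- sort(c(i_max, i_min))
  if (boundary == "open") b <- b - 1L
  lengths <- c(b[1], b[2] - b[1], n - b[2])
  region <- rep.int(1:3, times = lengths)
  rc <- matrix(0L, nrow = 3, ncol = 3,
               dimnames = list(paste0("region", 1:3),
                               c("n_plus", "n_zero", "n_minus")))
  for (p in 1:3) {
    m <- ordered[region == p]
    rc[p, ] <- c(sum(m == 1L), sum(m == 0L), sum(m == -1L))
  }
  slope <- null_line_slope(counts)
  delta_real <- delta_path(theta, slope)
  structure(
    list(
      i_max = i_max,
      i_min = i_min,
      boundaries = b,
      lengths = lengths,
      region_counts = rc,
      phi = c(phi1 = max(delta_real[-1L]), phi2 = min(delta_real[-1L])),
      counts = counts
    ),
    class = "gift_partition"
  )
}

#' @export
print.gift_partition <- function(x, ...) {
  cat("<gift_partition> boundaries (", x$boundaries[1], ", ", x$boundaries[2],
      ") of N = ", x$counts$n, "\n", sep = "")
  print(x$region_counts)
  invisible(x)
}

#' Log multinomial arrangement count
#'
#' `log( length! / (n_plus! n_zero! n_minus!) )` via `lgamma`; exact 0 for an
#' empty region. Log space is required: at `N = 565` the factorials overflow
#' any fixed-width numeric.
#'
#' @param length Region length.
#' @param counts Length-3 vector of per-type counts summing to `length`.
#' @return The log count (natural log).
#' @export
log_multinomial <- function(length, counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative region counts", call. = FALSE)
  if (!isTRUE(all.equal(sum(counts), as.numeric(length)))) {
    stop("region counts must sum to the region length", call. = FALSE)
  }
  lgamma(length + 1) - sum(lgamma(counts + 1))
}

#' Combinatorial path p-value
#'
#' Computes `p_hat = N1 N2 N3 / N0_path` entirely in log space from a path
#' partition. A monomorphic SNP has a single arrangement and `p_hat = 1`.
#'
#' @param partition A `"gift_partition"` object (or an ordered microstate
#'   string, which is partitioned first).
#'
#' @return A one-row tibble with `p_hat`, `mlog10_p_hat`, the boundaries and
#'   region lengths.
#'
#' @examples
#' gift_pvalue(c(1L, 1L, -1L, -1L))  # p_hat = 1/6
#' @export
gift_pvalue <- function(partition) {
  if (!inherits(partition, "gift_partition")) {
    partition <- path_partition(partition)
  }
  rc <- partition$region_counts
  totals <- .as_counts(partition$counts)
  n <- sum(totals)
  log_p <- sum(vapply(1:3, function(p) {
    log_multinomial(partition$lengths[p], rc[p, ])
  }, numeric(1))) - log_multinomial(n, totals)
  tibble::tibble(
    # exp() can underflow for extreme paths at very large N; the -log10
    # column is computed in log space and stays exact
    p_hat = max(exp(log_p), .Machine$double.xmin),
    mlog10_p_hat = -log_p / log(10),
    i1 = partition$boundaries[1],
    i2 = partition$boundaries[2],
    di1 = partition$lengths[1],
    di2 = partition$lengths[2],
    di3 = partition$lengths[3]
  )
}

# Internal: p_hat for an ordered string, scalar fast path.
.p_hat <- function(ordered) gift_pvalue(path_partition(ordered))$p_hat

#' Enumerate all arrangements of a microstate multiset
#'
#' Test-scale brute force: lists every distinct arrangement of the multiset
#' given by `counts`. Refuses `N > 10` (the count grows multinomially).
#'
#' @param counts Counts spec `(n_plus, n_zero, n_minus)`.
#' @return Integer matrix, one arrangement per row.
#' @export
enumerate_arrangements <- function(counts) {
  counts <- .as_counts(counts)
  n <- sum(counts)
  if (n > 10L) stop("refusing to enumerate arrangements for N > 10", call. = FALSE)
  if (n == 0L) return(matrix(integer(0), nrow = 1, ncol = 0))
  rec <- function(cnt) {
    if (sum(cnt) == 0L) return(list(integer(0)))
    out <- list()
    vals <- c(1L, 0L, -1L)
    for (j in 1:3) {
      if (cnt[j] > 0L) {
        cnt2 <- cnt
        cnt2[j] <- cnt2[j] - 1L
        for (tail in rec(cnt2)) out[[length(out) + 1L]] <- c(vals[j], tail)
      }
    }
    out
  }
  do.call(rbind, rec(counts))
}

#' Exhaustive null distribution of the path p-value
#'
#' Independent brute-force oracle for the combinatorial p-value: enumerates
#' every distinct arrangement of a small multiset, computes the pipeline
#' `p_hat` for each, and recomputes each arrangement's p-value a second way,
#' by *counting* the arrangements whose microstate composition matches the
#' focal arrangement's within its own extremum blocks. The two routes must
#' agree exactly; the counting route never touches the multinomial formula.
#'
#' @param counts Counts spec with total `N <= 8`.
#' @return A tibble with one row per arrangement: `arrangement` (string),
#'   `p_hat` (log-gamma route) and `p_count` (counting route).
#' @export
exhaustive_pvalue_oracle <- function(counts) {
  counts <- .as_counts(counts)
  n <- sum(counts)
  if (n > 8L) stop("exhaustive oracle limited to N <= 8", call. = FALSE)
  arr <- enumerate_arrangements(counts)
  n_arr <- nrow(arr)
  comp_in <- function(row, a, b) {
    # composition of arrangement `row` over positions (a, b]
    if (b <= a) return(c(0L, 0L, 0L))
    m <- row[(a + 1L):b]
    c(sum(m == 1L), sum(m == 0L), sum(m == -1L))
  }
  p_hat <- numeric(n_arr)
  p_count <- numeric(n_arr)
  parts <- vector("list", n_arr)
  for (k in seq_len(n_arr)) {
    parts[[k]] <- path_partition(arr[k, ])
    p_hat[k] <- gift_pvalue(parts[[k]])$p_hat
  }
  for (k in seq_len(n_arr)) {
    b <- parts[[k]]$boundaries
    target1 <- comp_in(arr[k, ], 0L, b[1])
    target2 <- comp_in(arr[k, ], b[1], b[2])
    hits <- 0L
    for (j in seq_len(n_arr)) {
      if (identical(comp_in(arr[j, ], 0L, b[1]), target1) &&
          identical(comp_in(arr[j, ], b[1], b[2]), target2)) {
        hits <- hits + 1L
      }
    }
    p_count[k] <- hits / n_arr
  }
  tibble::tibble(
    arrangement = apply(arr, 1L, paste, collapse = ","),
    p_hat = p_hat,
    p_count = p_count
  )
}

#' Calibrate empirical significance thresholds
#'
#' Simulates `K` permutation-null paths for each "theoretic" SNP (a bare
#' microstate-count specification), computes the path p-value of every
#' replicate, pools the `-log10 p_hat` values across SNPs, and takes the
#' 95th/99th percentiles of the pooled null distribution as the significance
#' thresholds. The null distribution is remarkably stable across microstate
#' frequencies and sample sizes, which is what makes a single genome-wide
#' threshold pair meaningful.
#'
#' @param theoretic_snps Counts: a data frame with columns
#'   `n_plus`, `n_zero`, `n_minus` (one row per theoretic SNP; see
#'   [theoretic_snp_presets()]) or a list of length-3 count vectors.
#' @param K Null replicates per SNP (default 1000; `K < 100` warns).
#' @param seed Integer master seed; each SNP gets a derived stream.
#' @param levels Confidence levels (default `c(0.95, 0.99)`).
#'
#' @return An object of class `"gift_thresholds"`: list with `level95`,
#'   `level99` (`-log10 p_hat` scale), `levels`, the pooled sample
#'   `pooled_mlog10`, a per-SNP summary tibble `per_snp`, and provenance
#'   (`K`, `seed`, the counts used).
#' @export
calibrate_thresholds <- function(theoretic_snps, K = 1000L, seed = 1L,
                                 levels = c(0.95, 0.99)) {
  if (is.data.frame(theoretic_snps)) {
    cl <- purrr::pmap(
      dplyr::select(theoretic_snps, "n_plus", "n_zero", "n_minus"),
      function(n_plus, n_zero, n_minus) c(n_plus, n_zero, n_minus)
    )
    labels <- if ("snp_id" %in% names(theoretic_snps)) {
      theoretic_snps$snp_id
    } else {
      paste0("theoretic", seq_along(cl))
    }
  } else {
    cl <- theoretic_snps
    labels <- paste0("theoretic", seq_along(cl))
  }
  stopifnot(length(cl) >= 1L)
  if (K < 100L) warning("K < 100 gives unstable threshold quantiles", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  per_snp <- purrr::map2(cl, labels, function(counts, label) {
    counts <- .as_counts(counts)
    if (sum(counts) < 3L) stop("theoretic SNP needs N >= 3", call. = FALSE)
    set.seed(.derive_seed(seed, label))
    values <- .counts_to_values(counts)
    mono <- sum(counts > 0L) <= 1L
    if (mono) warning("monomorphic theoretic SNP '", label,
                      "': degenerate null (p_hat = 1)", call. = FALSE)
    mlog10 <- vapply(seq_len(K), function(k) {
      -log10(.p_hat(sample(values)))
    }, numeric(1))
    tibble::tibble(snp_id = label, mlog10 = mlog10)
  })
  pooled <- unlist(purrr::map(per_snp, "mlog10"), use.names = FALSE)
  qs <- stats::quantile(pooled, probs = levels, names = FALSE)
  per_snp_summary <- dplyr::bind_rows(per_snp) |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      median = stats::median(.data$mlog10),
      q95 = stats::quantile(.data$mlog10, 0.95),
      q99 = stats::quantile(.data$mlog10, 0.99),
      .groups = "drop"
    )
  structure(
    list(
      level95 = unname(if (0.95 %in% levels) qs[match(0.95, levels)] else qs[1]),
      level99 = unname(if (0.99 %in% levels) qs[match(0.99, levels)] else qs[length(qs)]),
      levels = stats::setNames(qs, paste0("q", levels * 100)),
      pooled_mlog10 = pooled,
      per_snp = per_snp_summary,
      K = as.integer(K),
      seed = seed,
      theoretic_snps = purrr::map(cl, .as_counts)
    ),
    class = "gift_thresholds"
  )
}

#' @export
print.gift_thresholds <- function(x, ...) {
  cat("<gift_thresholds> from", length(x$theoretic_snps), "theoretic SNPs x K =",
      x$K, "null paths\n")
  cat("  95% threshold: -log10 p_hat =", format(x$level95, digits = 5), "\n")
  cat("  99% threshold: -log10 p_hat =", format(x$level99, digits = 5), "\n")
  invisible(x)
}

#' Tidy calibrated thresholds
#'
#' @param x A `"gift_thresholds"` object.
#' @param ... Unused.
#' @return Tibble with one row per confidence level.
#' @export
tidy.gift_thresholds <- function(x, ...) {
  tibble::tibble(
    level = as.numeric(sub("^q", "", names(x$levels))) / 100,
    mlog10_threshold = as.numeric(x$levels)
  )
}

#' Calibrate path scores to empirical null p-values
#'
#' The combinatorial score `p_hat` is far sub-uniform under the permutation
#' null (the extremum partition is an extreme-value selection), so it cannot
#' be fed to a false-discovery-rate procedure directly. This converts
#' observed `-log10 p_hat` values to proper empirical p-values against the
#' pooled null sample held by a `"gift_thresholds"` object:
#' `p_emp = (1 + #null >= observed) / (1 + #null)`. These are approximately
#' uniform under the null and are the quantities Benjamini-Hochberg can
#' legitimately control.
#'
#' @param mlog10_p_hat Observed `-log10 p_hat` values.
#' @param thresholds A `"gift_thresholds"` calibration object.
#' @return Empirical p-values in `(0, 1]`.
#' @seealso [bh_adjust()]
#' @export
null_calibrated_pvalues <- function(mlog10_p_hat, thresholds) {
  stopifnot(inherits(thresholds, "gift_thresholds"))
  null_sorted <- sort(thresholds$pooled_mlog10)
  n0 <- length(null_sorted)
  # #null >= x via binary search on the sorted pooled sample
  below <- findInterval(mlog10_p_hat - 1e-12, null_sorted)
  (1 + (n0 - below)) / (1 + n0)
}

#' Benjamini-Hochberg adjustment of path p-values
#'
#' Standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), with contract checks: inputs must lie in `(0, 1]`,
#' outputs are monotone in the raw ranks, capped at 1, and never smaller
#' than the raw values.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
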