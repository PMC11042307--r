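# Permutation null model for genetic paths.
#
# With the phenotype information removed, the only structure left in a SNP's
# microstate string is its counts (N+, N0, N-). Scrambling the string gives
# one realisation theta0(i) of the null path; the ensemble over scrambles has
# mean slope*i and a sampling-without-replacement partial-sum variance
#   Var theta0(i) = i (N - i) / (N - 1) * sigma2_m,
# where sigma2_m is the population variance of the N microstate values. The
# variance is quadratic in i/N and, once sd is normalised by sqrt(N),
# independent of the sample size at fixed microstate frequencies.

#' One permutation-null path realisation
#'
#' Uniformly shuffles a microstate multiset and returns its cumulative path.
#'
#' @param microstate Integer microstate values (`NA` dropped), or a one-row
#'   counts tibble as returned by [microstate_counts()].
#' @return Numeric `theta0` of length `N + 1`.
#' @export
permute_path <- function(microstate) {
  if (is.data.frame(microstate)) {
    values <- .counts_to_values(microstate)
  } else {
    values <- as.integer(microstate[!is.na(microstate)])
  }
  if (!length(values)) stop("empty microstate vector", call. = FALSE)
  cumulative_path(sample(values))
}

#' Simulate the permutation null ensemble of a SNP
#'
#' Generates `K` scrambles of the microstate multiset and summarises the
#' resulting paths position by position.
#'
#' @param counts Counts spec `(n_plus, n_zero, n_minus)` (vector or one-row
#'   tibble).
#' @param K Number of replicates (default 1000).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return An object of class `"gift_null_ensemble"`: a list with `counts`,
#'   `K`, `seed` and `summary`, a tibble with columns `position`, `mean`,
#'   `sd`, `rel_position` (`i/N`) and `normalized_sd` (`sd / sqrt(N)`).
#'
#' @seealso [null_variance()] for the closed-form variance.
#' @export
simulate_null_ensemble <- function(counts, K = 1000L, seed = NULL) {
  counts <- .as_counts(counts)
  stopifnot(K >= 1L)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  values <- .counts_to_values(counts)
  n <- length(values)
  # K x (N+1) matrix of paths; trivial memory at the sample sizes used here
  paths <- vapply(seq_len(K), function(k) cumulative_path(sample(values)),
                  numeric(n + 1L))
  mean_path <- rowMeans(paths)
  sd_path <- if (K > 1L) apply(paths, 1L, stats::sd) else rep(0, n + 1L)
  structure(
    list(
      counts = microstate_counts(values),
      K = as.integer(K),
      seed = seed,
      summary = tibble::tibble(
        position = 0:n,
        mean = mean_path,
        sd = sd_path,
        rel_position = (0:n) / n,
        normalized_sd = sd_path / sqrt(n)
      )
    ),
    class = "gift_null_ensemble"
  )
}

#' Closed-form variance of the null path
#'
#' Analytic variance of the partial sum of a uniformly permuted finite
#' population of microstate values:
#' \deqn{\mathrm{Var}\,\theta_0(i) = \frac{i (N - i)}{N - 1}\,\sigma^2_m,}
#' with \eqn{\sigma^2_m} the population variance of the `N` values. Serves as
#' the fast analytic oracle for the simulated ensemble.
#'
#' @param counts Counts spec `(n_plus, n_zero, n_minus)`.
#' @param i Integer position(s) in `0..N`.
#' @return Variance of `theta0(i)`, vectorised over `i`.
#' @export
null_variance <- function(counts, i) {
  counts <- .as_counts(counts)
  n <- sum(counts)
  if (any(i < 0 | i > n)) stop("position out of range 0..N", call. = FALSE)
  if (n <= 1L) return(rep(0, length(i)))
  mu <- (counts[1] - counts[3]) / n
  sigma2_m <- (counts[1] + counts[3]) / n - mu^2
  i * (n - i) / (n - 1) * sigma2_m
}

#' @export
print.gift_null_ensemble <- function(x, ...) {
  cat("<gift_null_ensemble> K =", x$K, "replicates, N =", x$counts$n, "\n")
  cat("  counts: N+ =", x$counts$n_plus, " N0 =", x$counts$n_zero,
      " N- =", x$counts$n_minus, "\n")
  invisible(x)
}

#' Tidy a null ensemble
#'
#' @param x A `"gift_null_ensemble"` object.
#' @param ... Unused.
#' @return The per-position summary tibble.
#' @export
tidy.gift_null_ensemble <- function(x, ...) x$summary

#' Export a null-ensemble envelope as TSV
#'
#' Writes `position mean sd` for envelope plots.
#'
#' @param x A `"gift_null_ensemble"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(x, path) {
  stopifnot(inherits(x, "gift_null_ensemble"))
  readr::write_tsv(dplyr::select(x$summary, "position", "mean", "sd"), path)
  invisible(path)
}

# Internal seed bracketing helpers: save/restore the global RNG state so a
# seeded call does not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Internal: derive a per-label RNG seed below 2^31 from a master seed and a
# string label (stable FNV-style hash), so per-SNP results are independent of
# processing order.
.derive_seed <- function(master, label) {
  # multiplicative-xor string hash; multiplier kept small so every product
  # stays below 2^53 and the arithmetic is exact in doubles
  h <- 19661366
  for (b in utf8ToInt(paste0(label, ":", master))) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 69069) %% 2147483647
  }
  as.integer(h %% 2147483629) + 1L
}
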