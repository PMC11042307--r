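# Genetic paths: phenotype-ranked cumulative sums of microstates.
#
# For one SNP with microstate counts (N+, N0, N-), individuals are ordered by
# ascending phenotypic residual and the microstates are cumulatively summed:
#   theta(0) = 0,  theta(i) = theta(i-1) + m_(i).
# Under random ordering the expected path is the straight line
#   theta0(i) = tan(alpha) * i,   tan(alpha) = (N+ - N-) / N,
# and all structure lives in the difference Delta(i) = theta(i) - theta0(i),
# which is anchored at 0 at both ends because theta(N) = N+ - N- exactly.

#' Order microstates by ascending phenotypic residual
#'
#' Ranks individuals by residual value, smallest first, and returns their
#' microstates in that order. Ties are broken by input (canonical) order, so
#' the result is deterministic.
#'
#' @param residuals Numeric vector of phenotypic residuals, all finite.
#' @param microstate Integer microstates of the same individuals, same length.
#'
#' @return Integer vector: the microstate string in residual order.
#' @export
rank_by_phenotype <- function(residuals, microstate) {
  if (length(residuals) != length(microstate)) {
    stop("`residuals` and `microstate` must cover the same individuals ",
         "(lengths ", length(residuals), " vs ", length(microstate), ")",
         call. = FALSE)
  }
  if (any(!is.finite(residuals))) {
    stop("non-finite residual value at position ",
         which(!is.finite(residuals))[1L], call. = FALSE)
  }
  microstate[order(residuals)]
}

#' Cumulative genetic path
#'
#' @param ordered Integer microstate string in residual order.
#' @return Numeric vector `theta` of length `N + 1` with `theta[1] = 0`
#'   (position 0) and increments equal to the microstates.
#' @export
cumulative_path <- function(ordered) {
  stopifnot(length(ordered) >= 1L)
  c(0, cumsum(as.numeric(ordered)))
}

#' Slope of the asymptotic null path
#'
#' The permutation-mean path is the line `theta0(i) = slope * i` with
#' `slope = (N+ - N-) / N`.
#'
#' @param counts Microstate counts: a one-row tibble from
#'   [microstate_counts()] or a length-3 vector `(n_plus, n_zero, n_minus)`.
#' @return The slope as a double in `[-1, 1]`.
#' @export
null_line_slope <- function(counts) {
  counts <- .as_counts(counts)
  n <- sum(counts)
  if (n == 0L) stop("degenerate SNP: no called genotypes", call. = FALSE)
  (counts[1] - counts[3]) / n
}

#' Difference path relative to the null line
#'
#' @param theta Cumulative path from [cumulative_path()].
#' @param slope Null slope from [null_line_slope()].
#' @return Numeric `delta` with `delta[i] = theta[i] - slope * i` over
#'   positions `0..N`; both endpoints are 0 up to floating point.
#' @export
delta_path <- function(theta, slope) {
  theta - slope * (seq_along(theta) - 1)
}

# Internal: integer-scaled delta, N * delta(i) = N*theta(i) - (N+ - N-)*i.
# Exact integer arithmetic makes extremum ties deterministic.
.delta_scaled <- function(theta, counts) {
  counts <- .as_counts(counts)
  n <- sum(counts)
  dn <- counts[1] - counts[3]
  as.integer(round(n * theta)) - dn * (seq_along(theta) - 1L)
}

#' Build the genetic path of one SNP
#'
#' One-stop constructor: drops individuals with a missing microstate
#' (pairwise deletion), orders the rest by ascending residual, and assembles
#' the cumulative path `theta(i)`, the null line slope, and the anchored
#' difference `delta(i)`.
#'
#' @param residuals Numeric phenotypic residuals, one per individual.
#' @param microstate Integer microstates (`NA` = missing call).
#' @param snp_id Optional SNP label carried in the result.
#'
#' @return An object of class `"gift_path"`: a list with elements
#'   `snp_id`, `counts` (one-row tibble), `slope`, `ordered` (the microstate
#'   string), and `path`, a tibble with columns `position` (`0..N`), `theta`,
#'   `delta` and `microstate` (the increment leading into each position,
#'   `NA` at position 0).
#'
#' @examples
#' gp <- genetic_path(c(3, 1, 2), c(1L, -1L, 0L))
#' gp$path
#' @export
genetic_path <- function(residuals, microstate, snp_id = NULL) {
  if (length(residuals) != length(microstate)) {
    stop("`residuals` and `microstate` must have the same length", call. = FALSE)
  }
  keep <- !is.na(microstate)
  residuals <- residuals[keep]
  microstate <- microstate[keep]
  if (!length(microstate)) stop("degenerate SNP: no called genotypes", call. = FALSE)
  counts <- microstate_counts(microstate)
  ordered <- rank_by_phenotype(residuals, microstate)
  theta <- cumulative_path(ordered)
  slope <- null_line_slope(counts)
  delta <- delta_path(theta, slope)
  structure(
    list(
      snp_id = snp_id,
      counts = counts,
      slope = slope,
      ordered = as.integer(ordered),
      path = tibble::tibble(
        position = seq_along(theta) - 1L,
        theta = theta,
        delta = delta,
        microstate = c(NA_integer_, as.integer(ordered))
      )
    ),
    class = "gift_path"
  )
}

#' @export
print.gift_path <- function(x, ...) {
  cat("<gift_path>",
      if (!is.null(x$snp_id)) paste0(" ", x$snp_id), "\n", sep = "")
  cat("  N = ", x$counts$n,
      "  (N+ = ", x$counts$n_plus,
      ", N0 = ", x$counts$n_zero,
      ", N- = ", x$counts$n_minus, ")\n", sep = "")
  cat("  null slope = ", format(x$slope, digits = 6),
      ";  max |delta| = ", format(max(abs(x$path$delta)), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Tidy a genetic path
#'
#' @param x A `"gift_path"` object.
#' @param ... Unused.
#' @return The per-position path tibble (`position`, `theta`, `delta`,
#'   `microstate`).
#' @export
tidy.gift_path <- function(x, ...) x$path

#' One-row summary of a genetic path
#'
#' @param x A `"gift_path"` object.
#' @param ... Unused.
#' @return Tibble with the counts, null slope and extreme `delta` amplitudes.
#' @export
glance.gift_path <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(snp_id = x$snp_id %||% NA_character_),
    x$counts,
    tibble::tibble(
      slope = x$slope,
      delta_max = max(x$path$delta),
      delta_min = min(x$path$delta)
    )
  )
}

#' Export a genetic path as TSV
#'
#' Writes the per-position table `position theta delta microstate`.
#'
#' @param x A `"gift_path"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_path_tsv <- function(x, path) {
  stopifnot(inherits(x, "gift_path"))
  readr::write_tsv(x$path, path)
  invisible(path)
}
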