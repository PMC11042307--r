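# Microstate encoding of diploid genotype calls.
#
# A bi-allelic genotype is collapsed to one of three "microstates":
#   +1  for A/A and T/T homozygotes,
#   -1  for G/G and C/C homozygotes,
#    0  for everything else (heterozygotes and ambiguous A/T, G/C pairs).
# Missing calls stay missing and are dropped SNP-wise downstream (pairwise
# deletion): an imputed 0 would distort the genetic path, a dropped
# individual merely shortens it.

.MISSING_CALL <- "NN"

#' Encode diploid genotype calls as microstates
#'
#' Collapses two-letter genotype calls to the three-valued microstate code
#' used throughout the package: `+1` for A/A or T/T, `-1` for G/G or C/C,
#' `0` for any other non-missing pair. The encoding is symmetric in allele
#' order, so `"AG"` and `"GA"` both give `0`.
#'
#' @param call Character vector of two-letter calls (`"AA"`, `"AG"`, ...),
#'   with `"NN"` or `NA` marking a missing call.
#' @param snp_id,individual_id Optional identifiers used to contextualise an
#'   invalid-allele error.
#'
#' @return Integer vector in `{-1, 0, 1}` with `NA` for missing calls.
#'
#' @examples
#' encode_genotype(c("AA", "GG", "AG", "TT", "NN"))
#' @export
encode_genotype <- function(call, snp_id = NULL, individual_id = NULL) {
  call <- toupper(as.character(call))
  missing <- is.na(call) | call == .MISSING_CALL
  bad_shape <- !missing & nchar(call) != 2L
  letters_ok <- !missing & !bad_shape &
    grepl("^[ACGT][ACGT]$", call)
  bad <- !missing & !letters_ok
  if (any(bad)) {
    i <- which(bad)[1L]
    ctx <- ""
    if (!is.null(snp_id)) ctx <- paste0(ctx, " at SNP ", snp_id[min(i, length(snp_id))])
    if (!is.null(individual_id)) {
      ctx <- paste0(ctx, " for individual ", individual_id[min(i, length(individual_id))])
    }
    stop("invalid allele call '", call[i], "'", ctx,
         ": alleles must be A, C, G or T (or 'NN' for missing)", call. = FALSE)
  }
  out <- rep(0L, length(call))
  out[call %in% c("AA", "TT")] <- 1L
  out[call %in% c("GG", "CC")] <- -1L
  out[missing] <- NA_integer_
  out
}

#' Encode a genotype table into microstates
#'
#' Applies [encode_genotype()] to every call of a long genotype table,
#' preserving individual order within each SNP.
#'
#' @param genotypes A tibble in the package's long genotype layout with
#'   columns `snp_id`, `id`, `call` (optionally `chrom`, `pos`, carried
#'   through).
#'
#' @return The input tibble with a `microstate` integer column appended
#'   (`NA` for missing calls) and `call` retained.
#'
#' @seealso [microstate_counts()], [genetic_path()]
#' @export
encode_genotypes <- function(genotypes) {
  stopifnot(is.data.frame(genotypes))
  req <- c("snp_id", "id", "call")
  if (!all(req %in% names(genotypes))) {
    stop("`genotypes` must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(genotypes),
    microstate = encode_genotype(.data$call, snp_id = .data$snp_id,
                                 individual_id = .data$id)
  )
}

#' Tally microstate counts
#'
#' Counts non-missing microstates of each type. The counts
#' \eqn{(N_+, N_0, N_-)} and their total \eqn{N} parameterise the
#' permutation null model: every arrangement statistic downstream depends on
#' the microstate vector only through them and the ordering.
#'
#' @param microstate Integer vector in `{-1, 0, 1}`, `NA` allowed.
#'
#' @return A one-row tibble with columns `n_plus`, `n_zero`, `n_minus`, `n`.
#'
#' @examples
#' microstate_counts(c(1L, 0L, -1L, NA))
#' @export
microstate_counts <- function(microstate) {
  m <- microstate[!is.na(microstate)]
  if (length(m) && !all(m %in% c(-1L, 0L, 1L))) {
    stop("microstates must be -1, 0 or +1", call. = FALSE)
  }
  tibble::tibble(
    n_plus = sum(m == 1L),
    n_zero = sum(m == 0L),
    n_minus = sum(m == -1L),
    n = length(m)
  )
}

# Internal: validate a counts spec given as (possibly named) length-3 vector,
# one-row data frame, or list. Returns c(n_plus, n_zero, n_minus).
.as_counts <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- c(counts$n_plus[1], counts$n_zero[1], counts$n_minus[1])
  } else if (!is.null(names(counts)) &&
             all(c("n_plus", "n_zero", "n_minus") %in% names(counts))) {
    counts <- c(counts[["n_plus"]], counts[["n_zero"]], counts[["n_minus"]])
  }
  counts <- as.integer(counts[1:3])
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be three non-negative integers (n_plus, n_zero, n_minus)",
         call. = FALSE)
  }
  counts
}

# Internal: expand counts to the canonical microstate value vector
# (+1 block, 0 block, -1 block) -- order is irrelevant for permutation work.
.counts_to_values <- function(counts) {
  counts <- .as_counts(counts)
  rep(c(1L, 0L, -1L), times = counts)
}
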