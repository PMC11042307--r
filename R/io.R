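# Genotype and phenotype readers/writers.
#
# Canonical in-memory layout is a long tibble: one row per (SNP, individual)
# with columns snp_id, chrom, pos, id, call. Three on-disk formats map onto
# it: the package's TSV dialect, VCF (diploid GT resolved to REF/ALT base
# letters), and PLINK ped/map.

#' Read genotypes
#'
#' @param path Input file. For `format = "ped"` this is the `.ped` file and
#'   a sibling `.map` is expected (or pass `map`).
#' @param format One of `"tsv"`, `"vcf"`, `"ped"`.
#' @param map Optional `.map` path for PLINK input.
#'
#' @return Long genotype tibble with columns `snp_id`, `chrom`, `pos`, `id`,
#'   `call` (two-letter strings, `"NN"` for missing).
#'
#' @section TSV dialect:
#' Header row `id <snp1> <snp2> ...`; one row per individual; cells are
#' two-letter allele strings (`"AA"`, `"AG"`, ...) or `"NN"` for missing.
#' Chromosome defaults to `"0"` (unplaced) and position to the column index.
#'
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "ped"), map = NULL) {
  format <- match.arg(format)
  switch(format,
    tsv = .read_genotypes_tsv(path),
    vcf = .read_genotypes_vcf(path),
    ped = .read_genotypes_ped(path, map)
  )
}

.read_genotypes_tsv <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (names(wide)[1] != "id") {
    stop("genotype TSV must start with an 'id' column (got '",
         names(wide)[1], "')", call. = FALSE)
  }
  if (anyDuplicated(wide$id)) stop("duplicate individual ids", call. = FALSE)
  snps <- names(wide)[-1]
  long <- tidyr::pivot_longer(wide, -"id", names_to = "snp_id",
                              values_to = "call")
  long |>
    dplyr::mutate(
      chrom = "0",
      pos = match(.data$snp_id, snps),
      call = dplyr::coalesce(.data$call, .MISSING_CALL)
    ) |>
    dplyr::select("snp_id", "chrom", "pos", "id", "call") |>
    dplyr::arrange(match(.data$snp_id, snps), match(.data$id, wide$id))
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  n_snp <- nrow(gt)
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, ":", fix$POS), fix$ID)
  resolve <- function(gt_str, ref, alt) {
    # diploid GT indices -> base letters; any half-call or '.' -> missing
    if (is.na(gt_str)) return(.MISSING_CALL)
    alleles <- strsplit(gt_str, "[/|]")[[1]]
    if (length(alleles) != 2L || any(alleles == ".")) return(.MISSING_CALL)
    lut <- c(ref, strsplit(alt, ",")[[1]])
    idx <- as.integer(alleles) + 1L
    if (any(is.na(idx)) || any(idx > length(lut))) return(.MISSING_CALL)
    paste0(lut[idx[1]], lut[idx[2]])
  }
  rows <- purrr::map(seq_len(n_snp), function(i) {
    tibble::tibble(
      snp_id = snp_id[i],
      chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]),
      id = ids,
      call = unname(vapply(gt[i, ], resolve, character(1),
                           ref = fix$REF[i], alt = fix$ALT[i]))
    )
  })
  dplyr::bind_rows(rows)
}

.read_genotypes_ped <- function(path, map = NULL) {
  map_path <- map %||% sub("\\.ped$", ".map", path)
  if (!file.exists(map_path)) {
    stop("PLINK .map file not found: ", map_path, call. = FALSE)
  }
  map_df <- utils::read.table(map_path, header = FALSE,
                              colClasses = "character")
  names(map_df)[1:4] <- c("chrom", "snp_id", "cm", "pos")
  ped <- utils::read.table(path, header = FALSE, colClasses = "character")
  n_snp <- nrow(map_df)
  if (ncol(ped) != 6 + 2 * n_snp) {
    stop("ped/map mismatch: ", ncol(ped), " ped columns for ", n_snp,
         " map SNPs", call. = FALSE)
  }
  ids <- ped[[2]]
  rows <- purrr::map(seq_len(n_snp), function(i) {
    a1 <- ped[[6 + 2 * i - 1]]
    a2 <- ped[[6 + 2 * i]]
    call <- ifelse(a1 == "0" | a2 == "0", .MISSING_CALL, paste0(a1, a2))
    tibble::tibble(
      snp_id = map_df$snp_id[i],
      chrom = map_df$chrom[i],
      pos = as.integer(map_df$pos[i]),
      id = ids,
      call = call
    )
  })
  dplyr::bind_rows(rows)
}

#' Write genotypes in the TSV dialect
#'
#' @param genotypes Long genotype tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  snp_order <- unique(genotypes$snp_id)
  id_order <- unique(genotypes$id)
  wide <- genotypes |>
    dplyr::select("id", "snp_id", "call") |>
    tidyr::pivot_wider(names_from = "snp_id", values_from = "call") |>
    dplyr::select("id", dplyr::all_of(snp_order)) |>
    dplyr::arrange(match(.data$id, id_order))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path TSV with an `id` column and one or more value columns.
#' @param log_transform Apply the natural logarithm to `phenotype_col`.
#' @param phenotype_col Column to transform (default `"phenotype"`).
#' @return Tibble; errors on duplicate ids.
#' @export
read_phenotypes <- function(path, log_transform = FALSE,
                            phenotype_col = "phenotype") {
  ph <- readr::read_tsv(path, col_types = readr::cols(id = "c", .default = "?"),
                        progress = FALSE)
  if (!"id" %in% names(ph)) stop("phenotype TSV needs an 'id' column", call. = FALSE)
  if (anyDuplicated(ph$id)) {
    stop("duplicate phenotype ids: ",
         paste(unique(ph$id[duplicated(ph$id)]), collapse = ", "), call. = FALSE)
  }
  if (log_transform) {
    if (!phenotype_col %in% names(ph)) {
      stop("column '", phenotype_col, "' not found", call. = FALSE)
    }
    if (any(ph[[phenotype_col]] <= 0, na.rm = TRUE)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    ph[[phenotype_col]] <- log(ph[[phenotype_col]])
  }
  ph
}
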