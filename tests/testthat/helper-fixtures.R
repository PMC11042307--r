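# Shared in-code fixtures: everything is generated, nothing read from disk
# except files the tests write themselves.

# small long genotype tibble: 2 SNPs x 3 individuals
tiny_genotypes <- function() {
  tibble::tibble(
    snp_id = rep(c("s1", "s2"), each = 3),
    chrom = rep(c("1", "2"), each = 3),
    pos = rep(c(100L, 200L), each = 3),
    id = rep(c("a", "b", "c"), times = 2),
    call = c("AA", "AG", "GG", "TT", "NN", "CC")
  )
}

# a minimal VCF text fixture written to a temp file
write_tiny_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tT\tC\t.\tPASS\t.\tGT\t0|0\t./.\t0/1"
  )
  writeLines(lines, path)
  path
}

# minimal PLINK ped/map pair
write_tiny_ped <- function(dir) {
  ped <- file.path(dir, "tiny.ped")
  map <- file.path(dir, "tiny.map")
  writeLines(c(
    "F1 a 0 0 1 -9 A A T T",
    "F1 b 0 0 2 -9 A G 0 0",
    "F1 c 0 0 1 -9 G G T C"
  ), ped)
  writeLines(c(
    "1 rs1 0 100",
    "1 rs2 0 200"
  ), map)
  list(ped = ped, map = map)
}

# all (n_plus, n_zero, n_minus) compositions with total n
all_count_compositions <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) {
    out[[length(out) + 1L]] <- c(a, b, n - a - b)
  }
  out
}
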