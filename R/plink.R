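#' Read a PLINK 1 binary fileset
#'
#' Reads a `.bed`/`.bim`/`.fam` triple into a [`genotype_dataset`] holding the
#' pedigree table, the variant table and an integer genotype matrix coded as
#' copies of allele2 (the `.bim` A2 column): 0, 1, 2 or `NA` for missing.
#'
#' The `.bed` file must be in SNP-major mode (magic bytes `0x6C 0x1B`, mode
#' byte `0x01`). Each byte packs four samples, two bits each, least-significant
#' pair first: `00` = homozygous allele1 (code 0), `10` = heterozygous
#' (code 1), `11` = homozygous allele2 (code 2), `01` = missing.
#'
#' @param bed_path Path to the `.bed` file.
#' @param bim_path Path to the `.bim` file; defaults to `bed_path` with the
#'   extension swapped.
#' @param fam_path Path to the `.fam` file; same default rule.
#' @return A `genotype_dataset`: a list with elements `fam` (data frame:
#'   `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`,
#'   `affection`), `bim` (data frame: `rsid`, `chrom`, `cm`, `pos`, `allele1`,
#'   `allele2`) and `geno` (integer matrix, samples x SNPs, dimnames set to
#'   individual ids and rsids).
#' @seealso [write_plink()], [assemble_triads()]
#' @examples
#' d <- simulate_triads(n_triads = 20, q = 0.3, seed = 1)
#' pre <- file.path(tempdir(), "toy")
#' write_plink(d$dataset, pre)
#' d2 <- read_plink(paste0(pre, ".bed"))
#' identical(d2$geno, d$dataset$geno)
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)

  fam <- utils::read.table(fam_path, header = FALSE, colClasses = "character",
                           col.names = c("family_id", "individual_id", "father_id",
                                         "mother_id", "sex", "affection"))
  fam$sex <- as.integer(fam$sex)
  fam$affection <- as.integer(fam$affection)
  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character",
                           col.names = c("chrom", "rsid", "cm", "pos",
                                         "allele1", "allele2"))
  bim$pos <- as.integer(bim$pos)
  bim$cm <- as.numeric(bim$cm)
  bim <- bim[, c("rsid", "chrom", "cm", "pos", "allele1", "allele2")]
  if (anyDuplicated(bim$rsid)) stop("duplicate rsids in ", bim_path)

  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B))
    stop("not a PLINK 1 .bed file (bad magic bytes): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop(".bed not in SNP-major mode: ", bed_path)
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m)
    stop(".bed truncated or wrong dimensions: expected ",
         bytes_per_snp * m, " data bytes, found ", length(body))

  geno <- .bed_decode(body, n, m)
  dimnames(geno) <- list(fam$individual_id, bim$rsid)
  genotype_dataset(fam, bim, geno)
}

# decode SNP-major packed bytes to an n x m integer matrix
.bed_decode <- function(body, n, m) {
  lut <- .plink_code_lut()           # 256 x 4 matrix of codes per byte
  bytes <- matrix(as.integer(body), ncol = m)   # bytes_per_snp x m
  codes <- lut[bytes + 1L, , drop = FALSE]      # (bytes_per_snp*m) x 4
  # rows are byte-order within column-major layout; expand to samples
  full <- matrix(t(codes), nrow = 4 * nrow(bytes), ncol = m)
  full[seq_len(n), , drop = FALSE]
}

# 2-bit pair -> code: 00 -> 0, 10 -> 1, 11 -> 2, 01 -> NA
.plink_code_lut <- function() {
  pair_code <- c(0L, NA_integer_, 1L, 2L)  # index by pair value 0..3
  b <- 0:255
  cbind(pair_code[b %% 4L + 1L],
        pair_code[(b %/% 4L) %% 4L + 1L],
        pair_code[(b %/% 16L) %% 4L + 1L],
        pair_code[(b %/% 64L) %% 4L + 1L])
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: writes `prefix.bed` (SNP-major), `prefix.bim`
#' and `prefix.fam`. Round-trips bit-exactly with [read_plink()].
#'
#' @param dataset A [`genotype_dataset`].
#' @param prefix Output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  fam <- dataset$fam
  bim <- dataset$bim
  geno <- dataset$geno
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(bim[, c("chrom", "rsid", "cm", "pos", "allele1", "allele2")],
                     paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  n <- nrow(geno)
  pair_bits <- c(0L, 2L, 3L)  # code 0,1,2 -> pair value; NA -> 1
  enc <- matrix(1L, nrow = 4 * ceiling(n / 4), ncol = ncol(geno))
  g <- geno
  v <- ifelse(is.na(g), 1L, pair_bits[g + 1L])
  enc[seq_len(n), ] <- v
  # pad slots beyond n encode as 0 (hom allele1), per plink convention
  if (nrow(enc) > n) enc[(n + 1):nrow(enc), ] <- 0L
  idx <- seq(1, nrow(enc), by = 4)
  bytes <- enc[idx, , drop = FALSE] +
    4L * enc[idx + 1, , drop = FALSE] +
    16L * enc[idx + 2, , drop = FALSE] +
    64L * enc[idx + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Construct a genotype dataset
#'
#' Low-level constructor validating the container invariants: matrix
#' dimensions match the pedigree and variant tables, codes are in
#' \{0, 1, 2, NA\}, rsids and individual ids are unique.
#'
#' @param fam Pedigree data frame (`family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `affection`).
#' @param bim Variant data frame (`rsid`, `chrom`, `cm`, `pos`, `allele1`,
#'   `allele2`).
#' @param geno Integer matrix of allele2 dosage codes, samples x SNPs.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(fam, bim, geno) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(fam) || ncol(geno) != nrow(bim))
    stop("genotype matrix must be n_samples x n_snps")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be in {0, 1, 2, NA}")
  if (anyDuplicated(bim$rsid)) stop("rsids must be unique")
  if (anyDuplicated(fam$individual_id)) stop("individual ids must be unique")
  dimnames(geno) <- list(fam$individual_id, bim$rsid)
  structure(list(fam = fam, bim = bim, geno = geno),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$fam), "samples,", nrow(x$bim), "SNPs\n")
  cat("  missing rate:",
      format(mean(is.na(x$geno)), digits = 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)
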