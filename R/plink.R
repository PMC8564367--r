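# PLINK 1 binary (bed/bim/fam) input/output.
#
# bed v1.0, SNP-major: magic bytes 0x6c 0x1b 0x01, then per variant
# ceiling(n_samples / 4) bytes, two bits per sample, sample 1 in the two
# lowest-order bits. Two-bit codes: 00 = homozygous A1, 01 = missing,
# 10 = heterozygous, 11 = homozygous A2. The bim A1 allele is treated as
# the alternative (counted) allele, so code 00 maps to dosage 2.

# dosage lookup by 2-bit code 0..3
.bed_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)
.bed_dosage_to_code <- function(g) {
  out <- integer(length(g))
  out[is.na(g)] <- 1L
  out[!is.na(g) & g == 2L] <- 0L
  out[!is.na(g) & g == 1L] <- 2L
  out[!is.na(g) & g == 0L] <- 3L
  out
}

#' Read a PLINK bed/bim/fam fileset
#'
#' @param bed_path,bim_path,fam_path paths to the three files. `bim_path`
#'   and `fam_path` default to `bed_path` with the extension swapped.
#' @return A [genotype_dataset()]. Dosage counts the bim A1 allele
#'   (stored as `alt`); fam phenotype 2 maps to case (1), 1 to control (0),
#'   0/-9 to `NA`.
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (f in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "vid", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "integer"))
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")

  n_samples <- nrow(fam)
  n_variants <- nrow(bim)
  bytes_per_variant <- ceiling(n_samples / 4)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 ||
      raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01)) {
    stop("not a SNP-major PLINK v1.0 bed file: ", bed_path, call. = FALSE)
  }
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_variant * n_variants) {
    stop(sprintf(
      "bed payload of %s (%d bytes) inconsistent with %d samples x %d variants",
      bed_path, length(payload), n_samples, n_variants
    ), call. = FALSE)
  }

  b <- matrix(as.integer(payload), nrow = bytes_per_variant, ncol = n_variants)
  geno <- matrix(NA_integer_, nrow = n_samples, ncol = n_variants)
  for (k in 0:3) {                      # sample slot within byte
    rows <- seq.int(1 + k, by = 4, length.out = bytes_per_variant)
    rows <- rows[rows <= n_samples]
    if (!length(rows)) next
    code <- (b[seq_along(rows), , drop = FALSE] %/% 4L^k) %% 4L
    geno[rows, ] <- .bed_code_to_dosage[code + 1L]
  }

  phenotype <- ifelse(fam$pheno == 2L, 1L,
                      ifelse(fam$pheno == 1L, 0L, NA_integer_))
  genotype_dataset(
    geno,
    data.frame(chrom = bim$chrom, pos = bim$pos, vid = bim$vid,
               ref = bim$a2, alt = bim$a1, stringsAsFactors = FALSE),
    data.frame(sid = fam$iid, phenotype = phenotype,
               stringsAsFactors = FALSE)
  )
}

#' Write a genotype dataset as PLINK bed/bim/fam
#'
#' @param ds a [genotype_dataset()].
#' @param prefix output path prefix; writes `<prefix>.bed/.bim/.fam`.
#' @return Invisibly, the prefix.
#' @export
write_plink <- function(ds, prefix) {
  geno <- ds$genotypes
  n_samples <- nrow(geno)
  n_variants <- ncol(geno)
  bytes_per_variant <- ceiling(n_samples / 4)

  codes <- matrix(.bed_dosage_to_code(geno), nrow = n_samples)
  # pad rows to a multiple of 4 with code 0 (ignored on read)
  pad <- bytes_per_variant * 4 - n_samples
  if (pad > 0) codes <- rbind(codes, matrix(0L, nrow = pad, ncol = n_variants))
  idx <- function(k) seq.int(k, by = 4, length.out = bytes_per_variant)
  bytes <- codes[idx(1), , drop = FALSE] +
    4L * codes[idx(2), , drop = FALSE] +
    16L * codes[idx(3), , drop = FALSE] +
    64L * codes[idx(4), , drop = FALSE]

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)

  bim <- data.frame(ds$variants$chrom, ds$variants$vid, 0,
                    ds$variants$pos, ds$variants$alt, ds$variants$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  pheno <- ifelse(is.na(ds$samples$phenotype), -9L,
                  ifelse(ds$samples$phenotype == 1L, 2L, 1L))
  fam <- data.frame(ds$samples$sid, ds$samples$sid, 0, 0, 0, pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
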