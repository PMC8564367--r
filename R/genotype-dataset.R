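#' Construct a genotype dataset
#'
#' The central container of the package: a samples-by-variants matrix of
#' alternative-allele dosages together with variant and sample metadata.
#' Dosage counts the alternative (effect) allele, so 0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternative, `NA` = missing
#' call. This coding is used consistently by the association scan, the
#' polygenic risk score and the hypothesis search.
#'
#' @param genotypes integer/numeric matrix, samples in rows, variants in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom` (character label,
#'   1-22/X/Y/MT), `pos` (1-based bp), `vid` (unique variant id), `ref`,
#'   `alt` (allele strings). Order defines column order.
#' @param samples data.frame with columns `sid` (unique sample id) and
#'   `phenotype` (1 = case, 0 = control, `NA` = unknown).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, variants, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  check_that(all(c("chrom", "pos", "vid", "ref", "alt") %in% names(variants)),
             "`variants` needs columns chrom, pos, vid, ref, alt")
  check_that(all(c("sid", "phenotype") %in% names(samples)),
             "`samples` needs columns sid, phenotype")
  check_that(nrow(genotypes) == nrow(samples),
             "genotype rows must match sample count")
  check_that(ncol(genotypes) == nrow(variants),
             "genotype columns must match variant count")
  check_that(!anyDuplicated(variants$vid), "variant ids must be unique")
  check_that(!anyDuplicated(samples$sid), "sample ids must be unique")
  rng <- suppressWarnings(range(genotypes, na.rm = TRUE))  # all-NA is valid
  if (any(is.finite(rng))) {
    check_that(rng[1] >= 0 && rng[2] <= 2,
               "non-missing genotypes must be 0, 1 or 2")
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  rownames(genotypes) <- samples$sid
  colnames(genotypes) <- variants$vid
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  structure(
    list(genotypes = genotypes, variants = variants, samples = samples),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_case <- sum(x$samples$phenotype == 1, na.rm = TRUE)
  n_ctrl <- sum(x$samples$phenotype == 0, na.rm = TRUE)
  miss <- mean(is.na(x$genotypes))
  cat(sprintf(
    "<genotype_dataset> %d samples (%d cases / %d controls) x %d variants; %.2f%% missing\n",
    nrow(x$genotypes), n_case, n_ctrl, ncol(x$genotypes), 100 * miss
  ))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset
#'
#' @param ds a `genotype_dataset`.
#' @param samples sample ids or row indices to keep (default all).
#' @param variants variant ids or column indices to keep (default all).
#' @return A `genotype_dataset` restricted to the requested rows/columns.
#' @export
subset_dataset <- function(ds, samples = NULL, variants = NULL) {
  si <- seq_len(nrow(ds$genotypes))
  vi <- seq_len(ncol(ds$genotypes))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, ds$samples$sid) else samples
    check_that(!anyNA(si), "unknown sample id in subset")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, ds$variants$vid) else variants
    check_that(!anyNA(vi), "unknown variant id in subset")
  }
  genotype_dataset(
    ds$genotypes[si, vi, drop = FALSE],
    ds$variants[vi, , drop = FALSE],
    ds$samples[si, , drop = FALSE]
  )
}

#' Alternative-allele frequencies
#'
#' @param ds a `genotype_dataset`.
#' @return Named numeric vector of alt-allele frequencies computed over
#'   non-missing calls (`NaN` where a variant has no calls).
#' @export
alt_freq <- function(ds) {
  colMeans(ds$genotypes, na.rm = TRUE) / 2
}

# genotype label like "TC": dosage 0 -> ref/ref, 1 -> ref/alt, 2 -> alt/alt
genotype_label <- function(ref, alt, dosage) {
  ifelse(dosage == 0L, paste0(ref, ref),
         ifelse(dosage == 1L, paste0(ref, alt), paste0(alt, alt)))
}
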