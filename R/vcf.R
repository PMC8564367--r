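# VCF input/output. Reading goes through vcfR; writing emits a minimal
# plain-text VCF 4.2 with GT-only FORMAT.

#' Read genotypes from a VCF file
#'
#' Biallelic records only: GT `0/0` maps to dosage 0, `0/1` or `1/0` to 1,
#' `1/1` to 2 and `./.` to `NA` (phased separators are accepted).
#' Multiallelic records are skipped with a warning by default.
#'
#' @param path VCF file (plain text or gzipped).
#' @param multiallelic one of `"skip"` (default) or `"error"`.
#' @return A [genotype_dataset()]; phenotypes are `NA` (VCF carries none).
#' @export
read_vcf <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF: ", path, call. = FALSE)
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":"), function(x) "GT" %in% x, logical(1)))) {
    stop("VCF record without GT in FORMAT: ", path, call. = FALSE)
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error") {
      stop(sum(multi), " multiallelic record(s) in ", path, call. = FALSE)
    }
    warning("skipping ", sum(multi), " multiallelic record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dosage[gt_clean == "0/0"] <- 0L
  dosage[gt_clean %in% c("0/1", "1/0")] <- 1L
  dosage[gt_clean == "1/1"] <- 2L

  vid <- fix$ID
  vid[is.na(vid) | vid == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(vid) | vid == "."]
  genotype_dataset(
    t(dosage),
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), vid = vid,
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    data.frame(sid = colnames(gt), phenotype = NA_integer_,
               stringsAsFactors = FALSE)
  )
}

#' Write a genotype dataset as a plain-text VCF
#'
#' @param ds a [genotype_dataset()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(ds, path) {
  gt <- matrix("./.", nrow = ncol(ds$genotypes), ncol = nrow(ds$genotypes))
  g <- t(ds$genotypes)
  gt[!is.na(g) & g == 0L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 2L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples$sid), collapse = "\t")
  )
  body <- paste(
    ds$variants$chrom, ds$variants$pos, ds$variants$vid,
    ds$variants$ref, ds$variants$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
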