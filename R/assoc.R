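#' Per-variant case/control association scan
#'
#' Fits, for each variant, the logistic regression
#' `phenotype ~ dosage` on samples with non-missing genotype and
#' phenotype, and reports the Wald test on the dosage coefficient.
#' Monomorphic variants and non-converged fits (including complete
#' separation) yield an `NA` row with a flag rather than an error.
#'
#' @param ds a [genotype_dataset()] with both phenotype classes present.
#' @param covariates optional numeric matrix of per-sample covariates
#'   (rows aligned with samples); default none.
#' @return An `assoc_result` data.frame ordered by (chrom, pos) with
#'   columns `vid`, `chrom`, `pos`, `beta` (log-odds per alt allele),
#'   `se`, `p`, `n_used`, `flag`.
#' @export
assoc_scan <- function(ds, covariates = NULL) {
  y_all <- ds$samples$phenotype
  check_that(length(unique(stats::na.omit(y_all))) == 2,
             "both phenotype classes must be present")
  m <- ncol(ds$genotypes)
  beta <- se <- p <- rep(NA_real_, m)
  n_used <- integer(m)
  flag <- rep("", m)
  for (j in seq_len(m)) {
    g <- ds$genotypes[, j]
    ok <- !is.na(g) & !is.na(y_all)
    if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
    n_used[j] <- sum(ok)
    g_ok <- g[ok]; y_ok <- y_all[ok]
    if (length(unique(g_ok)) < 2 || length(unique(y_ok)) < 2) {
      flag[j] <- "monomorphic"
      next
    }
    x <- if (is.null(covariates)) cbind(g_ok)
         else cbind(g_ok, covariates[ok, , drop = FALSE])
    fit <- logistic_fit(x, y_ok)
    b <- fit$coef[2]; s <- fit$se[2]
    if (!fit$converged || is.na(s) || !is.finite(s) || s > 100) {
      flag[j] <- "nonconverged"
      next
    }
    beta[j] <- b; se[j] <- s
    p[j] <- 2 * stats::pnorm(-abs(b / s))
  }
  out <- data.frame(
    vid = ds$variants$vid, chrom = ds$variants$chrom, pos = ds$variants$pos,
    beta = beta, se = se, p = p, n_used = n_used, flag = flag,
    stringsAsFactors = FALSE
  )
  ord <- order(suppressWarnings(as.integer(out$chrom)), out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Manhattan-plot export table
#'
#' @param results an `assoc_result` from [assoc_scan()].
#' @param highlight_ids variant ids to flag (e.g. model-selected SNPs).
#' @return data.frame `(vid, chrom, pos, neg_log10_p, highlight)`.
#' @export
manhattan_table <- function(results, highlight_ids = character()) {
  data.frame(
    vid = results$vid, chrom = results$chrom, pos = results$pos,
    neg_log10_p = -log10(results$p),
    highlight = results$vid %in% highlight_ids,
    stringsAsFactors = FALSE
  )
}

#' Write association results as a PLINK-score-compatible TSV
#'
#' Columns: SNP, CHR, BP, A1 (effect/alt allele), BETA, SE, P.
#'
#' @param results an `assoc_result`.
#' @param ds the dataset the scan ran on (for allele columns).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_assoc <- function(results, ds, path) {
  a1 <- ds$variants$alt[match(results$vid, ds$variants$vid)]
  df <- data.frame(SNP = results$vid, CHR = results$chrom, BP = results$pos,
                   A1 = a1, BETA = results$beta, SE = results$se,
                   P = results$p)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
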