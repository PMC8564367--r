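#' Merge two genotype datasets (e.g. two genotyping chips)
#'
#' Variants are matched on (chrom, pos). Where both datasets typed a
#' variant, alleles are reconciled: identical ref/alt pairs are combined
#' directly; a swapped pair (ref and alt exchanged) has its dosage flipped
#' (`2 - dosage`) before combining; any other allele pair is irreconcilable
#' and the variant is dropped with a logged count. Where both typed a
#' shared sample with different non-missing calls, the merged call is set
#' `NA` and counted. Samples are matched on id and must agree on phenotype.
#'
#' @param a,b [genotype_dataset()] objects.
#' @return A `genotype_dataset` over the union of samples and reconcilable
#'   variants, with attributes `n_dropped_alleles` (irreconcilable variant
#'   count) and `n_call_conflicts` (discordant calls set to `NA`).
#' @export
merge_datasets <- function(a, b) {
  shared <- intersect(a$samples$sid, b$samples$sid)
  if (length(shared)) {
    pa <- a$samples$phenotype[match(shared, a$samples$sid)]
    pb <- b$samples$phenotype[match(shared, b$samples$sid)]
    bad <- !is.na(pa) & !is.na(pb) & pa != pb
    if (any(bad)) {
      stop("conflicting phenotypes for shared sample(s): ",
           paste(utils::head(shared[bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  sids <- union(a$samples$sid, b$samples$sid)
  pheno <- a$samples$phenotype[match(sids, a$samples$sid)]
  pb_all <- b$samples$phenotype[match(sids, b$samples$sid)]
  pheno[is.na(pheno)] <- pb_all[is.na(pheno)]

  key_a <- paste(a$variants$chrom, a$variants$pos, sep = ":")
  key_b <- paste(b$variants$chrom, b$variants$pos, sep = ":")
  common <- intersect(key_a, key_b)
  only_a <- which(!(key_a %in% common))
  only_b <- which(!(key_b %in% common))

  n_dropped <- 0L
  n_conflict <- 0L
  geno_cols <- list()
  var_rows <- list()

  add_from <- function(ds, j, dosage) {
    col <- rep(NA_integer_, length(sids))
    col[match(ds$samples$sid, sids)] <- dosage
    col
  }

  for (j in only_a) {
    geno_cols[[length(geno_cols) + 1L]] <- add_from(a, j, a$genotypes[, j])
    var_rows[[length(var_rows) + 1L]] <- a$variants[j, ]
  }
  for (j in only_b) {
    geno_cols[[length(geno_cols) + 1L]] <- add_from(b, j, b$genotypes[, j])
    var_rows[[length(var_rows) + 1L]] <- b$variants[j, ]
  }
  for (key in common) {
    ja <- match(key, key_a)
    jb <- match(key, key_b)
    va <- a$variants[ja, ]
    vb <- b$variants[jb, ]
    db <- b$genotypes[, jb]
    if (va$ref == vb$ref && va$alt == vb$alt) {
      # direct
    } else if (va$ref == vb$alt && va$alt == vb$ref) {
      db <- 2L - db
    } else {
      n_dropped <- n_dropped + 1L
      next
    }
    col <- add_from(a, ja, a$genotypes[, ja])
    col_b <- add_from(b, jb, db)
    conflict <- !is.na(col) & !is.na(col_b) & col != col_b
    n_conflict <- n_conflict + sum(conflict)
    col[is.na(col)] <- col_b[is.na(col)]
    col[conflict] <- NA_integer_
    geno_cols[[length(geno_cols) + 1L]] <- col
    var_rows[[length(var_rows) + 1L]] <- va
  }

  check_that(length(geno_cols) > 0, "merge produced no variants")
  variants <- do.call(rbind, var_rows)
  geno <- do.call(cbind, geno_cols)
  ord <- order(suppressWarnings(as.integer(variants$chrom)),
               variants$chrom, variants$pos)
  out <- genotype_dataset(
    geno[, ord, drop = FALSE],
    variants[ord, , drop = FALSE],
    data.frame(sid = sids, phenotype = pheno, stringsAsFactors = FALSE)
  )
  attr(out, "n_dropped_alleles") <- n_dropped
  attr(out, "n_call_conflicts") <- n_conflict
  out
}
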