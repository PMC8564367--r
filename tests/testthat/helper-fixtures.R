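# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# tiny hand-rolled dataset: explicit genotypes, optional phenotypes
tiny_dataset <- function(genotypes, phenotype = NULL,
                         chrom = NULL, pos = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (is.null(phenotype)) phenotype <- rep(NA_integer_, n)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_dataset(
    genotypes,
    data.frame(chrom = chrom, pos = pos,
               vid = sprintf("v%03d", seq_len(m)),
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    data.frame(sid = sprintf("s%03d", seq_len(n)), phenotype = phenotype,
               stringsAsFactors = FALSE)
  )
}

# random valid dataset with HWE genotypes and optional missingness
random_dataset <- function(n = 60, m = 30, seed = 1, missing_rate = 0,
                           phenotype = TRUE, maf_range = c(0.1, 0.5)) {
  withr::with_seed(seed, {
    maf <- runif(m, maf_range[1], maf_range[2])
    g <- vapply(maf, function(p) rbinom(n, 2, p), integer(n))
    if (missing_rate > 0) {
      g[matrix(runif(n * m) < missing_rate, n, m)] <- NA_integer_
    }
    ph <- if (phenotype) rbinom(n, 1, 0.5) else rep(NA_integer_, n)
    tiny_dataset(g, phenotype = ph)
  })
}

# straightforward independent re-implementation of the AUC as an oracle:
# exhaustive comparison over all case/control pairs
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# independent enumeration oracle for the HWE exact test: enumerate every
# heterozygote count compatible with the allele totals and sum the exact
# multinomial-conditional probabilities directly (log-factorial form)
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(NA_real_)
  na <- 2 * n_AA + n_Aa   # allele A count
  nb <- 2 * n_aa + n_Aa
  hets <- seq(if (n_Aa %% 2 == 0) 0 else 1, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- (nb - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# independent reference implementation of the same greedy pruning rule,
# written as a direct transcription (no windows reuse, full recompute)
reference_prune <- function(ds, window, step, r2) {
  af <- colMeans(ds$genotypes, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  kept <- setNames(rep(TRUE, ncol(ds$genotypes)), ds$variants$vid)
  for (chr in unique(ds$variants$chrom)) {
    idx <- which(ds$variants$chrom == chr)
    if (length(idx) < 2) next
    for (s in seq(1, max(1, length(idx) - 1), by = step)) {
      win <- idx[s:min(s + window - 1, length(idx))]
      repeat {
        cur <- win[kept[win]]
        found <- NULL
        if (length(cur) >= 2) {
          for (a in 1:(length(cur) - 1)) {
            for (b in (a + 1):length(cur)) {
              x <- ds$genotypes[, cur[a]]; y <- ds$genotypes[, cur[b]]
              ok <- !is.na(x) & !is.na(y)
              if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
              if (cor(x[ok], y[ok])^2 > r2) { found <- c(cur[a], cur[b]); break }
            }
            if (!is.null(found)) break
          }
        }
        if (is.null(found)) break
        drop <- if (maf[found[1]] < maf[found[2]]) found[1] else
                if (maf[found[2]] < maf[found[1]]) found[2] else found[2]
        kept[drop] <- FALSE
      }
    }
  }
  names(kept)[kept]
}

# direct reference implementation of the greedy clumping rule
reference_clump <- function(results, ds, r2_clump, window_kb) {
  res <- results[!is.na(results$p), ]
  res <- res[order(res$p, match(res$vid, ds$variants$vid)), ]
  kept <- character(); removed <- character()
  for (i in seq_len(nrow(res))) {
    v <- res$vid[i]
    if (v %in% removed) next
    kept <- c(kept, v)
    for (j in seq_len(nrow(res))) {
      w <- res$vid[j]
      if (w == v || w %in% removed || w %in% kept) next
      if (res$chrom[j] != res$chrom[i]) next
      if (abs(res$pos[j] - res$pos[i]) > window_kb * 1000) next
      x <- ds$genotypes[, v]; y <- ds$genotypes[, w]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      if (cor(x[ok], y[ok])^2 > r2_clump) removed <- c(removed, w)
    }
  }
  kept
}
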