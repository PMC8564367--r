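# Quality-control pipeline for case/control genotype data.
# Step order: missingness (variants before samples) -> autosome ->
# two-stage HWE -> LD pruning -> heterozygosity -> IBD relatedness.

#' QC configuration
#'
#' @param miss_thresh maximum missing-call fraction per variant and per
#'   sample (default 0.02).
#' @param hwe_p_controls HWE exact-test p-value threshold applied to
#'   controls only (stage 1, default 1e-6).
#' @param hwe_p_all HWE threshold applied to all samples (stage 2,
#'   default 1e-10).
#' @param het_sd_k heterozygosity-rate outlier cut in standard deviations
#'   (default 3).
#' @param prune_window,prune_step,prune_r2 LD-pruning window (variants),
#'   step (variants) and squared-correlation threshold (defaults 50, 5,
#'   0.2).
#' @param ibd_pi_hat_max maximum PI_HAT before one member of a pair is
#'   removed (default 0.1875, midway between second- and third-degree
#'   relative expectations).
#' @return A `qc_config` list.
#' @export
qc_config <- function(miss_thresh = 0.02,
                      hwe_p_controls = 1e-6,
                      hwe_p_all = 1e-10,
                      het_sd_k = 3,
                      prune_window = 50L,
                      prune_step = 5L,
                      prune_r2 = 0.2,
                      ibd_pi_hat_max = 0.1875) {
  check_that(miss_thresh >= 0 && miss_thresh <= 1,
             "miss_thresh must be in [0, 1]")
  check_that(hwe_p_controls > 0 && hwe_p_controls <= 1 &&
               hwe_p_all > 0 && hwe_p_all <= 1,
             "HWE thresholds must be in (0, 1]")
  check_that(het_sd_k > 0, "het_sd_k must be positive")
  check_that(prune_window >= 2 && prune_step >= 1,
             "prune_window >= 2 and prune_step >= 1 required")
  check_that(prune_r2 >= 0 && prune_r2 <= 1, "prune_r2 must be in [0, 1]")
  check_that(ibd_pi_hat_max >= 0 && ibd_pi_hat_max <= 1,
             "ibd_pi_hat_max must be in [0, 1]")
  structure(
    list(miss_thresh = miss_thresh, hwe_p_controls = hwe_p_controls,
         hwe_p_all = hwe_p_all, het_sd_k = het_sd_k,
         prune_window = as.integer(prune_window),
         prune_step = as.integer(prune_step), prune_r2 = prune_r2,
         ibd_pi_hat_max = ibd_pi_hat_max),
    class = "qc_config"
  )
}

qc_entry <- function(step, variants_removed, samples_removed, detail = NULL) {
  list(step = step, variants_removed = as.integer(variants_removed),
       samples_removed = as.integer(samples_removed), detail = detail)
}

#' Missing-call-rate filter
#'
#' Variants are filtered before samples: first drop variants whose missing
#' fraction exceeds the threshold, then drop samples whose missing fraction
#' (over the surviving variants) exceeds it. Denominators count all
#' entries; missing fractions are per row/column of the call matrix.
#'
#' @param ds a [genotype_dataset()].
#' @param miss_thresh maximum tolerated missing fraction.
#' @return List with elements `dataset` and `entry` (a step log record).
#' @export
missingness_filter <- function(ds, miss_thresh = 0.02) {
  check_that(miss_thresh >= 0 && miss_thresh <= 1,
             "miss_thresh must be in [0, 1]")
  check_that(nrow(ds$genotypes) > 0 && ncol(ds$genotypes) > 0,
             "dataset is empty")
  na <- is.na(ds$genotypes)
  var_keep <- colMeans(na) <= miss_thresh
  ds2 <- subset_dataset(ds, variants = which(var_keep))
  smp_keep <- rowMeans(is.na(ds2$genotypes)) <= miss_thresh
  ds3 <- subset_dataset(ds2, samples = which(smp_keep))
  list(
    dataset = ds3,
    entry = qc_entry("missingness", sum(!var_keep), sum(!smp_keep))
  )
}

#' Keep autosomal variants only
#'
#' @param ds a [genotype_dataset()].
#' @return List with `dataset` (chromosomes 1-22 only) and `entry`.
#' @export
autosome_filter <- function(ds) {
  keep <- ds$variants$chrom %in% as.character(1:22)
  list(
    dataset = subset_dataset(ds, variants = which(keep)),
    entry = qc_entry("autosome", sum(!keep), 0L)
  )
}

#' Hardy-Weinberg exact test
#'
#' Exact test on genotype counts: conditional on the observed allele
#' counts, the p-value sums the probabilities of all heterozygote counts
#' no more probable than the observed one (no mid-p correction). Vectorized
#' over the three count arguments.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts
#'   (homozygous reference, heterozygous, homozygous alternative).
#' @return p-values in (0, 1]; `NA` where all three counts are zero.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  mapply(hwe_exact_p1, n_AA, n_Aa, n_aa, USE.NAMES = FALSE)
}

hwe_exact_p1 <- function(n_AA, n_Aa, n_aa) {
  if (anyNA(c(n_AA, n_Aa, n_aa))) return(NA_real_)
  check_that(n_AA >= 0 && n_Aa >= 0 && n_aa >= 0,
             "genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(NA_real_)
  rare <- 2L * min(n_AA, n_aa) + n_Aa        # rare-allele count
  # heterozygote counts compatible with the allele totals share the
  # parity of `rare` and run from that parity up to `rare`
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  if (length(hets) == 1L) return(1)
  probs <- numeric(length(hets))
  # start at the mode and use the hypergeometric-style recurrences
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  # downward: P(h-2) = P(h) * h(h-1) / (4 (hom_r + 1)(hom_c + 1))
  h <- mid
  hom_r <- (rare - h) / 2
  hom_c <- n - h - hom_r
  i <- i_mid
  while (h > hets[1]) {
    probs[i - 1L] <- probs[i] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
    h <- h - 2L; hom_r <- hom_r + 1; hom_c <- hom_c + 1; i <- i - 1L
  }
  # upward: P(h+2) = P(h) * 4 hom_r hom_c / ((h+1)(h+2))
  h <- mid
  hom_r <- (rare - h) / 2
  hom_c <- n - h - hom_r
  i <- i_mid
  while (h < rare) {
    probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c / ((h + 1) * (h + 2))
    h <- h + 2L; hom_r <- hom_r - 1; hom_c <- hom_c - 1; i <- i + 1L
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

hwe_p_per_variant <- function(geno) {
  n1 <- colSums(geno == 0L, na.rm = TRUE)
  n2 <- colSums(geno == 1L, na.rm = TRUE)
  n3 <- colSums(geno == 2L, na.rm = TRUE)
  hwe_exact_p(n1, n2, n3)
}

#' Two-stage Hardy-Weinberg filter
#'
#' Stage 1 removes variants whose HWE exact p in controls falls below
#' `hwe_p_controls`; stage 2 then removes variants whose p over all
#' samples falls below `hwe_p_all`. Stage counts are reported separately.
#'
#' @param ds a [genotype_dataset()] with phenotypes.
#' @param hwe_p_controls,hwe_p_all stage thresholds.
#' @return List with `dataset` and `entry`; `entry$detail` carries
#'   `removed_controls_stage` and `removed_all_stage`.
#' @export
hwe_filter <- function(ds, hwe_p_controls = 1e-6, hwe_p_all = 1e-10) {
  ctrl <- which(!is.na(ds$samples$phenotype) & ds$samples$phenotype == 0)
  n_stage1 <- 0L
  if (length(ctrl) == 0) {
    warning("no controls present; HWE stage 1 skipped")
  } else {
    p1 <- hwe_p_per_variant(ds$genotypes[ctrl, , drop = FALSE])
    drop1 <- !is.na(p1) & p1 < hwe_p_controls
    n_stage1 <- sum(drop1)
    ds <- subset_dataset(ds, variants = which(!drop1))
  }
  p2 <- hwe_p_per_variant(ds$genotypes)
  drop2 <- !is.na(p2) & p2 < hwe_p_all
  ds <- subset_dataset(ds, variants = which(!drop2))
  list(
    dataset = ds,
    entry = qc_entry("hwe", n_stage1 + sum(drop2), 0L,
                     detail = list(removed_controls_stage = n_stage1,
                                   removed_all_stage = sum(drop2)))
  )
}

# squared Pearson correlation between two dosage vectors over complete pairs
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
  if (sx == 0 || sy == 0) return(NA_real_)   # monomorphic: undefined r
  stats::cor(x[ok], y[ok])^2
}

#' LD pruning (sliding-window pairwise r^2)
#'
#' Windows of `window` variants slide by `step` within each chromosome.
#' Inside a window, while any surviving pair has squared genotype
#' correlation above `r2`, the member of the first such pair (scanning
#' pairs in map order) with the lower minor-allele frequency is removed
#' (tie: the later variant). Monomorphic variants have undefined r and are
#' always kept.
#'
#' @param ds a [genotype_dataset()].
#' @param window,step window size and step in variants.
#' @param r2 squared-correlation threshold.
#' @return Character vector of retained variant ids, in map order.
#' @export
ld_prune <- function(ds, window = 50L, step = 5L, r2 = 0.2) {
  m <- ncol(ds$genotypes)
  check_that(m >= 2, "need at least two variants to prune")
  keep <- rep(TRUE, m)
  af <- alt_freq(ds)
  maf <- pmin(af, 1 - af)
  for (chr in unique(ds$variants$chrom)) {
    idx <- which(ds$variants$chrom == chr)
    if (length(idx) < 2) next
    starts <- seq.int(1L, max(1L, length(idx) - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      # pairwise r^2 once per window; removals do not change the
      # correlations among the survivors
      C <- suppressWarnings(
        stats::cor(ds$genotypes[, win, drop = FALSE],
                   use = "pairwise.complete.obs")
      )^2
      repeat {
        alive <- which(keep[win])
        if (length(alive) < 2) break
        drop_at <- NA_integer_
        for (a in seq_len(length(alive) - 1L)) {
          hits <- which(!is.na(C[alive[a], alive]) &
                          C[alive[a], alive] > r2)
          hits <- hits[alive[hits] > alive[a]]
          if (length(hits)) {
            pa <- win[alive[a]]; pb <- win[alive[hits[1]]]
            drop_at <- if (maf[pa] < maf[pb]) pa
                       else if (maf[pb] < maf[pa]) pb
                       else pb              # tie: later map order
            break
          }
        }
        if (is.na(drop_at)) break
        keep[drop_at] <- FALSE
      }
    }
  }
  ds$variants$vid[keep]
}

#' Heterozygosity-rate outlier filter
#'
#' Per-sample heterozygosity rate = (# heterozygous calls) / (# non-missing
#' calls), computed over an LD-pruned variant set; samples deviating from
#' the mean rate by more than `het_sd_k` standard deviations are removed.
#'
#' @param ds a [genotype_dataset()].
#' @param pruned_ids variant ids to compute the rate on (from [ld_prune()]).
#' @param het_sd_k cut in standard deviations (default 3).
#' @return List with `dataset` and `entry`; `entry$detail$rates` has the
#'   per-sample rates.
#' @export
heterozygosity_filter <- function(ds, pruned_ids, het_sd_k = 3) {
  check_that(all(pruned_ids %in% ds$variants$vid),
             "pruned_ids must be dataset variant ids")
  if (nrow(ds$genotypes) < 3) {
    warning("fewer than 3 samples; heterozygosity filter skipped")
    return(list(dataset = ds, entry = qc_entry("heterozygosity", 0L, 0L)))
  }
  g <- ds$genotypes[, pruned_ids, drop = FALSE]
  rate <- rowSums(g == 1L, na.rm = TRUE) / rowSums(!is.na(g))
  mu <- mean(rate, na.rm = TRUE)
  sdev <- stats::sd(rate, na.rm = TRUE)
  drop <- if (is.na(sdev) || sdev == 0) rep(FALSE, length(rate))
          else !is.na(rate) & abs(rate - mu) > het_sd_k * sdev
  list(
    dataset = subset_dataset(ds, samples = which(!drop)),
    entry = qc_entry("heterozygosity", 0L, sum(drop),
                     detail = list(rates = stats::setNames(rate, ds$samples$sid)))
  )
}

#' Pairwise IBD estimation (method of moments)
#'
#' Moment estimator in the PLINK --genome style: observed identity-by-state
#' (IBS) 0/1/2 counts per sample pair are compared with their expectations
#' under IBD state 0/1 to estimate P(IBD = 0/1/2);
#' PI_HAT = P(IBD=1)/2 + P(IBD=2). Because allele frequencies are estimated
#' from the same sample, the expectations use unbiased estimators of the
#' allele-probability products (ratios of falling factorials of the allele
#' counts) rather than plug-in powers of the frequency -- without this
#' finite-sample correction PI_HAT is badly inflated at small n.
#' Estimates are clamped to [0, 1] and renormalized.
#'
#' @param ds a [genotype_dataset()].
#' @param pruned_ids variant ids to estimate from (near-independent set).
#' @return data.frame with columns `sid_a`, `sid_b` (`sid_a` earlier in
#'   dataset order), `z0`, `z1`, `z2`, `pi_hat` for every sample pair.
#' @export
ibd_estimate <- function(ds, pruned_ids = ds$variants$vid) {
  g <- ds$genotypes[, pruned_ids, drop = FALSE]
  n <- nrow(g)
  check_that(n >= 2, "need at least two samples")
  A <- colSums(g, na.rm = TRUE)                       # alt allele count
  T_ <- 2 * colSums(!is.na(g))                        # total alleles
  B <- T_ - A
  ok <- A >= 2 & B >= 2 & T_ >= 8                     # informative variants
  check_that(any(ok), "no polymorphic variants for IBD estimation")
  g <- g[, ok, drop = FALSE]
  A <- A[ok]; B <- B[ok]; T_ <- T_[ok]
  G0 <- (!is.na(g) & g == 0L) + 0
  G1 <- (!is.na(g) & g == 1L) + 0
  G2 <- (!is.na(g) & g == 2L) + 0
  M <- (!is.na(g)) + 0
  ibs0 <- tcrossprod(G0, G2) + tcrossprod(G2, G0)
  ibs2 <- tcrossprod(G0) + tcrossprod(G1) + tcrossprod(G2)
  m_tot <- tcrossprod(M)
  ibs1 <- m_tot - ibs0 - ibs2
  # unbiased estimators of p^a q^b from allele counts: falling factorials
  ff <- function(x, k) {
    out <- rep(1, length(x))
    for (i in seq_len(k)) out <- out * (x - i + 1)
    out
  }
  d4 <- ff(T_, 4); d3 <- ff(T_, 3)
  p2q2 <- ff(A, 2) * ff(B, 2) / d4
  p3q <- ff(A, 3) * B / d4
  pq3 <- A * ff(B, 3) / d4
  p4 <- ff(A, 4) / d4
  q4 <- ff(B, 4) / d4
  p2q <- ff(A, 2) * B / d3
  pq2 <- A * ff(B, 2) / d3
  # conditional IBS probabilities given IBD state
  w0_ibs0 <- 2 * p2q2
  w0_ibs1 <- 4 * p3q + 4 * pq3
  w0_ibs2 <- p4 + q4 + 4 * p2q2
  w1_ibs1 <- 2 * p2q + 2 * pq2
  w1_ibs2 <- 1 - w1_ibs1
  e0_0 <- tcrossprod(M * rep(w0_ibs0, each = n), M)
  e0_1 <- tcrossprod(M * rep(w0_ibs1, each = n), M)
  e0_2 <- tcrossprod(M * rep(w0_ibs2, each = n), M)
  e1_1 <- tcrossprod(M * rep(w1_ibs1, each = n), M)
  e1_2 <- tcrossprod(M * rep(w1_ibs2, each = n), M)

  pairs <- which(upper.tri(m_tot), arr.ind = TRUE)
  z0 <- ibs0[pairs] / pmax(e0_0[pairs], .Machine$double.eps)
  z1 <- (ibs1[pairs] - z0 * e0_1[pairs]) /
    pmax(e1_1[pairs], .Machine$double.eps)
  z2 <- (ibs2[pairs] - z0 * e0_2[pairs] - z1 * e1_2[pairs]) /
    pmax(m_tot[pairs], 1)
  z <- cbind(z0, z1, z2)
  z[z < 0] <- 0
  z[z > 1] <- 1
  z <- z / pmax(rowSums(z), .Machine$double.eps)
  data.frame(
    sid_a = ds$samples$sid[pairs[, 1]],   # upper.tri: row index < col index
    sid_b = ds$samples$sid[pairs[, 2]],
    z0 = z[, 1], z1 = z[, 2], z2 = z[, 3],
    pi_hat = z[, 2] / 2 + z[, 3],
    stringsAsFactors = FALSE
  )
}

#' Relatedness filter on PI_HAT
#'
#' For each pair exceeding `pi_hat_max`, the member with the higher
#' missing-call rate is removed (tie: the later sample in dataset order);
#' pairs are revisited until none remain over the threshold.
#'
#' @param ds a [genotype_dataset()].
#' @param pruned_ids LD-pruned variant ids used for IBD estimation.
#' @param pi_hat_max removal threshold (default 0.1875).
#' @return List with `dataset` and `entry`; `entry$detail$pairs` lists
#'   flagged pairs.
#' @export
ibd_filter <- function(ds, pruned_ids, pi_hat_max = 0.1875) {
  if (nrow(ds$genotypes) < 2) {
    return(list(dataset = ds, entry = qc_entry("ibd", 0L, 0L)))
  }
  est <- ibd_estimate(ds, pruned_ids)
  flagged <- est[est$pi_hat > pi_hat_max, , drop = FALSE]
  missing_rate <- rowMeans(is.na(ds$genotypes))
  names(missing_rate) <- ds$samples$sid
  order_of <- stats::setNames(seq_len(nrow(ds$genotypes)), ds$samples$sid)
  removed <- character()
  active <- flagged
  while (nrow(active) > 0) {
    pr <- active[1, ]
    mr_a <- missing_rate[pr$sid_a]; mr_b <- missing_rate[pr$sid_b]
    victim <- if (mr_a > mr_b) pr$sid_a
              else if (mr_b > mr_a) pr$sid_b
              else if (order_of[pr$sid_a] > order_of[pr$sid_b]) pr$sid_a
              else pr$sid_b
    removed <- c(removed, victim)
    active <- active[active$sid_a != victim & active$sid_b != victim, ,
                     drop = FALSE]
  }
  keep <- setdiff(ds$samples$sid, removed)
  list(
    dataset = subset_dataset(ds, samples = keep),
    entry = qc_entry("ibd", 0L, length(removed),
                     detail = list(pairs = flagged, removed = removed))
  )
}

#' Run the full QC pipeline
#'
#' Applies, in order: missingness (variants then samples), autosome
#' restriction, two-stage HWE, LD pruning (to obtain a near-independent
#' variant set), heterozygosity outlier removal, and IBD relatedness
#' filtering.
#'
#' @param ds a [genotype_dataset()].
#' @param config a [qc_config()].
#' @return List with `dataset` (the QCed data) and `report`, a `qc_report`
#'   object logging removals per step.
#' @export
run_qc <- function(ds, config = qc_config()) {
  dims0 <- dim(ds$genotypes)
  steps <- list()
  r <- missingness_filter(ds, config$miss_thresh)
  steps <- c(steps, list(r$entry)); ds <- r$dataset
  r <- autosome_filter(ds)
  steps <- c(steps, list(r$entry)); ds <- r$dataset
  r <- hwe_filter(ds, config$hwe_p_controls, config$hwe_p_all)
  steps <- c(steps, list(r$entry)); ds <- r$dataset
  pruned <- if (ncol(ds$genotypes) >= 2) {
    ld_prune(ds, config$prune_window, config$prune_step, config$prune_r2)
  } else {
    ds$variants$vid
  }
  r <- heterozygosity_filter(ds, pruned, config$het_sd_k)
  steps <- c(steps, list(r$entry)); ds <- r$dataset
  r <- ibd_filter(ds, pruned, config$ibd_pi_hat_max)
  steps <- c(steps, list(r$entry)); ds <- r$dataset
  report <- structure(
    list(steps = steps, initial = dims0, final = dim(ds$genotypes)),
    class = "qc_report"
  )
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d x %d -> %d x %d (samples x variants)\n",
              x$initial[1], x$initial[2], x$final[1], x$final[2]))
  for (s in x$steps) {
    cat(sprintf("  %-16s -%d variants, -%d samples\n",
                s$step, s$variants_removed, s$samples_removed))
  }
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(
    step = vapply(x$steps, `[[`, character(1), "step"),
    variants_removed = vapply(x$steps, `[[`, integer(1), "variants_removed"),
    samples_removed = vapply(x$steps, `[[`, integer(1), "samples_removed"),
    stringsAsFactors = FALSE
  )
}
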