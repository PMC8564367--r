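# QC pipeline: missingness, autosome, HWE, LD pruning, heterozygosity, IBD.

test_that("missingness filter removes variants before samples", {
  ds <- random_dataset(n = 100, m = 20, seed = 1)
  clean <- missingness_filter(ds, 0.02)
  expect_identical(dim(clean$dataset$genotypes), dim(ds$genotypes))

  # one variant missing in 3/100 samples exceeds the 2% threshold
  ds$genotypes[1:3, 5] <- NA_integer_
  r <- missingness_filter(ds, 0.02)
  expect_identical(r$entry$variants_removed, 1L)
  expect_false("v005" %in% r$dataset$variants$vid)

  expect_error(missingness_filter(ds, 1.5), "miss_thresh")
})

test_that("missingness removals match a brute-force recount", {
  ds <- random_dataset(n = 80, m = 50, seed = 9, missing_rate = 0.05)
  th <- 0.06
  r <- missingness_filter(ds, th)
  # independent recount: column fractions first, then rows on survivors
  na <- is.na(ds$genotypes)
  bad_var <- colnames(ds$genotypes)[apply(na, 2, mean) > th]
  surviving <- setdiff(colnames(ds$genotypes), bad_var)
  bad_smp <- rownames(ds$genotypes)[
    apply(na[, surviving, drop = FALSE], 1, mean) > th]
  expect_setequal(setdiff(ds$variants$vid, r$dataset$variants$vid), bad_var)
  expect_setequal(setdiff(ds$samples$sid, r$dataset$samples$sid), bad_smp)
})

test_that("autosome filter keeps chromosomes 1-22 only", {
  ds <- random_dataset(n = 10, m = 6, seed = 3)
  expect_identical(autosome_filter(ds)$dataset$variants$vid, ds$variants$vid)
  ds$variants$chrom <- c("1", "X", "22", "Y", "MT", "7")
  r <- autosome_filter(ds)
  expect_identical(r$entry$variants_removed, 3L)
  expect_identical(r$dataset$variants$chrom, c("1", "22", "7"))
})

test_that("HWE exact p equals full enumeration and is a valid probability", {
  # extreme heterozygote excess is vanishingly improbable
  expect_lt(hwe_exact_p(0, 100, 0), 1e-6)
  # random counts agree with the independent enumeration oracle
  withr::with_seed(5, {
    for (rep in 1:60) {
      n <- sample(3:200, 1)
      counts <- as.vector(stats::rmultinom(1, n, c(0.3, 0.45, 0.25)))
      p_pkg <- hwe_exact_p(counts[1], counts[2], counts[3])
      p_ora <- oracle_hwe_p(counts[1], counts[2], counts[3])
      expect_equal(p_pkg, p_ora, tolerance = 1e-12)
      expect_gt(p_pkg, 0)
      expect_lte(p_pkg, 1)
    }
  })
  expect_true(is.na(hwe_exact_p(0, 0, 0)))
})

test_that("HWE p is invariant under allele relabelling", {
  withr::with_seed(8, {
    for (rep in 1:25) {
      cnt <- sample(0:60, 3, replace = TRUE)
      if (sum(cnt) == 0) next
      expect_equal(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                   hwe_exact_p(cnt[3], cnt[2], cnt[1]), tolerance = 1e-12)
    }
  })
})

test_that("two-stage HWE filter removes planted violations by stage", {
  ds <- random_dataset(n = 200, m = 10, seed = 13, phenotype = TRUE)
  r0 <- hwe_filter(ds)
  expect_identical(r0$entry$variants_removed, 0L)

  # plant an all-heterozygous variant among controls only
  ctrl <- which(ds$samples$phenotype == 0)
  ds$genotypes[ctrl, 4] <- 1L
  stopifnot(hwe_exact_p(0, length(ctrl), 0) < 1e-6)
  r1 <- hwe_filter(ds)
  expect_identical(r1$entry$detail$removed_controls_stage, 1L)
  expect_false("v004" %in% r1$dataset$variants$vid)

  # stage counts are reported separately
  expect_named(r1$entry$detail,
               c("removed_controls_stage", "removed_all_stage"))

  # without controls stage 1 is skipped with a warning
  nos <- ds
  nos$samples$phenotype <- rep(1L, nrow(ds$genotypes))
  expect_warning(hwe_filter(nos), "stage 1")
})


test_that("LD pruning matches the reference greedy rule and its contract", {
  # independent variants survive
  ds <- random_dataset(n = 150, m = 20, seed = 21)
  expect_identical(ld_prune(ds, 10, 2, 0.2), ds$variants$vid)

  # duplicated column: exactly one of the pair removed
  dup <- ds
  dup$genotypes[, 7] <- dup$genotypes[, 6]
  kept <- ld_prune(dup, 10, 2, 0.2)
  expect_identical(sum(c("v006", "v007") %in% kept), 1L)

  # correlated instances match the reference implementation
  for (seed in 1:4) {
    sim <- simulate_genotypes(sim_config(
      n_samples = 120, n_variants = 60, ld_block_size = 6, rho_ld = 0.75,
      missing_rate = 0.02, seed = seed
    ))
    expect_identical(ld_prune(sim, 12, 3, 0.2),
                     reference_prune(sim, 12, 3, 0.2))
  }
})

test_that("pruned sets contain no within-window pair above the threshold", {
  sim <- simulate_genotypes(sim_config(
    n_samples = 150, n_variants = 50, ld_block_size = 10, rho_ld = 0.8,
    missing_rate = 0, seed = 77
  ))
  kept <- ld_prune(sim, 10, 5, 0.25)
  pos <- match(kept, sim$variants$vid)
  for (a in seq_along(pos)) {
    for (b in seq_along(pos)) {
      if (b <= a || pos[b] - pos[a] >= 10) next
      if (sim$variants$chrom[pos[a]] != sim$variants$chrom[pos[b]]) next
      r2 <- suppressWarnings(
        cor(sim$genotypes[, pos[a]], sim$genotypes[, pos[b]])^2)
      if (!is.na(r2)) expect_lte(r2, 0.25)
    }
  }
})

test_that("heterozygosity filter flags planted outliers", {
  ds <- random_dataset(n = 100, m = 60, seed = 31, maf_range = c(0.3, 0.5))
  ids <- ds$variants$vid
  # identical het profile everywhere: nothing removed
  same <- tiny_dataset(matrix(1L, nrow = 5, ncol = 4))
  r0 <- heterozygosity_filter(same, same$variants$vid)
  expect_identical(r0$entry$samples_removed, 0L)

  # an all-heterozygous sample among binomial peers is a > 3 SD outlier
  ds$genotypes[17, ] <- 1L
  rates <- rowSums(ds$genotypes == 1L) / ncol(ds$genotypes)
  z <- abs(rates - mean(rates)) / sd(rates)
  expect_gt(z[17], 3)
  r <- heterozygosity_filter(ds, ids, 3)
  expect_false("s017" %in% r$dataset$samples$sid)

  # removal set equals an independent recomputation
  g <- ds$genotypes
  rate2 <- apply(g, 1, function(x) sum(x == 1, na.rm = TRUE) / sum(!is.na(x)))
  out <- abs(rate2 - mean(rate2)) > 3 * sd(rate2)
  expect_setequal(setdiff(ds$samples$sid, r$dataset$samples$sid),
                  ds$samples$sid[out])
})

test_that("IBD estimates separate unrelated, duplicate and parent-child pairs", {
  # relatedness estimation needs many near-independent markers; at a few
  # hundred the moment estimator's noise floor dominates
  ds <- random_dataset(n = 30, m = 2500, seed = 41, maf_range = c(0.2, 0.5))
  est <- ibd_estimate(ds)
  expect_lt(max(est$pi_hat), 0.1875)     # unrelated: no removals due
  expect_lt(mean(est$pi_hat), 0.05)      # and near zero on average
  r <- ibd_filter(ds, ds$variants$vid, 0.1875)
  expect_identical(r$entry$samples_removed, 0L)

  # duplicated sample: PI_HAT near 1, one copy removed
  dup <- ds
  dup$genotypes[2, ] <- dup$genotypes[1, ]
  est2 <- ibd_estimate(dup)
  pair <- est2[est2$sid_a == "s001" & est2$sid_b == "s002", ]
  expect_gt(pair$pi_hat, 0.9)
  r2 <- ibd_filter(dup, colnames(dup$genotypes), 0.1875)
  expect_identical(r2$entry$samples_removed, 1L)
  expect_identical(r2$entry$detail$removed, "s002")   # later order loses

  # parent-child from explicit haplotype transmission: PI_HAT about 0.5
  withr::with_seed(5, {
    m <- 1500
    maf <- runif(m, 0.2, 0.5)
    hap <- function() rbinom(m, 1, maf)
    parents <- replicate(30, hap() + hap())
    # child inherits one allele per locus from the parent's genotype
    transmitted <- rbinom(m, 1, parents[, 1] / 2)
    child <- transmitted + hap()
    fam <- tiny_dataset(t(cbind(parents[, 1], child, parents[, 2:30])))
    est3 <- ibd_estimate(fam)
    pc <- est3[est3$sid_a == "s001" & est3$sid_b == "s002", ]
    expect_equal(pc$pi_hat, 0.5, tolerance = 0.07)
  })
})

test_that("full QC run composes the steps, reconciles counts, idempotent", {
  cfg <- sim_config(n_samples = 40, n_variants = 2000, ld_block_size = 8,
                    rho_ld = 0.3, missing_rate = 0.005, seed = 17)
  ph <- simulate_phenotype(simulate_genotypes(cfg), cfg)
  ds <- ph$dataset
  res <- run_qc(ds, qc_config(miss_thresh = 0.1))
  rep_df <- as.data.frame(res$report)
  expect_identical(nrow(rep_df), 5L)
  expect_identical(res$report$initial[1] - sum(rep_df$samples_removed),
                   res$report$final[1])
  expect_identical(res$report$initial[2] - sum(rep_df$variants_removed),
                   res$report$final[2])
  # idempotence: a second run removes nothing
  res2 <- run_qc(res$dataset, qc_config(miss_thresh = 0.1))
  expect_identical(dim(res2$dataset$genotypes), dim(res$dataset$genotypes))
  expect_identical(sum(as.data.frame(res2$report)$variants_removed) +
                     sum(as.data.frame(res2$report)$samples_removed), 0L)
})

test_that("planted defects are each removed by their own QC step", {
  ds <- random_dataset(n = 60, m = 1500, seed = 55, maf_range = c(0.2, 0.5),
                       phenotype = TRUE)
  m <- ncol(ds$genotypes)
  ds$variants$chrom[m] <- "X"                  # autosome target
  ds$genotypes[1:6, m - 1] <- NA_integer_      # missingness target (10%)
  ds$genotypes[, m - 2] <- 1L                  # HWE target (all het)
  ds$genotypes[7, ] <- 1L                      # het-rate outlier sample
  ds$genotypes[12, ] <- ds$genotypes[11, ]     # duplicate pair
  res <- run_qc(ds, qc_config(miss_thresh = 0.05))
  rep_df <- as.data.frame(res$report)
  expect_identical(rep_df$variants_removed[rep_df$step == "missingness"], 1L)
  expect_identical(rep_df$variants_removed[rep_df$step == "autosome"], 1L)
  expect_identical(rep_df$variants_removed[rep_df$step == "hwe"], 1L)
  expect_identical(rep_df$samples_removed[rep_df$step == "heterozygosity"], 1L)
  expect_identical(rep_df$samples_removed[rep_df$step == "ibd"], 1L)
  expect_false("s007" %in% res$dataset$samples$sid)
  expect_false(any(sprintf("v%03d", (m - 2):m) %in% res$dataset$variants$vid))
})
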