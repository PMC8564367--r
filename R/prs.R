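# Clumping + thresholding polygenic risk score (the additive baseline).

#' LD clumping of association results
#'
#' Greedy: take the most significant remaining variant as an index, remove
#' every variant on the same chromosome within `window_kb` whose squared
#' genotype correlation with the index exceeds `r2_clump`, repeat.
#' Significance gates are disabled (every variant is clumpable); the
#' downstream p-value threshold grid does the filtering.
#'
#' @param results an `assoc_result` from [assoc_scan()].
#' @param ds the [genotype_dataset()] providing genotypes for r^2.
#' @param r2_clump squared-correlation threshold (default 0.1).
#' @param window_kb clumping window in kilobases (default 250).
#' @return Character vector of retained (index) variant ids.
#' @export
clump <- function(results, ds, r2_clump = 0.1, window_kb = 250) {
  res <- results[!is.na(results$p), , drop = FALSE]
  res <- res[order(res$p, match(res$vid, ds$variants$vid)), , drop = FALSE]
  alive <- stats::setNames(rep(TRUE, nrow(res)), res$vid)
  kept <- character()
  for (i in seq_len(nrow(res))) {
    v <- res$vid[i]
    if (!alive[v]) next
    kept <- c(kept, v)
    alive[v] <- FALSE
    near <- res$vid[alive[res$vid] &
                      res$chrom == res$chrom[i] &
                      abs(res$pos - res$pos[i]) <= window_kb * 1000]
    if (length(near)) {
      gv <- ds$genotypes[, v]
      r2s <- vapply(near, function(w) pair_r2(gv, ds$genotypes[, w]),
                    numeric(1))
      alive[near[!is.na(r2s) & r2s > r2_clump]] <- FALSE
    }
  }
  kept
}

#' Score samples with a weighted allele sum
#'
#' PRS_i = sum_j beta_j * dosage_ij over the weight table's variants,
#' where dosage counts the effect allele. Missing dosages are imputed as
#' twice the effect-allele frequency computed on the scoring dataset.
#'
#' @param ds a [genotype_dataset()].
#' @param weights data.frame with columns `vid`, `effect_allele`, `beta`
#'   (a `prs_model` is also accepted).
#' @return Named numeric vector of per-sample scores.
#' @export
prs_score <- function(ds, weights) {
  if (inherits(weights, "prs_model")) weights <- weights$weights
  check_that(nrow(weights) > 0, "empty weight set")
  present <- weights$vid %in% ds$variants$vid
  if (!all(present)) {
    warning(sum(!present), " weight variant(s) absent from dataset; dropped")
    weights <- weights[present, , drop = FALSE]
    check_that(nrow(weights) > 0, "no weight variants present in dataset")
  }
  g <- ds$genotypes[, weights$vid, drop = FALSE]
  alt <- ds$variants$alt[match(weights$vid, ds$variants$vid)]
  flip <- weights$effect_allele != alt
  g[, flip] <- 2L - g[, flip, drop = FALSE]
  ef <- colMeans(g, na.rm = TRUE) / 2       # effect-allele frequency
  ef[is.nan(ef)] <- 0
  for (j in which(colSums(is.na(g)) > 0)) {
    g[is.na(g[, j]), j] <- 2 * ef[j]
  }
  drop(g %*% weights$beta)
}

#' Fit the p-value threshold grid of PRS classifiers
#'
#' For each threshold: clump, keep variants with p <= threshold, score the
#' training samples, and fit the one-feature logistic calibration
#' `phenotype ~ PRS` with `glm`.
#'
#' @param results `assoc_result` for the training data.
#' @param ds_train training [genotype_dataset()].
#' @param thresholds p-value cutoffs (default the grid
#'   0.001, 0.05, 0.1, 0.2, 0.4, 0.5).
#' @param r2_clump,window_kb clumping parameters.
#' @return List of `prs_model` objects (one per threshold; models that
#'   retain no variants are flagged `empty`).
#' @export
fit_threshold_grid <- function(results, ds_train,
                               thresholds = c(0.001, 0.05, 0.1, 0.2, 0.4, 0.5),
                               r2_clump = 0.1, window_kb = 250) {
  check_that(length(thresholds) > 0, "thresholds must be non-empty")
  clumped <- clump(results, ds_train, r2_clump, window_kb)
  alt <- ds_train$variants$alt
  names(alt) <- ds_train$variants$vid
  lapply(thresholds, function(th) {
    vids <- results$vid[!is.na(results$p) & results$p <= th &
                          results$vid %in% clumped]
    if (length(vids) == 0) {
      return(structure(
        list(threshold = th, weights = NULL, intercept = NA_real_,
             slope = NA_real_, empty = TRUE),
        class = "prs_model"
      ))
    }
    w <- data.frame(
      vid = vids,
      effect_allele = unname(alt[vids]),
      beta = results$beta[match(vids, results$vid)],
      stringsAsFactors = FALSE
    )
    prs <- prs_score(ds_train, w)
    y <- ds_train$samples$phenotype
    ok <- !is.na(y)
    fit <- stats::glm(y[ok] ~ prs[ok], family = stats::binomial())
    structure(
      list(threshold = th, weights = w,
           intercept = unname(stats::coef(fit)[1]),
           slope = unname(stats::coef(fit)[2]), empty = FALSE),
      class = "prs_model"
    )
  })
}

#' Predicted case probability from a PRS model
#'
#' @param object a `prs_model`.
#' @param ds dataset to score.
#' @param ... unused.
#' @return Per-sample probabilities from the logistic calibration.
#' @export
predict.prs_model <- function(object, ds, ...) {
  check_that(!isTRUE(object$empty), "cannot predict from an empty PRS model")
  stats::plogis(object$intercept + object$slope * prs_score(ds, object))
}

#' Select the PRS threshold by validation AUC
#'
#' @param models list of `prs_model`s from [fit_threshold_grid()].
#' @param ds_valid validation [genotype_dataset()].
#' @return The model with the highest validation AUC (ties: the smaller
#'   threshold), with its `valid_auc` recorded.
#' @export
select_model <- function(models, ds_valid) {
  nonempty <- Filter(function(m) !isTRUE(m$empty), models)
  check_that(length(nonempty) > 0, "all candidate PRS models are empty")
  y <- ds_valid$samples$phenotype
  aucs <- vapply(nonempty, function(m) {
    roc_auc(predict(m, ds_valid), y)$auc
  }, numeric(1))
  ths <- vapply(nonempty, `[[`, numeric(1), "threshold")
  best <- order(-aucs, ths)[1]
  out <- nonempty[[best]]
  out$valid_auc <- aucs[best]
  out
}

#' @export
print.prs_model <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat(sprintf("<prs_model> threshold %g: empty (no variants retained)\n",
                x$threshold))
  } else {
    cat(sprintf("<prs_model> threshold %g: %d variants%s\n",
                x$threshold, nrow(x$weights),
                if (!is.null(x$valid_auc))
                  sprintf("; validation AUC %.3f", x$valid_auc) else ""))
  }
  invisible(x)
}
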