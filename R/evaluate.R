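# Held-out evaluation: ROC/AUC, bootstrap confidence intervals,
# Youden-optimal operating point, genotype-combination contingency tables,
# and deterministic stratified splits.

# Mann-Whitney AUC with midrank tie handling; y in {0,1}
auc_value <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney U statistic divided by n_case * n_control;
#' tied score pairs contribute 1/2. The ROC is evaluated at every distinct
#' score threshold (predict case when score >= threshold).
#'
#' @param scores numeric risk scores (higher = more case-like).
#' @param labels 0/1 class labels.
#' @return List with `roc` (data.frame `threshold`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  check_that(length(scores) == length(labels),
             "scores and labels must have equal length")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  check_that(length(unique(labels)) == 2 && all(labels %in% 0:1),
             "labels must contain both classes, coded 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  th <- sort(unique(scores))
  tp <- vapply(th, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(th, function(t) sum(scores >= t & labels == 0), numeric(1))
  roc <- data.frame(
    threshold = c(th, Inf),
    tp = c(tp, 0), fp = c(fp, 0),
    tn = n0 - c(fp, 0), fn = n1 - c(tp, 0)
  )
  roc$sensitivity <- roc$tp / n1
  roc$specificity <- roc$tn / n0
  list(roc = roc, auc = auc_value(scores, labels))
}

#' Bootstrap confidence interval for the AUC
#'
#' Resamples (score, label) pairs with replacement and reports the
#' percentile interval of the replicate AUCs. Resamples containing a
#' single class are redrawn (and counted).
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_iter bootstrap iterations (default 1e4; minimum 100).
#' @param alpha two-sided miscoverage (default 0.05 for a 95% interval).
#' @param seed integer seed; the routine owns its RNG stream.
#' @return List: `auc` (plug-in estimate), `auc_boot_mean` (mean of
#'   replicate AUCs), `ci` (length-2 percentile interval), `n_iter`,
#'   `n_redrawn`, `seed`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_iter = 10000, alpha = 0.05,
                             seed = 1L) {
  check_that(n_iter >= 100, "n_iter must be at least 100")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  check_that(length(unique(labels)) == 2, "both classes required")
  n <- length(scores)
  n_redrawn <- 0L
  reps <- with_seed(seed, {
    out <- numeric(n_iter)
    for (b in seq_len(n_iter)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
        n_redrawn <- n_redrawn + 1L
      }
      out[b] <- auc_value(scores[idx], labels[idx])
    }
    out
  })
  if (n_redrawn > 0) {
    warning(n_redrawn, " single-class bootstrap resample(s) redrawn")
  }
  list(
    auc = auc_value(scores, labels),
    auc_boot_mean = mean(reps),
    ci = unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                                type = 7)),
    n_iter = n_iter, n_redrawn = n_redrawn, seed = seed
  )
}

#' Youden-optimal operating point
#'
#' Maximizes J = sensitivity + specificity - 1 over the ROC thresholds
#' (ties broken towards higher specificity). Accuracy uses the evaluation
#' set's actual class mix.
#'
#' @param roc the `roc` data.frame from [roc_auc()].
#' @return List: `threshold`, `youden_j`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
youden_point <- function(roc) {
  check_that(nrow(roc) > 0, "empty ROC")
  j <- roc$sensitivity + roc$specificity - 1
  best <- order(-j, -roc$specificity)[1]
  n <- roc$tp[best] + roc$fp[best] + roc$tn[best] + roc$fn[best]
  list(
    threshold = roc$threshold[best],
    youden_j = j[best],
    accuracy = (roc$tp[best] + roc$tn[best]) / n,
    sensitivity = roc$sensitivity[best],
    specificity = roc$specificity[best]
  )
}

#' Full held-out evaluation report
#'
#' Combines the ROC/AUC, the bootstrap AUC interval and the
#' Youden-optimal operating point into one record (one row of a model
#' performance table).
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot bootstrap iterations.
#' @param seed RNG seed for the bootstrap.
#' @return An `eval_report` list: `auc`, `auc_boot_mean`, `ci_low`,
#'   `ci_high`, `youden_j`, `threshold_at_j`, `accuracy`, `sensitivity`,
#'   `specificity`, `n_boot`, `seed`, plus the `roc` table.
#' @export
evaluate_classifier <- function(scores, labels, n_boot = 10000, seed = 1L) {
  ra <- roc_auc(scores, labels)
  bs <- bootstrap_auc_ci(scores, labels, n_iter = n_boot, seed = seed)
  yp <- youden_point(ra$roc)
  structure(
    list(auc = ra$auc, auc_boot_mean = bs$auc_boot_mean,
         ci_low = bs$ci[1], ci_high = bs$ci[2],
         youden_j = yp$youden_j, threshold_at_j = yp$threshold,
         accuracy = yp$accuracy, sensitivity = yp$sensitivity,
         specificity = yp$specificity, n_boot = n_boot, seed = seed,
         roc = ra$roc),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> AUC %.3f [%.3f; %.3f] | acc %.2f sens %.2f spec %.2f | J %.2f\n",
    x$auc, x$ci_low, x$ci_high, x$accuracy, x$sensitivity, x$specificity,
    x$youden_j
  ))
  invisible(x)
}

#' Genotype-combination contingency table
#'
#' Cross-classifies samples by the named genotypes of a set of variants
#' (typically the two members of a discovered interaction). For each
#' variant the strata are its listed genotypes plus `"-"` (any other
#' genotype); the table covers the full cross-product, so the strata
#' partition the samples. Percentages are row-wise case/control shares
#' rounded to one decimal.
#'
#' @param ds a [genotype_dataset()] with phenotypes.
#' @param conditions list of `list(vid =, genotypes =)` entries, where
#'   `genotypes` are the dosage levels (0/1/2) given named strata.
#' @return data.frame with columns `combination`, `cases`, `controls`,
#'   `case_pct`, `control_pct` (percentages `NA` for empty strata).
#' @export
combo_table <- function(ds, conditions) {
  check_that(length(conditions) >= 1, "need at least one variant")
  y <- ds$samples$phenotype
  levels_per <- lapply(conditions, function(cn) {
    check_that(cn$vid %in% ds$variants$vid,
               paste("unknown variant:", cn$vid))
    c(as.list(cn$genotypes), list(NA))   # NA marks the "-" stratum
  })
  vrows <- match(vapply(conditions, `[[`, character(1), "vid"),
                 ds$variants$vid)
  grid <- expand.grid(lapply(levels_per, seq_along))
  out <- lapply(seq_len(nrow(grid)), function(r) {
    inside <- rep(TRUE, nrow(ds$genotypes))
    labels <- character(length(conditions))
    for (k in seq_along(conditions)) {
      lv <- levels_per[[k]][[grid[r, k]]]
      g <- ds$genotypes[, conditions[[k]]$vid]
      if (is.null(lv) || length(lv) == 0 || is.na(lv)) {
        # "-": none of the listed genotypes for this variant
        listed <- unlist(conditions[[k]]$genotypes)
        inside <- inside & (is.na(g) | !(g %in% listed))
        labels[k] <- "-"
      } else {
        inside <- inside & !is.na(g) & g == lv
        labels[k] <- paste0(
          conditions[[k]]$vid, "_",
          genotype_label(ds$variants$ref[vrows[k]],
                         ds$variants$alt[vrows[k]], lv)
        )
      }
    }
    cases <- sum(inside & !is.na(y) & y == 1)
    controls <- sum(inside & !is.na(y) & y == 0)
    tot <- cases + controls
    data.frame(
      combination = paste(labels, collapse = "/"),
      cases = cases, controls = controls,
      case_pct = if (tot > 0) round(100 * cases / tot, 1) else NA_real_,
      control_pct = if (tot > 0) round(100 * controls / tot, 1) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Deterministic stratified train/validation/test split
#'
#' Allocates the requested sizes, stratified by class as closely as the
#' sizes allow (largest-remainder apportionment), with a seed-owned RNG.
#'
#' @param ds a [genotype_dataset()].
#' @param sizes integer vector of split sizes (named or not), summing to
#'   at most the sample count; default `c(train = 367, valid = 33,
#'   test = 36)`.
#' @param seed integer seed.
#' @return Named list of [genotype_dataset()]s, one per split.
#' @export
make_split <- function(ds, sizes = c(train = 367, valid = 33, test = 36),
                       seed = 1L) {
  n <- nrow(ds$genotypes)
  check_that(sum(sizes) <= n, "split sizes exceed sample count")
  if (is.null(names(sizes))) {
    names(sizes) <- paste0("split", seq_along(sizes))
  }
  y <- ds$samples$phenotype
  strata <- split(seq_len(n), factor(ifelse(is.na(y), "na", y)))
  with_seed(seed, {
    strata <- lapply(strata, sample)       # shuffle within stratum
    # largest-remainder apportionment of each split across strata
    alloc <- matrix(0L, nrow = length(sizes), ncol = length(strata),
                    dimnames = list(names(sizes), names(strata)))
    remaining <- vapply(strata, length, integer(1))
    for (s in seq_along(sizes)) {
      quota <- sizes[s] * remaining / sum(remaining)
      base <- pmin(floor(quota), remaining)
      short <- sizes[s] - sum(base)
      if (short > 0) {
        ord <- order(-(quota - base))
        for (k in ord) {
          if (short == 0) break
          if (base[k] < remaining[k]) {
            base[k] <- base[k] + 1L
            short <- short - 1L
          }
        }
      }
      alloc[s, ] <- base
      remaining <- remaining - base
    }
    taken <- lapply(strata, function(x) 0L)
    out <- vector("list", length(sizes))
    names(out) <- names(sizes)
    for (s in seq_along(sizes)) {
      idx <- integer()
      for (k in seq_along(strata)) {
        a <- alloc[s, k]
        if (a > 0) {
          idx <- c(idx, strata[[k]][taken[[k]] + seq_len(a)])
          taken[[k]] <- taken[[k]] + a
        }
      }
      out[[s]] <- subset_dataset(ds, samples = sort(idx))
    }
    out
  })
}
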