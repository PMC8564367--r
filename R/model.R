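# Final model: hypothesis indicators -> L1-penalized logistic regression
# (glmnet), lambda chosen by stratified k-fold cross-validated deviance.

#' Build the hypothesis feature matrix
#'
#' One binary indicator column per selected hypothesis (via
#' [encode_hypothesis()]). Hypotheses referencing variants absent from the
#' dataset (e.g. removed by QC) are dropped with a warning; duplicate
#' indicator columns are collapsed to the first id (merges logged as an
#' attribute).
#'
#' @param ds a [genotype_dataset()].
#' @param selected a `selected_features` data.frame from
#'   [run_selection()], or a character vector of hypothesis ids.
#' @param collapse collapse duplicate indicator columns (default TRUE;
#'   use FALSE when building features for prediction, where every model
#'   term must stay addressable).
#' @return Binary matrix samples x hypotheses with attribute `merged`
#'   (named list of collapsed ids).
#' @export
build_features <- function(ds, selected, collapse = TRUE) {
  ids <- if (is.character(selected)) selected else selected$id
  check_that(length(ids) > 0, "no hypotheses supplied")
  hyps <- lapply(ids, parse_hypothesis)
  known <- vapply(hyps, function(h) all(h$vids %in% ds$variants$vid),
                  logical(1))
  if (!all(known)) {
    warning(sum(!known),
            " hypothesis(es) reference variants absent from the dataset; dropped")
    hyps <- hyps[known]; ids <- ids[known]
  }
  check_that(length(hyps) > 0, "no scorable hypotheses remain")
  X <- vapply(hyps, encode_hypothesis, integer(nrow(ds$genotypes)), ds = ds)
  X <- matrix(X, nrow = nrow(ds$genotypes),
              dimnames = list(ds$samples$sid, ids))
  key <- apply(X, 2, paste, collapse = "")
  dup <- if (collapse) duplicated(key) else rep(FALSE, ncol(X))
  merged <- list()
  if (any(dup)) {
    for (k in unique(key[dup])) {
      grp <- ids[key == k]
      merged[[grp[1]]] <- grp[-1]
    }
    X <- X[, !dup, drop = FALSE]
  }
  attr(X, "merged") <- merged
  X
}

# deterministic stratified fold assignment
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

#' Fit the L1-penalized logistic model with cross-validated lambda
#'
#' `cv.glmnet` over the lasso path with stratified `k_folds`-fold
#' cross-validation. By default lambda is chosen by the one-standard-error
#' rule on the mean CV binomial deviance (the sparser choice, which keeps
#' the model essentially empty on label-noise inputs); `lambda_rule =
#' "min"` takes the deviance minimum instead. The model is refit at the
#' chosen lambda on the full input. Deterministic given `seed`.
#'
#' @param features binary feature matrix from [build_features()].
#' @param labels 0/1 phenotype vector.
#' @param k_folds CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @return An `l1_model`: `coef` (named nonzero coefficients),
#'   `intercept`, `lambda`, `k_folds`, `seed`, `feature_ids`.
#' @export
fit_l1_cv <- function(features, labels, k_folds = 5L, seed = 1L,
                      lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  check_that(k_folds >= 2, "k_folds must be >= 2")
  check_that(length(unique(labels)) == 2, "both classes required")
  check_that(nrow(features) == length(labels),
             "feature rows must match labels")
  X <- as.matrix(features)
  pad <- ncol(X) < 2
  if (pad) X <- cbind(X, `.pad` = 0)       # glmnet needs >= 2 columns
  with_seed(seed, {
    foldid <- stratified_folds(labels, k_folds)
    cv <- glmnet::cv.glmnet(X, labels, family = "binomial", alpha = 1,
                            foldid = foldid, type.measure = "deviance",
                            standardize = FALSE)
    s <- if (lambda_rule == "min") "lambda.min" else "lambda.1se"
    cf <- as.matrix(stats::coef(cv, s = s))
    beta <- cf[-1, 1]
    beta <- beta[names(beta) != ".pad"]
    structure(
      list(coef = beta[beta != 0], intercept = cf[1, 1],
           lambda = cv[[s]], k_folds = as.integer(k_folds),
           seed = as.integer(seed), lambda_rule = lambda_rule,
           feature_ids = setdiff(colnames(X), ".pad"),
           cv_deviance = min(cv$cvm)),
      class = "l1_model"
    )
  })
}

#' @export
print.l1_model <- function(x, ...) {
  cat(sprintf("<l1_model> %d nonzero term(s), lambda %.4g (%d-fold CV)\n",
              length(x$coef), x$lambda, x$k_folds))
  invisible(x)
}

#' Fit the L1 path on training data, tuning lambda on a validation set
#'
#' The lasso path is fitted to the training features and the penalty is
#' chosen where the binomial deviance on the held-aside validation set is
#' minimal (ties towards the heavier penalty). Because the validation
#' labels played no part in hypothesis selection or the path fit, terms
#' that only reflect training-set selection optimism do not generalize
#' and are penalized away -- on label-noise inputs the tuned model is
#' essentially always empty, while genuinely predictive terms keep their
#' full-training-set coefficients.
#'
#' @param features_train,labels_train training feature matrix and 0/1
#'   labels.
#' @param features_valid,labels_valid validation feature matrix (same
#'   columns) and labels.
#' @param se_factor size of the standard-error guard in units of the
#'   validation deviance's standard error (default 1).
#' @return An `l1_model` (as in [fit_l1_cv()]) with `lambda_rule =
#'   "validation"` and the validation deviance per path knot in
#'   `valid_deviance`.
#' @export
fit_l1_valid <- function(features_train, labels_train,
                         features_valid, labels_valid, se_factor = 1) {
  check_that(length(unique(labels_train)) == 2, "both classes required")
  X <- as.matrix(features_train)
  Xv <- as.matrix(features_valid)
  check_that(identical(colnames(X), colnames(Xv)),
             "training and validation features must share columns")
  pad <- ncol(X) < 2
  if (pad) {
    X <- cbind(X, `.pad` = 0)
    Xv <- cbind(Xv, `.pad` = 0)
  }
  fit <- glmnet::glmnet(X, labels_train, family = "binomial", alpha = 1,
                        standardize = FALSE)
  pv <- stats::predict(fit, Xv, type = "response")
  eps <- 1e-12
  d_i <- -2 * (labels_valid * log(pmax(pv, eps)) +
                 (1 - labels_valid) * log(pmax(1 - pv, eps)))
  dev <- colMeans(d_i)
  # one-standard-error guard: the heaviest penalty whose validation
  # deviance is within one SE of the minimum (33-sample deviance curves
  # are noisy; without the guard chance dips at light penalties win)
  i_min <- which.min(dev)
  # guard on the PAIRED deviance difference to the best knot: the curves
  # share the same samples, so the marginal deviance SE vastly overstates
  # the comparison uncertainty
  se <- apply(d_i - d_i[, i_min], 2, stats::sd) / sqrt(nrow(Xv))
  # lambdas decrease along the path: first qualifying = heaviest penalty
  best <- which(dev <= dev[i_min] + se_factor * se)[1]
  cf <- as.matrix(stats::coef(fit, s = fit$lambda[best]))
  beta <- cf[-1, 1]
  beta <- beta[names(beta) != ".pad"]
  structure(
    list(coef = beta[beta != 0], intercept = cf[1, 1],
         lambda = fit$lambda[best], k_folds = NA_integer_,
         seed = NA_integer_, lambda_rule = "validation",
         feature_ids = setdiff(colnames(X), ".pad"),
         valid_deviance = dev),
    class = "l1_model"
  )
}

#' Signed coefficient report
#'
#' Nonzero model terms sorted by absolute coefficient, with their
#' condition strings; negative coefficients mark protective combinations,
#' positive ones risk combinations. The distinct-SNP count is the number
#' of distinct variants appearing across nonzero terms.
#'
#' @param model an `l1_model`.
#' @param selected optional `selected_features` (for carrier counts).
#' @return data.frame (`id`, `conditions`, `coefficient`, `direction`)
#'   with attribute `snp_count`.
#' @export
coefficient_report <- function(model, selected = NULL) {
  cf <- model$coef
  if (length(cf) == 0) {
    out <- data.frame(id = character(), conditions = character(),
                      coefficient = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
    attr(out, "snp_count") <- 0L
    return(out)
  }
  ord <- order(-abs(cf))
  ids <- names(cf)[ord]
  out <- data.frame(
    id = ids, conditions = ids, coefficient = unname(cf[ord]),
    direction = ifelse(cf[ord] > 0, "risk", "protective"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  vids <- unique(unlist(lapply(ids, function(i) parse_hypothesis(i)$vids)))
  attr(out, "snp_count") <- length(vids)
  out
}

#' Predicted case probability from an L1 model
#'
#' @param object an `l1_model`.
#' @param features feature matrix whose columns cover the model's nonzero
#'   terms.
#' @param ... unused.
#' @return Per-sample probabilities in (0, 1).
#' @export
predict.l1_model <- function(object, features, ...) {
  terms <- names(object$coef)
  missing_cols <- setdiff(terms, colnames(features))
  check_that(length(missing_cols) == 0,
             paste("missing feature column(s):",
                   paste(missing_cols, collapse = ", ")))
  eta <- rep(object$intercept, nrow(features))
  if (length(terms)) {
    eta <- eta + drop(as.matrix(features[, terms, drop = FALSE]) %*%
                        object$coef)
  }
  stats::plogis(eta)
}

#' Serialize an L1 model to JSON
#'
#' @param model an `l1_model`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept, lambda = model$lambda,
         k_folds = model$k_folds, seed = model$seed,
         terms = as.list(model$coef)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
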