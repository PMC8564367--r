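#' Multiplicity-adjusted screen of selected hypotheses
#'
#' The search scores `n_scored` hypotheses while hill-climbing on the
#' training labels, so the selected set's top scores are maxima over
#' many draws and carry selection optimism; with few carriers the
#' deviance score's chi-squared approximation is also anti-conservative.
#' This screen therefore tests each selected hypothesis's carrier/case
#' 2x2 table with Fisher's exact test -- valid at any stratum size --
#' and keeps those with `p < alpha / n_scored` (Bonferroni over
#' everything the search scored). Under a global null the screened set
#' is empty with probability at least about `1 - alpha`; planted
#' associations of practical size pass by orders of magnitude.
#'
#' @param selected a `selected_features` data.frame from
#'   [run_selection()] (its `n_scored` attribute supplies the
#'   multiplicity; falls back to the row count).
#' @param ds the training [genotype_dataset()] the selection ran on.
#' @param alpha family-wise error rate of the screen (default 0.01;
#'   conservative because the search's adaptive hill-climbing makes the
#'   effective multiplicity larger than the realized score count).
#' @return The filtered `selected_features` (possibly zero rows) with a
#'   `fisher_p` column and attribute `screen_cut` (the per-test
#'   threshold used).
#' @export
screen_hypotheses <- function(selected, ds, alpha = 0.01) {
  n_scored <- attr(selected, "n_scored") %||% nrow(selected)
  cut <- alpha / max(n_scored, 1)
  y <- ds$samples$phenotype
  ok <- !is.na(y)
  cand <- selected[!selected$degenerate, , drop = FALSE]
  p <- vapply(cand$id, function(id) {
    ind <- encode_hypothesis(parse_hypothesis(id), ds)[ok]
    tab <- table(factor(ind, levels = 0:1), factor(y[ok], levels = 0:1))
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  cand$fisher_p <- unname(p)
  out <- cand[cand$fisher_p < cut, , drop = FALSE]
  attr(out, "screen_cut") <- cut
  out
}

# intercept-only fallback when no hypothesis survives screening
null_l1_model <- function(labels) {
  structure(
    list(coef = stats::setNames(numeric(0), character(0)),
         intercept = stats::qlogis(mean(labels)), lambda = Inf,
         k_folds = NA_integer_, seed = NA_integer_,
         lambda_rule = "empty", feature_ids = character()),
    class = "l1_model"
  )
}

#' Run the full case/control analysis pipeline on one dataset
#'
#' Splits the data (stratified train/validation/test), runs the
#' association scan on the training set, fits the clumping+thresholding
#' PRS baseline (threshold chosen on validation AUC), runs the
#' prior-graph-guided interaction search on the training set, screens
#' the selected hypotheses for multiplicity-adjusted significance
#' ([screen_hypotheses()]), fits the L1-penalized logistic model over
#' the surviving hypothesis indicators (lambda by stratified 5-fold CV
#' on the training set), and evaluates both models on the held-out test
#' set with bootstrap AUC intervals. If no hypothesis survives the
#' screen the final model is the intercept-only null model.
#'
#' @param ds a [genotype_dataset()] with phenotypes.
#' @param graph a [prior_graph()] over the dataset's variants.
#' @param seed integer seed driving the split, the search, the CV folds
#'   and the bootstrap.
#' @param split_sizes named sizes for [make_split()] (default
#'   `c(train = 367, valid = 33, test = 36)`).
#' @param select_cfg a [select_config()] (its seed is overridden by
#'   `seed`).
#' @param n_boot bootstrap iterations for the evaluation (default 1e4).
#' @param prs_thresholds p-value grid for the PRS baseline.
#' @param lambda_tuning `"train_cv"` (default): stratified 5-fold
#'   cross-validated penalty on the training split via [fit_l1_cv()];
#'   `"validation"`: penalty chosen by validation-set deviance via
#'   [fit_l1_valid()]. Applied after the multiplicity screen.
#' @param screen_alpha family-wise error rate of
#'   [screen_hypotheses()] between selection and the lasso
#'   (default 0.01).
#' @return List: `assoc`, `prs_model`, `prs_eval`, `selected`,
#'   `screened`, `model`, `model_eval`, `splits`.
#' @export
run_pipeline <- function(ds, graph, seed = 1L,
                         split_sizes = c(train = 367, valid = 33, test = 36),
                         select_cfg = select_config(),
                         n_boot = 10000,
                         prs_thresholds = c(0.001, 0.05, 0.1, 0.2, 0.4, 0.5),
                         lambda_tuning = c("train_cv", "validation"),
                         screen_alpha = 0.01) {
  splits <- make_split(ds, split_sizes, seed = seed)
  train <- splits[[1]]; valid <- splits[[2]]; test <- splits[[3]]

  res <- assoc_scan(train)

  grid <- fit_threshold_grid(res, train, thresholds = prs_thresholds)
  prs_model <- tryCatch(select_model(grid, valid), error = function(e) NULL)
  prs_eval <- if (!is.null(prs_model)) {
    evaluate_classifier(predict(prs_model, test), test$samples$phenotype,
                        n_boot = n_boot, seed = child_seed(seed, 11))
  }

  select_cfg$seed <- child_seed(seed, 23)
  selected <- run_selection(train, graph, select_cfg)
  screened <- screen_hypotheses(selected, train, alpha = screen_alpha)

  if (nrow(screened) == 0) {
    model <- null_l1_model(train$samples$phenotype)
    feats_test <- matrix(0, nrow(test$genotypes), 0)
  } else {
    feats_train <- build_features(train, screened, collapse = FALSE)
    feats_valid <- build_features(valid, screened, collapse = FALSE)
    model <- switch(
      match.arg(lambda_tuning),
      train_cv = fit_l1_cv(feats_train, train$samples$phenotype,
                           k_folds = 5L, seed = child_seed(seed, 37)),
      validation = fit_l1_valid(feats_train, train$samples$phenotype,
                                feats_valid, valid$samples$phenotype)
    )
    feats_test <- build_features(test, screened, collapse = FALSE)
  }
  model_eval <- evaluate_classifier(predict(model, feats_test),
                                    test$samples$phenotype,
                                    n_boot = n_boot,
                                    seed = child_seed(seed, 41))

  list(assoc = res, prs_model = prs_model, prs_eval = prs_eval,
       selected = selected, screened = screened, model = model,
       model_eval = model_eval, splits = splits)
}

#' Did a selection recover a planted interaction?
#'
#' A planted interaction counts as recovered when some selected,
#' non-degenerate hypothesis contains all of its (variant, genotype)
#' conditions.
#'
#' @param selected a `selected_features` data.frame.
#' @param interaction a truth record with elements `vids` and either
#'   `genotypes` or an `id` in canonical form.
#' @return TRUE/FALSE.
#' @export
recovered_interaction <- function(selected, interaction) {
  target <- if (!is.null(interaction$id)) {
    parse_hypothesis(interaction$id)
  } else {
    hypothesis(interaction$vids, interaction$genotypes)
  }
  want <- paste0(target$vids, ":", target$genotypes)
  ok <- selected[!selected$degenerate, , drop = FALSE]
  any(vapply(ok$id, function(id) {
    all(want %in% strsplit(id, ";", fixed = TRUE)[[1]])
  }, logical(1)))
}
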