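# Graph-guided hypothesis search: encoding, scoring, proposing, refining,
# propensity updates, convergence and recovery.

make_state <- function(seed = 1, n = 200, m = 12, graph = NULL, ...) {
  ds <- random_dataset(n = n, m = m, seed = seed, phenotype = TRUE,
                       maf_range = c(0.25, 0.5))
  if (is.null(graph)) {
    graph <- prior_graph(
      data.frame(id = ds$variants$vid, kind = "variant", matched = TRUE),
      data.frame(from = character(), to = character(), weight = numeric(),
                 source = character())
    )
  }
  search_state(ds, graph, select_config(seed = seed, ...))
}

test_that("hypothesis ids are canonical and conditions validated", {
  h1 <- hypothesis(c("b", "a"), c(2L, 1L))
  h2 <- hypothesis(c("a", "b"), c(1L, 2L))
  expect_identical(hypothesis_id(h1), hypothesis_id(h2))
  expect_error(hypothesis(c("a", "a"), c(1L, 1L)), "distinct")
  expect_error(hypothesis("a", 3L), "genotype")
  expect_error(hypothesis(character(), integer()), "at least one")
})

test_that("encoding is exact-genotype conjunction with missing as non-carrier", {
  g <- matrix(c(0L, 1L, 2L, NA,
                2L, 2L, 2L, 2L), nrow = 4)
  ds <- tiny_dataset(g)
  expect_identical(encode_hypothesis(hypothesis("v001", 2L), ds),
                   c(0L, 0L, 1L, 0L))
  # conjunction equals the AND of single-condition indicators
  both <- encode_hypothesis(hypothesis(c("v001", "v002"), c(1L, 2L)), ds)
  a <- encode_hypothesis(hypothesis("v001", 1L), ds)
  b <- encode_hypothesis(hypothesis("v002", 2L), ds)
  expect_identical(both, as.integer(a & b))
  expect_error(encode_hypothesis(hypothesis("nope", 1L), ds), "unknown")
})

test_that("null hypothesis scores behave like chi-squared(1)", {
  scores <- withr::with_seed(12, vapply(1:200, function(i) {
    y <- rbinom(250, 1, 0.6)
    ind <- rbinom(250, 1, 0.25)
    ds <- tiny_dataset(cbind(ind), phenotype = y)   # indicator as genotype
    score_hypothesis(hypothesis("v001", 1L), ds)$fit_score
  }, numeric(1)))
  expect_lt(abs(mean(scores) - 1), 0.35)
  expect_gt(mean(scores < 5), 0.93)
})

test_that("perfect and planted predictors score high; tiny strata degenerate", {
  withr::with_seed(3, {
    y <- rbinom(300, 1, 0.5)
    ds <- tiny_dataset(cbind(as.integer(y), rbinom(300, 1, 0.3)),
                       phenotype = y)
    perfect <- score_hypothesis(hypothesis("v001", 1L), ds)
    other <- score_hypothesis(hypothesis("v002", 1L), ds)
    expect_gt(perfect$fit_score, other$fit_score)
    expect_true(perfect$separated)

    # a stratum shaped like a strong observed combination: 87% case rate
    # among 31 carriers of 436 against a 2:1 background
    ind <- c(rep(1L, 31), rep(0L, 405))
    yy <- c(rbinom(31, 1, 0.87), rbinom(405, 1, 0.65))
    ds2 <- tiny_dataset(cbind(ind), phenotype = yy)
    planted <- score_hypothesis(hypothesis("v001", 1L), ds2)
    expect_gt(planted$fit_score, qchisq(0.95, df = 1))
    expect_identical(planted$direction, 1)

    few <- tiny_dataset(cbind(c(rep(1L, 3), rep(0L, 97))),
                        phenotype = rbinom(100, 1, 0.5))
    deg <- score_hypothesis(hypothesis("v001", 1L), few, min_carriers = 5)
    expect_true(deg$degenerate)
    expect_identical(deg$fit_score, 0)
  })
})

test_that("proposals are propensity-uniform when flat and graph-bound when rho=1", {
  st <- make_state(seed = 5, m = 10)
  # marginal variant frequencies approximately uniform over many draws
  counts <- withr::with_seed(11, {
    tab <- table(unlist(lapply(1:1500, function(i) {
      h <- episelect:::propose_one(st)
      h$vids
    })))
    tab
  })
  freq <- as.numeric(counts) / sum(counts)
  expect_true(all(abs(freq - 1 / 10) < 0.03))

  # connected two-variant component with rho = 1: multi-variant proposals
  # never leave the component
  nodes <- data.frame(id = c("v001", "v002", "g1"),
                      kind = c("variant", "variant", "gene"),
                      matched = TRUE)
  edges <- data.frame(from = c("v001", "v002"), to = "g1", weight = 1,
                      source = "x")
  ds <- random_dataset(n = 100, m = 2, seed = 6, phenotype = TRUE,
                       maf_range = c(0.3, 0.5))
  st2 <- search_state(ds, prior_graph(nodes, edges),
                      select_config(rho = 1, max_order = 2, seed = 1))
  props <- with(list(), withr::with_seed(2, propose(st2, 20)))
  multi <- Filter(function(h) length(h$vids) > 1, props)
  for (h in multi) expect_setequal(h$vids, c("v001", "v002"))
})

test_that("proposal stream is deterministic given the seed and avoids archive", {
  g <- NULL
  run <- function() {
    st <- make_state(seed = 9, m = 8)
    withr::with_seed(4, vapply(propose(st, 15), hypothesis_id, character(1)))
  }
  ids1 <- run(); ids2 <- run()
  expect_identical(ids1, ids2)
  expect_false(anyDuplicated(ids1) > 0)
})

test_that("refinement enumerates exactly the edit-distance-1 neighborhood", {
  # 5-variant toy graph: v1-v2 share a gene, v3 isolated, v4-v5 share one
  nodes <- data.frame(
    id = c(sprintf("v%03d", 1:5), "gA", "gB"),
    kind = c(rep("variant", 5), "gene", "gene"), matched = TRUE)
  edges <- data.frame(from = c("v001", "v002", "v004", "v005"),
                      to = c("gA", "gA", "gB", "gB"),
                      weight = 1, source = "x")
  ds <- random_dataset(n = 300, m = 5, seed = 8, maf_range = c(0.3, 0.5),
                       phenotype = TRUE)
  st <- search_state(ds, prior_graph(nodes, edges),
                     select_config(max_order = 2, min_carriers = 5, seed = 1))
  h <- hypothesis("v001", 1L)
  nb <- refine(h, st)
  ids <- vapply(nb, hypothesis_id, character(1))

  # brute-force enumeration of the same move set
  adm <- episelect:::admissible_genotypes(ds, 5)
  expected <- character()
  for (gg in setdiff(adm[["v001"]], 1L)) {            # genotype change
    expected <- c(expected, hypothesis_id(hypothesis("v001", gg)))
  }
  for (gg in adm[["v002"]]) {                          # swap to neighbor
    expected <- c(expected, hypothesis_id(hypothesis("v002", gg)))
  }
  for (gg in adm[["v002"]]) {                          # extension
    expected <- c(expected,
                  hypothesis_id(hypothesis(c("v001", "v002"), c(1L, gg))))
  }
  expect_setequal(ids, unique(expected))
  # every neighbor differs by exactly one edit
  for (x in nb) {
    shared <- intersect(paste0(x$vids, ":", x$genotypes),
                        paste0(h$vids, ":", h$genotypes))
    expect_true(length(shared) %in% c(0L, 1L))
  }
  # an order-2 hypothesis can drop either condition
  h2 <- hypothesis(c("v001", "v002"), c(1L, 1L))
  ids2 <- vapply(refine(h2, st), hypothesis_id, character(1))
  expect_true(all(c(hypothesis_id(hypothesis("v001", 1L)),
                    hypothesis_id(hypothesis("v002", 1L))) %in% ids2))
})

test_that("propensity updates follow the multiplicative-weights formula", {
  st <- make_state(seed = 2, m = 6)
  mk <- function(id, s) structure(list(id = id, fit_score = s,
                                       carriers = 20, direction = 1,
                                       degenerate = FALSE, separated = FALSE),
                                  class = "hypothesis_score")
  # equal scores: fixed point
  before <- st$propensity
  update_propensities(st, list(mk("v001:1", 2), mk("v002:1", 2)), eta = 0.3)
  expect_equal(st$propensity, before, tolerance = 1e-12)

  # high-scoring variant gains, and the update matches a hand computation
  st2 <- make_state(seed = 2, m = 3)
  batch <- list(mk("v001:1;v002:1", 6), mk("v002:2", 3), mk("v003:0", 0))
  update_propensities(st2, batch, eta = 0.5)
  baseline <- mean(c(6, 3, 0))
  adv <- c(v001 = 6 - baseline, v002 = mean(c(6, 3)) - baseline,
           v003 = 0 - baseline)
  w <- exp(0.5 * adv)
  expect_equal(unname(st2$propensity), unname(w / sum(w) * 3),
               tolerance = 1e-12)
  expect_gt(st2$propensity["v001"], 1)
  expect_true(all(st2$propensity > 0) && all(is.finite(st2$propensity)))
})

test_that("propensities stay positive and finite over many updates", {
  st <- make_state(seed = 4, m = 5)
  withr::with_seed(21, {
    for (i in 1:200) {
      ids <- paste0(sprintf("v%03d", sample(5, 2)), ":", sample(0:2, 2, TRUE))
      batch <- lapply(seq_along(ids), function(j) {
        structure(list(id = ids[j], fit_score = rexp(1, 1 / 3),
                       carriers = 10, direction = 1, degenerate = FALSE,
                       separated = FALSE), class = "hypothesis_score")
      })
      update_propensities(st, batch)
    }
  })
  expect_true(all(st$propensity > 0))
  expect_true(all(is.finite(st$propensity)))
  expect_equal(sum(st$propensity), 5, tolerance = 1e-9)
})

test_that("run_selection is deterministic, bounded and converges on null data", {
  sim <- simulate_study(preset_config("null", seed = 31))
  cfg <- select_config(seed = 77, max_rounds = 15)
  sel1 <- run_selection(sim$dataset, sim$graph, cfg)
  sel2 <- run_selection(sim$dataset, sim$graph, cfg)
  expect_identical(sel1$id, sel2$id)
  expect_identical(attr(sel1, "round_means"), attr(sel2, "round_means"))
  expect_lte(nrow(sel1), 99)
  expect_false(anyDuplicated(sel1$id) > 0)
  # null scores stay within chi-squared(1) expectations: the bulk of the
  # archive is unremarkable even though the selected head is the maximum
  # of many null draws
  st <- attr(sel1, "state")
  arch <- as.list(st$archive)
  all_scores <- vapply(arch, `[[`, numeric(1), "fit_score")
  expect_lt(mean(all_scores), 2.5)
  expect_lt(mean(all_scores > qchisq(0.999, 1)), 0.02)
})

test_that("an informative graph recovers a planted interaction; an
           uninformative one recovers less", {
  reps <- 6
  rec <- matrix(NA, reps, 2, dimnames = list(NULL, c("info", "noinfo")))
  for (i in seq_len(reps)) {
    seed <- 800 + i
    for (cov in c(1, 0)) {
      sim <- simulate_study(preset_config("epistatic_ppmi_like",
                                          seed = seed,
                                          graph_coverage = cov))
      sel <- run_selection(sim$dataset, sim$graph,
                           select_config(seed = seed))
      rec[i, if (cov == 1) "info" else "noinfo"] <-
        recovered_interaction(sel, sim$truth$interactions[[1]])
    }
  }
  expect_gte(mean(rec[, "info"]), 0.8)
  expect_gt(mean(rec[, "info"]), mean(rec[, "noinfo"]))
})
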