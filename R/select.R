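# Prior-graph-guided search over multi-variant genotype-combination
# hypotheses. A hypothesis is a conjunction of exact (variant, genotype)
# conditions; its predictive power is the deviance improvement of the
# logistic fit phenotype ~ carrier-indicator. Variant sampling
# propensities on the knowledge graph are the search's learned state and
# receive multiplicative-weights updates from scored batches.

#' Construct an interaction hypothesis
#'
#' A conjunction of exact genotype conditions over distinct variants; the
#' canonical id is the sorted `vid:genotype` list joined by `;`, so two
#' hypotheses with the same condition set share an id.
#'
#' @param vids variant ids (distinct).
#' @param genotypes dosage conditions in `{0, 1, 2}`, one per variant.
#' @return A `hypothesis` object.
#' @export
hypothesis <- function(vids, genotypes) {
  check_that(length(vids) >= 1, "a hypothesis needs at least one condition")
  check_that(length(vids) == length(genotypes),
             "vids and genotypes must have equal length")
  check_that(!anyDuplicated(vids), "variants within a hypothesis distinct")
  check_that(all(genotypes %in% 0:2), "genotype conditions must be 0, 1 or 2")
  ord <- order(vids)
  structure(
    list(vids = vids[ord], genotypes = as.integer(genotypes[ord])),
    class = "hypothesis"
  )
}

#' @export
print.hypothesis <- function(x, ...) {
  cat("<hypothesis>", hypothesis_id(x), "\n")
  invisible(x)
}

#' Canonical id of a hypothesis
#'
#' @param h a [hypothesis()].
#' @return The canonical string id.
#' @export
hypothesis_id <- function(h) {
  paste(paste0(h$vids, ":", h$genotypes), collapse = ";")
}

parse_hypothesis <- function(id) {
  parts <- strsplit(strsplit(id, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  hypothesis(vapply(parts, `[`, character(1), 1),
             as.integer(vapply(parts, `[`, character(1), 2)))
}

#' Carrier indicator of a hypothesis
#'
#' Sample i maps to 1 iff every condition matches its non-missing
#' genotype; any missing genotype among the conditioned variants maps the
#' sample to 0.
#'
#' @param h a [hypothesis()].
#' @param ds a [genotype_dataset()] containing all conditioned variants.
#' @return Integer 0/1 vector over samples.
#' @export
encode_hypothesis <- function(h, ds) {
  check_that(all(h$vids %in% ds$variants$vid),
             paste("unknown variant(s):",
                   paste(setdiff(h$vids, ds$variants$vid), collapse = ", ")))
  g <- ds$genotypes[, h$vids, drop = FALSE]
  ind <- rep(1L, nrow(g))
  for (k in seq_along(h$vids)) {
    ind <- ind & !is.na(g[, k]) & g[, k] == h$genotypes[k]
  }
  as.integer(ind)
}

#' Score a hypothesis on training data
#'
#' Predictive power is the likelihood-ratio improvement of the logistic
#' fit `phenotype ~ indicator`: fit_score = null deviance - residual
#' deviance (asymptotically chi-squared with 1 df under the null).
#' Hypotheses with fewer than `min_carriers` carriers or non-carriers are
#' degenerate and score 0; complete separation among carriers is flagged
#' but the (finite) deviance improvement is kept.
#'
#' @param h a [hypothesis()].
#' @param ds training [genotype_dataset()] with phenotypes.
#' @param min_carriers minimum carriers and non-carriers (default 5).
#' @return A `hypothesis_score` list: `id`, `carriers`, `fit_score`,
#'   `direction` (+1 risk / -1 protective / 0), `degenerate`, `separated`.
#' @export
score_hypothesis <- function(h, ds, min_carriers = 5L) {
  y <- ds$samples$phenotype
  ok <- !is.na(y)
  ind <- encode_hypothesis(h, ds)[ok]
  y <- y[ok]
  carriers <- sum(ind)
  res <- list(id = hypothesis_id(h), carriers = carriers,
              fit_score = 0, direction = 0, degenerate = TRUE,
              separated = FALSE)
  if (carriers < min_carriers || (length(ind) - carriers) < min_carriers) {
    return(structure(res, class = "hypothesis_score"))
  }
  fit <- logistic_fit(cbind(ind), y)
  score <- max(0, fit$null_deviance - fit$deviance)
  carrier_rate <- mean(y[ind == 1])
  res$fit_score <- score
  res$direction <- unname(sign(fit$coef[2]))
  res$degenerate <- FALSE
  res$separated <- carrier_rate %in% c(0, 1)
  structure(res, class = "hypothesis_score")
}

#' Search configuration
#'
#' @param n_per_round hypotheses proposed per round (default 45).
#' @param max_order maximum conditions per hypothesis (default 4).
#' @param learning_rate multiplicative-weights step size eta (default 0.25).
#' @param patience convergence window P: stop when the moving average
#'   (window P) of per-round mean proposal scores has not strictly
#'   increased for P consecutive rounds (default 5).
#' @param max_rounds hard round cap (default 40).
#' @param max_selected hypotheses returned (default 99; must stay < 100).
#' @param min_carriers minimum carriers/non-carriers for a non-degenerate
#'   score (default 5).
#' @param rho probability that a co-member of a multi-variant proposal is
#'   drawn from the graph neighborhood (distance <= 2) of the variants
#'   already in the hypothesis, rather than from all variants
#'   (default 0.9).
#' @param refine_top_frac refinement budget per round, as a fraction of
#'   `n_per_round` (default 0.25).
#' @param refine_k neighbors scored per refined hypothesis (default 20).
#' @param order_probs sampling weights for the proposal order 1..
#'   `max_order` (default favors orders 1-2, where marginal signal seeds
#'   the refinement ladder).
#' @param seed integer RNG seed (mandatory for a reproducible search).
#' @return A `select_config` list.
#' @export
select_config <- function(n_per_round = 45L, max_order = 4L,
                          learning_rate = 0.25, patience = 6L,
                          max_rounds = 40L, max_selected = 99L,
                          min_carriers = 5L, rho = 0.9,
                          refine_top_frac = 0.25, refine_k = 20L,
                          order_probs = c(0.35, 0.4, 0.15, 0.1),
                          seed = 1L) {
  check_that(max_selected < 100, "max_selected must stay below 100")
  check_that(min_carriers >= 1, "min_carriers must be >= 1")
  check_that(max_order >= 1, "max_order must be >= 1")
  check_that(rho >= 0 && rho <= 1, "rho must be in [0, 1]")
  check_that(patience >= 1 && max_rounds >= 1, "positive round counts")
  order_probs <- rep_len(order_probs, max_order)
  order_probs <- order_probs / sum(order_probs)
  structure(
    list(n_per_round = as.integer(n_per_round),
         max_order = as.integer(max_order),
         learning_rate = learning_rate, patience = as.integer(patience),
         max_rounds = as.integer(max_rounds),
         max_selected = as.integer(max_selected),
         min_carriers = as.integer(min_carriers), rho = rho,
         refine_top_frac = refine_top_frac,
         refine_k = as.integer(refine_k), order_probs = order_probs,
         seed = as.integer(seed)),
    class = "select_config"
  )
}

# genotype conditions admissible per variant: observed >= min_carriers times
admissible_genotypes <- function(ds, min_carriers) {
  lapply(stats::setNames(seq_len(ncol(ds$genotypes)), ds$variants$vid),
         function(j) {
           tab <- tabulate(ds$genotypes[, j] + 1L, nbins = 3L)
           which(tab >= min_carriers) - 1L
         })
}

#' Initialize the search state
#'
#' @param ds training dataset.
#' @param graph a [prior_graph()] whose matched variant nodes are in `ds`.
#' @param config a [select_config()].
#' @return A `search_state` environment: graph propensities, archive of
#'   scored hypotheses, round index, score history.
#' @export
search_state <- function(ds, graph, config = select_config()) {
  vids <- graph$nodes$id[graph$nodes$kind == "variant" & graph$nodes$matched]
  vids <- intersect(vids, ds$variants$vid)
  check_that(length(vids) >= 1, "graph has no matched variant nodes")
  st <- new.env(parent = emptyenv())
  st$ds <- ds
  st$graph <- graph
  st$config <- config
  st$vids <- vids
  st$propensity <- stats::setNames(rep(1, length(vids)), vids)
  st$neighborhoods <- variant_neighborhoods(graph, order = 2)
  st$admissible <- admissible_genotypes(ds, config$min_carriers)
  st$archive <- new.env(parent = emptyenv())   # id -> hypothesis_score
  st$refined <- character()                    # ids already expanded
  st$round <- 0L
  st$round_means <- numeric()
  class(st) <- "search_state"
  st
}

# sample one new hypothesis; NULL if none found within `tries`
propose_one <- function(st, tries = 30L) {
  cfg <- st$config
  for (t in seq_len(tries)) {
    k <- sample.int(cfg$max_order, 1L, prob = cfg$order_probs)
    w <- st$propensity
    first <- sample(st$vids, 1L, prob = w)
    chosen <- first
    while (length(chosen) < k) {
      nb <- unique(unlist(st$neighborhoods[chosen], use.names = FALSE))
      nb <- setdiff(intersect(nb, st$vids), chosen)
      use_graph <- length(nb) > 0 && stats::runif(1) < cfg$rho
      pool <- if (use_graph) nb else setdiff(st$vids, chosen)
      if (!length(pool)) break
      chosen <- c(chosen, sample(pool, 1L, prob = st$propensity[pool]))
    }
    gts <- vapply(chosen, function(v) {
      adm <- st$admissible[[v]]
      if (!length(adm)) return(NA_integer_)
      if (length(adm) == 1L) adm else sample(adm, 1L)
    }, integer(1))
    if (anyNA(gts)) next
    h <- hypothesis(chosen, gts)
    if (!exists(hypothesis_id(h), envir = st$archive)) return(h)
  }
  NULL
}

#' Propose a batch of new hypotheses
#'
#' Variants are drawn proportionally to their current propensities; with
#' probability `rho`, co-members of a multi-variant hypothesis come from
#' the graph neighborhood (distance <= 2 through gene/pathway nodes) of
#' the variants already chosen. Genotype conditions are drawn uniformly
#' from the genotypes observed at least `min_carriers` times. Hypotheses
#' already in the archive are not re-proposed.
#'
#' @param st a [search_state()]. Uses the current global RNG stream (the
#'   driver [run_selection()] owns one stream for the whole search).
#' @param n batch size.
#' @return List of [hypothesis()] objects (shorter than `n`, with
#'   attribute `exhausted = TRUE`, if the unseen space ran out).
#' @export
propose <- function(st, n = st$config$n_per_round) {
  out <- list()
  batch_ids <- character()
  misses <- 0L
  while (length(out) < n && misses < 5L) {
    h <- propose_one(st)
    if (is.null(h)) { misses <- misses + 1L; next }
    id <- hypothesis_id(h)
    if (id %in% batch_ids) { misses <- misses + 1L; next }
    out <- c(out, list(h))
    batch_ids <- c(batch_ids, id)
  }
  if (length(out) < n) attr(out, "exhausted") <- TRUE
  out
}

#' Edit-distance-1 neighborhood of a hypothesis
#'
#' Neighbors differ by exactly one edit: (a) one condition's genotype
#' changed to another admissible genotype; (b) one variant swapped for a
#' graph-neighbor variant (distance <= 2) not already present, at each
#' admissible genotype; (c) one condition dropped (if order > 1); (d) one
#' condition added on a graph-neighbor variant at each admissible
#' genotype (if order < `max_order`).
#'
#' @param h a [hypothesis()].
#' @param st a [search_state()] (provides graph neighborhoods, admissible
#'   genotypes and order bounds).
#' @param k if finite, at most `k` neighbors sampled uniformly from the
#'   enumeration (default `Inf` = all neighbors).
#' @return List of [hypothesis()] objects (possibly empty).
#' @export
refine <- function(h, st, k = Inf) {
  cfg <- st$config
  out <- list()
  add <- function(vv, gg) {
    hh <- tryCatch(hypothesis(vv, gg), error = function(e) NULL)
    if (!is.null(hh)) out[[length(out) + 1L]] <<- hh
  }
  # (a) change one genotype
  for (i in seq_along(h$vids)) {
    for (g in setdiff(st$admissible[[h$vids[i]]], h$genotypes[i])) {
      gg <- h$genotypes; gg[i] <- g
      add(h$vids, gg)
    }
  }
  # (b) swap one variant for a graph neighbor
  for (i in seq_along(h$vids)) {
    nb <- setdiff(intersect(st$neighborhoods[[h$vids[i]]] %||% character(),
                            st$vids), h$vids)
    for (v in nb) {
      for (g in st$admissible[[v]]) {
        vv <- h$vids; vv[i] <- v
        gg <- h$genotypes; gg[i] <- g
        add(vv, gg)
      }
    }
  }
  # (c) drop one condition
  if (length(h$vids) > 1L) {
    for (i in seq_along(h$vids)) add(h$vids[-i], h$genotypes[-i])
  }
  # (d) add one condition from the neighborhood of the current variants
  if (length(h$vids) < cfg$max_order) {
    nb <- unique(unlist(st$neighborhoods[h$vids], use.names = FALSE))
    nb <- setdiff(intersect(nb, st$vids), h$vids)
    for (v in nb) {
      for (g in st$admissible[[v]]) add(c(h$vids, v), c(h$genotypes, g))
    }
  }
  ids <- vapply(out, hypothesis_id, character(1))
  out <- out[!duplicated(ids) & ids != hypothesis_id(h)]
  if (is.finite(k) && length(out) > k) {
    out <- out[sample.int(length(out), k)]
  }
  out
}

#' Multiplicative-weights propensity update
#'
#' Each variant node's propensity is multiplied by
#' `exp(eta * (mean score of batch hypotheses containing it - batch mean
#' score))` and the propensities are renormalized to sum to the variant
#' node count. Variants absent from the batch have zero advantage and are
#' only rescaled.
#'
#' @param st a [search_state()] (modified in place and returned).
#' @param scored list of `hypothesis_score`s for this round's batch.
#' @param eta learning rate (default from config).
#' @return The updated state, invisibly.
#' @export
update_propensities <- function(st, scored, eta = st$config$learning_rate) {
  check_that(length(scored) > 0, "empty batch")
  scores <- vapply(scored, `[[`, numeric(1), "fit_score")
  baseline <- mean(scores)
  sums <- counts <- stats::setNames(numeric(length(st$vids)), st$vids)
  for (i in seq_along(scored)) {
    h <- parse_hypothesis(scored[[i]]$id)
    vs <- intersect(h$vids, st$vids)
    sums[vs] <- sums[vs] + scores[i]
    counts[vs] <- counts[vs] + 1
  }
  seen <- counts > 0
  adv <- numeric(length(st$vids))
  adv[seen] <- sums[seen] / counts[seen] - baseline
  w <- st$propensity * exp(eta * adv)
  st$propensity <- w / sum(w) * length(w)
  invisible(st)
}

score_batch <- function(st, hyps) {
  lapply(hyps, function(h) {
    sc <- score_hypothesis(h, st$ds, st$config$min_carriers)
    assign(sc$id, sc, envir = st$archive)
    sc
  })
}

#' Run the graph-guided hypothesis search
#'
#' Each round proposes a batch of unseen hypotheses from the current
#' propensities, scores them, refines the best-scoring fraction by
#' enumerating and scoring edit-distance-1 neighbors, and applies the
#' multiplicative-weights propensity update to everything scored this
#' round. The search converges when the moving average (window =
#' `patience`) of per-round mean proposal scores has failed to strictly
#' increase for `patience` consecutive rounds, or at `max_rounds`. The
#' final feature set is the top `max_selected` (< 100) archived
#' hypotheses by fit score.
#'
#' @param ds_train training [genotype_dataset()] with phenotypes.
#' @param graph a [prior_graph()].
#' @param config a [select_config()]; `config$seed` drives the single RNG
#'   stream the whole search owns.
#' @return A `selected_features` data.frame (`id`, `conditions`, `order`,
#'   `carriers`, `fit_score`, `direction`) with attributes `converged`,
#'   `rounds`, `round_means`, `n_scored`, `state`.
#' @export
run_selection <- function(ds_train, graph, config = select_config()) {
  st <- search_state(ds_train, graph, config)
  with_seed(config$seed, {
    best_ma <- -Inf
    stall <- 0L
    converged <- FALSE
    while (st$round < config$max_rounds) {
      st$round <- st$round + 1L
      props <- propose(st, config$n_per_round)
      if (!length(props)) { converged <- TRUE; break }
      scored <- score_batch(st, props)
      st$round_means <- c(st$round_means,
                          mean(vapply(scored, `[[`, numeric(1), "fit_score")))
      # refine the best archived hypotheses not yet expanded, so strong
      # hypotheses found by earlier refinements keep being fine-tuned
      arch <- as.list(st$archive)
      cand <- Filter(function(s) !s$degenerate && s$fit_score > 0 &&
                       !(s$id %in% st$refined), arch)
      cand <- cand[order(-vapply(cand, `[[`, numeric(1), "fit_score"),
                         vapply(cand, `[[`, character(1), "id"))]
      n_ref <- ceiling(config$refine_top_frac * config$n_per_round)
      refined_scored <- list()
      for (s in utils::head(cand, n_ref)) {
        st$refined <- c(st$refined, s$id)
        nbrs <- refine(parse_hypothesis(s$id), st, k = config$refine_k)
        nbrs <- Filter(function(h) !exists(hypothesis_id(h),
                                           envir = st$archive), nbrs)
        refined_scored <- c(refined_scored, score_batch(st, nbrs))
      }
      update_propensities(st, c(scored, refined_scored))
      # convergence on the moving average of new-proposal scores
      if (st$round >= config$patience) {
        ma <- mean(utils::tail(st$round_means, config$patience))
        if (ma > best_ma + 1e-12) {
          best_ma <- ma
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
        if (stall >= config$patience) { converged <- TRUE; break }
      }
    }
    all_scores <- as.list(st$archive)
    df <- data.frame(
      id = vapply(all_scores, `[[`, character(1), "id"),
      carriers = vapply(all_scores, `[[`, numeric(1), "carriers"),
      fit_score = vapply(all_scores, `[[`, numeric(1), "fit_score"),
      direction = vapply(all_scores, `[[`, numeric(1), "direction"),
      degenerate = vapply(all_scores, `[[`, logical(1), "degenerate"),
      stringsAsFactors = FALSE
    )
    df <- df[order(-df$fit_score, df$id), , drop = FALSE]
    df <- utils::head(df, config$max_selected)
    df$order <- lengths(strsplit(df$id, ";", fixed = TRUE))
    df$conditions <- df$id
    rownames(df) <- NULL
    structure(
      df[, c("id", "conditions", "order", "carriers", "fit_score",
             "direction", "degenerate")],
      class = c("selected_features", "data.frame"),
      converged = converged, rounds = st$round,
      round_means = st$round_means,
      n_scored = length(all_scores), state = st
    )
  })
}

#' Write a selected-feature set as TSV
#'
#' @param selected a `selected_features` data.frame.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_selected <- function(selected, path) {
  utils::write.table(as.data.frame(selected), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
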