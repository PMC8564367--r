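# Synthetic case/control genotype data with block LD, additive +
# epistatic phenotype architecture, and a partially informative prior
# graph with a ground-truth record. Stands in for restricted cohort data
# in tests and calibration studies.

#' Simulation configuration
#'
#' @param n_samples samples to simulate (default 436, a two-chip cohort
#'   after QC).
#' @param n_variants biallelic autosomal variants (default 120).
#' @param maf_range alt-allele frequency range, each variant uniform
#'   within it (default c(0.05, 0.5)).
#' @param ld_block_size variants per LD block (default 10).
#' @param rho_ld latent haplotype correlation within a block (default 0.8;
#'   0 = independent variants).
#' @param baseline_logit intercept of the liability logit (default
#'   `qlogis(296/436)`, a two-thirds-case cohort).
#' @param additive data.frame (`vid`, `beta`) of additive log-odds
#'   effects, or NULL.
#' @param interactions list of
#'   `list(vids =, genotypes =, beta = | penetrance =)` planted
#'   genotype-combination effects; if `penetrance` is given, beta is set
#'   by logit inversion so carriers reach that case probability.
#' @param missing_rate per-call missingness (default 0.01).
#' @param graph_coverage fraction of planted interactions whose variants
#'   the prior graph links (default 1).
#' @param graph_noise_edges random variant-gene edges among non-causal
#'   variants (default 30).
#' @param seed mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 436L, n_variants = 120L,
                       maf_range = c(0.05, 0.5), ld_block_size = 10L,
                       rho_ld = 0.8,
                       baseline_logit = stats::qlogis(296 / 436),
                       additive = NULL, interactions = list(),
                       missing_rate = 0.01, graph_coverage = 1,
                       graph_noise_edges = 30L, seed = 1L) {
  check_that(!missing(seed) || !is.null(seed), "seed is mandatory")
  check_that(all(maf_range > 0) && all(maf_range <= 0.5),
             "maf_range must lie in (0, 0.5]")
  check_that(rho_ld >= 0 && rho_ld < 1, "rho_ld must be in [0, 1)")
  check_that(missing_rate >= 0 && missing_rate < 1,
             "missing_rate must be in [0, 1)")
  check_that(graph_coverage >= 0 && graph_coverage <= 1,
             "graph_coverage must be in [0, 1]")
  structure(
    list(n_samples = as.integer(n_samples),
         n_variants = as.integer(n_variants), maf_range = maf_range,
         ld_block_size = as.integer(ld_block_size), rho_ld = rho_ld,
         baseline_logit = baseline_logit, additive = additive,
         interactions = interactions, missing_rate = missing_rate,
         graph_coverage = graph_coverage,
         graph_noise_edges = as.integer(graph_noise_edges),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate genotypes with block LD
#'
#' Latent-Gaussian threshold model: within each block of
#' `ld_block_size` variants, the two haplotype latents of every sample
#' share an exchangeable correlation `rho_ld` across variants; each
#' haplotype latent is thresholded at `qnorm(maf)` to an allele, and the
#' two alleles sum to the dosage. This yields Hardy-Weinberg marginals at
#' each variant's MAF and tunable within-block r^2, independent across
#' blocks. Missingness is Bernoulli(`missing_rate`) per call.
#'
#' Variants are laid out on chromosomes 1..22 (blocks round-robin across
#' chromosomes, 100 kb between adjacent variants).
#'
#' @param config a [sim_config()].
#' @return A [genotype_dataset()] with phenotypes `NA` (see
#'   [simulate_phenotype()]).
#' @export
simulate_genotypes <- function(config) {
  with_seed(config$seed, {
    n <- config$n_samples
    m <- config$n_variants
    rho <- config$rho_ld
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    blocks <- split(seq_len(m),
                    ceiling(seq_len(m) / config$ld_block_size))
    geno <- matrix(0L, nrow = n, ncol = m)
    for (bl in blocks) {
      for (hap in 1:2) {
        shared <- stats::rnorm(n)
        z <- sqrt(rho) * matrix(shared, n, length(bl)) +
          sqrt(1 - rho) * matrix(stats::rnorm(n * length(bl)), n)
        allele <- sweep(z, 2, stats::qnorm(maf[bl]), `<`)
        geno[, bl] <- geno[, bl] + allele
      }
    }
    if (config$missing_rate > 0) {
      geno[matrix(stats::runif(n * m) < config$missing_rate, n, m)] <-
        NA_integer_
    }
    chrom <- rep(rep(1:22, length.out = length(blocks)),
                 times = lengths(blocks))
    pos <- integer(m)
    for (c22 in unique(chrom)) {
      pos[chrom == c22] <- seq_len(sum(chrom == c22)) * 100000L
    }
    genotype_dataset(
      geno,
      data.frame(chrom = as.character(chrom), pos = pos,
                 vid = sprintf("snp%04d", seq_len(m)),
                 ref = "A", alt = "B", stringsAsFactors = FALSE),
      data.frame(sid = sprintf("S%04d", seq_len(n)),
                 phenotype = NA_integer_, stringsAsFactors = FALSE)
    )
  })
}

# Interaction effect size. A `beta` is taken as given; a `penetrance`
# target is inverted through the logistic link against the carriers'
# background risk (their mean linear predictor before the interaction),
# so the realized carrier case rate lands on the target.
interaction_beta <- function(inter, baseline_logit, eta_carriers = NULL) {
  if (!is.null(inter$beta)) return(inter$beta)
  check_that(!is.null(inter$penetrance),
             "interaction needs `beta` or `penetrance`")
  background <- if (is.null(eta_carriers) || !length(eta_carriers)) {
    baseline_logit
  } else {
    stats::qlogis(mean(stats::plogis(eta_carriers)))
  }
  stats::qlogis(inter$penetrance) - background
}

#' Simulate a binary phenotype with additive and epistatic effects
#'
#' `logit(p_i) = baseline + sum additive beta * dosage + sum interaction
#' beta * [all conditions met]`; labels are Bernoulli(p_i). Missing
#' dosages contribute their expected value (2 x MAF) to the additive
#' term; interaction indicators treat missing as non-carrier.
#'
#' @param ds a [genotype_dataset()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return List: `dataset` (with phenotypes filled) and `truth`, a
#'   `sim_truth` list recording causal additive variants, planted
#'   interactions (with realized carrier penetrance) and the graph-linked
#'   subset (filled by [simulate_prior_graph()]).
#' @export
simulate_phenotype <- function(ds, config) {
  with_seed(config$seed + 1L, {
    n <- nrow(ds$genotypes)
    eta <- rep(config$baseline_logit, n)
    if (!is.null(config$additive) && nrow(config$additive) > 0) {
      for (i in seq_len(nrow(config$additive))) {
        v <- config$additive$vid[i]
        check_that(v %in% ds$variants$vid, paste("unknown additive vid:", v))
        g <- ds$genotypes[, v]
        g[is.na(g)] <- 2 * mean(g, na.rm = TRUE) / 2
        eta <- eta + config$additive$beta[i] * g
      }
    }
    indicators <- lapply(config$interactions, function(inter) {
      h <- hypothesis(inter$vids, inter$genotypes)
      encode_hypothesis(h, ds)
    })
    betas <- numeric(length(config$interactions))
    for (k in seq_along(config$interactions)) {
      betas[k] <- interaction_beta(config$interactions[[k]],
                                   config$baseline_logit,
                                   eta[indicators[[k]] == 1])
      eta <- eta + betas[k] * indicators[[k]]
    }
    y <- stats::rbinom(n, 1L, stats::plogis(eta))
    ds$samples$phenotype <- y
    realized <- vapply(seq_along(indicators), function(k) {
      idx <- indicators[[k]] == 1
      if (!any(idx)) NA_real_ else mean(y[idx])
    }, numeric(1))
    truth <- structure(
      list(
        additive_vids = if (is.null(config$additive)) character()
                        else config$additive$vid,
        interactions = lapply(seq_along(config$interactions), function(k) {
          inter <- config$interactions[[k]]
          list(id = hypothesis_id(hypothesis(inter$vids, inter$genotypes)),
               vids = sort(inter$vids),
               beta = betas[k],
               carriers = sum(indicators[[k]]),
               realized_penetrance = realized[k])
        }),
        graph_linked = character()
      ),
      class = "sim_truth"
    )
    list(dataset = ds, truth = truth)
  })
}

#' Simulate a partially informative prior graph
#'
#' Every dataset variant becomes a (matched) variant node. For a fraction
#' `graph_coverage` of the planted interactions, the interaction's
#' variants are connected through a shared synthetic gene node
#' (provenance tag `sim_causal`). `graph_noise_edges` additional edges
#' connect random non-causal variants to synthetic noise gene nodes
#' (tag `sim_noise`), so total edge count is the covered interactions'
#' condition counts plus the configured noise count.
#'
#' @param truth a `sim_truth` from [simulate_phenotype()].
#' @param config the [sim_config()].
#' @param ds the simulated [genotype_dataset()].
#' @return A [prior_graph()]; `truth$graph_linked` is mirrored in the
#'   attribute `linked_interactions`.
#' @export
simulate_prior_graph <- function(truth, config, ds) {
  with_seed(config$seed + 2L, {
    vids <- ds$variants$vid
    n_int <- length(truth$interactions)
    n_link <- round(config$graph_coverage * n_int)
    linked <- if (n_int > 0 && n_link > 0) {
      sort(sample.int(n_int, n_link))
    } else {
      integer()
    }
    edges <- list()
    gene_nodes <- character()
    for (k in linked) {
      gene <- sprintf("gene_causal_%02d", k)
      gene_nodes <- c(gene_nodes, gene)
      for (v in truth$interactions[[k]]$vids) {
        edges[[length(edges) + 1L]] <-
          data.frame(from = v, to = gene, weight = 1, source = "sim_causal",
                     stringsAsFactors = FALSE)
      }
    }
    causal_vids <- unique(unlist(lapply(truth$interactions, `[[`, "vids")))
    noise_pool <- setdiff(vids, causal_vids)
    n_noise_genes <- max(1L, ceiling(config$graph_noise_edges / 4))
    noise_genes <- sprintf("gene_noise_%03d", seq_len(n_noise_genes))
    if (config$graph_noise_edges > 0 && length(noise_pool) > 0) {
      for (e in seq_len(config$graph_noise_edges)) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = sample(noise_pool, 1L),
          to = noise_genes[((e - 1L) %% n_noise_genes) + 1L],
          weight = 1, source = "sim_noise", stringsAsFactors = FALSE
        )
      }
      gene_nodes <- c(gene_nodes, noise_genes)
    }
    edges <- if (length(edges)) unique(do.call(rbind, edges))
             else data.frame(from = character(), to = character(),
                             weight = numeric(), source = character())
    nodes <- rbind(
      data.frame(id = vids, kind = "variant", matched = TRUE,
                 stringsAsFactors = FALSE),
      if (length(gene_nodes)) {
        data.frame(id = unique(gene_nodes), kind = "gene", matched = TRUE,
                   stringsAsFactors = FALSE)
      }
    )
    g <- prior_graph(nodes, edges)
    attr(g, "linked_interactions") <-
      vapply(truth$interactions[linked], `[[`, character(1), "id")
    g
  })
}

#' Generate a full simulated study (genotypes, phenotype, graph, truth)
#'
#' @param config a [sim_config()].
#' @return List: `dataset`, `graph`, `truth` (with `graph_linked` filled).
#' @export
simulate_study <- function(config) {
  ds <- simulate_genotypes(config)
  ph <- simulate_phenotype(ds, config)
  graph <- simulate_prior_graph(ph$truth, config, ph$dataset)
  truth <- ph$truth
  truth$graph_linked <- attr(graph, "linked_interactions")
  list(dataset = ph$dataset, graph = graph, truth = truth)
}

#' Preset simulation configurations
#'
#' * `"null"`: no genetic effects; phenotype is pure Bernoulli noise at
#'   the cohort case fraction, graph is noise-only.
#' * `"additive_only"`: eight additive variants (log-OR 0.35), no
#'   planted interactions.
#' * `"epistatic_ppmi_like"`: 436 samples, one planted two-variant
#'   heterozygote-pair interaction with target carrier penetrance 0.87
#'   (echoing the strongest observed genotype-combination stratum of a
#'   436-sample cohort), plus four weak additive variants; graph links
#'   the interaction's variants by default.
#'
#' @param preset one of `"null"`, `"additive_only"`,
#'   `"epistatic_ppmi_like"`.
#' @param seed integer seed.
#' @param graph_coverage fraction of planted interactions linked in the
#'   graph (default 1; use 0 for an uninformative graph).
#' @return A [sim_config()].
#' @export
preset_config <- function(preset = c("null", "additive_only",
                                     "epistatic_ppmi_like"),
                          seed = 1L, graph_coverage = 1) {
  preset <- match.arg(preset)
  base <- list(n_samples = 436L, n_variants = 120L, ld_block_size = 10L,
               rho_ld = 0.4, missing_rate = 0.01, seed = seed,
               graph_coverage = graph_coverage, graph_noise_edges = 30L)
  # baseline logits offset the mean additive/epistatic shift so every
  # preset's cohort case fraction sits near the 296/436 target
  extra <- switch(
    preset,
    null = list(),
    additive_only = list(
      additive = data.frame(vid = sprintf("snp%04d", c(5, 18, 31, 44, 57,
                                                       70, 83, 96)),
                            beta = 0.5, stringsAsFactors = FALSE),
      maf_range = c(0.2, 0.5),
      baseline_logit = stats::qlogis(296 / 436) - 8 * 0.5 * 0.7
    ),
    epistatic_ppmi_like = list(
      # purely epistatic architecture: the additive baseline has nothing
      # to find (as when a PRS barely beats chance), while het/het
      # carriers of two variants in different LD blocks (~1/5 of the
      # cohort at these MAFs) reach a high case probability, echoing the
      # strongest genotype-combination strata of a 436-sample
      # case/control cohort
      interactions = list(list(vids = c("snp0015", "snp0085"),
                               genotypes = c(1L, 1L),
                               penetrance = 0.95)),
      maf_range = c(0.3, 0.5),
      baseline_logit = stats::qlogis(296 / 436) - 0.45
    )
  )
  do.call(sim_config, utils::modifyList(base, extra))
}

#' Write a ready-to-run fixture to disk
#'
#' Simulates a preset study and writes PLINK bed/bim/fam, the prior-graph
#' TSV, and a truth JSON (causal sets, realized penetrances, split sample
#' ids at sizes 367/33/36).
#'
#' @param preset preset name (see [preset_config()]).
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param graph_coverage passed to [preset_config()].
#' @return Invisibly, the named list of written file paths.
#' @export
end_to_end_fixture <- function(preset, dir, seed = 1L, graph_coverage = 1) {
  cfg <- preset_config(preset, seed = seed, graph_coverage = graph_coverage)
  sim <- simulate_study(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, preset)
  write_plink(sim$dataset, prefix)
  graph_path <- paste0(prefix, "_graph.tsv")
  write_prior_graph(sim$graph, graph_path)
  splits <- make_split(sim$dataset, c(train = 367, valid = 33, test = 36),
                       seed = seed)
  truth_path <- paste0(prefix, "_truth.json")
  jsonlite::write_json(
    list(
      preset = preset, seed = seed,
      additive_vids = sim$truth$additive_vids,
      interactions = sim$truth$interactions,
      graph_linked = sim$truth$graph_linked,
      split = lapply(splits, function(s) s$samples$sid)
    ),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(list(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
                 fam = paste0(prefix, ".fam"), graph = graph_path,
                 truth = truth_path))
}
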