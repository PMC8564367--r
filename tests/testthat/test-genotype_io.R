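# Reading, writing and merging genotype data and the prior-graph edge list.

test_that("PLINK round-trip preserves genotypes, metadata and phenotypes", {
  # tiny hand-written fixture, including one missing call
  g <- matrix(c(0L, 1L, 2L,
                2L, NA, 0L), nrow = 3)
  ds <- tiny_dataset(g, phenotype = c(1L, 0L, NA))
  prefix <- file.path(withr::local_tempdir(), "tiny")
  write_plink(ds, prefix)
  back <- read_plink(paste0(prefix, ".bed"))
  expect_identical(unname(back$genotypes), unname(ds$genotypes))
  expect_identical(sum(is.na(back$genotypes)), 1L)
  expect_true(is.na(back$genotypes[2, 2]))
  expect_identical(back$samples$phenotype, ds$samples$phenotype)
  expect_identical(back$variants$vid, ds$variants$vid)
  expect_identical(back$variants$alt, ds$variants$alt)

  # larger simulated dataset: bitwise-equal genotypes after round-trip
  big <- random_dataset(n = 100, m = 500, seed = 42, missing_rate = 0.05)
  prefix2 <- file.path(withr::local_tempdir(), "big")
  write_plink(big, prefix2)
  back2 <- read_plink(paste0(prefix2, ".bed"))
  expect_identical(back2$genotypes, big$genotypes)
})

test_that("malformed bed files raise format errors naming the file", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "bad.bed")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0xff)), bad)
  writeLines("1\tv1\t0\t100\tG\tA", file.path(d, "bad.bim"))
  writeLines("s1\ts1\t0\t0\t0\t1", file.path(d, "bad.fam"))
  expect_error(read_plink(bad), "bad.bed")

  # truncated payload: 2 variants declared, bytes for 1
  ds <- tiny_dataset(matrix(c(0L, 1L, 2L, 0L, 1L, 2L), nrow = 3))
  prefix <- file.path(d, "trunc")
  write_plink(ds, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 100)
  writeBin(raw[1:4], paste0(prefix, ".bed"))
  expect_error(read_plink(paste0(prefix, ".bed")), "inconsistent")
})

test_that("VCF genotype codes map to dosages and round-trip", {
  ds <- tiny_dataset(matrix(c(0L, 1L, 2L, NA), nrow = 4),
                     phenotype = c(1L, 1L, 0L, 0L))
  path <- file.path(withr::local_tempdir(), "x.vcf")
  write_vcf(ds, path)
  back <- read_vcf(path)
  expect_identical(unname(back$genotypes), unname(ds$genotypes))
  expect_identical(back$variants$ref, ds$variants$ref)

  # simulated dataset exported and read back
  big <- random_dataset(n = 40, m = 25, seed = 7, missing_rate = 0.03)
  path2 <- file.path(withr::local_tempdir(), "big.vcf")
  write_vcf(big, path2)
  expect_identical(read_vcf(path2)$genotypes, big$genotypes)
})

test_that("multiallelic VCF records are skipped or rejected per option", {
  d <- withr::local_tempdir()
  path <- file.path(d, "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1",
    "1\t200\tv2\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/0"
  ), path)
  expect_warning(ds <- read_vcf(path), "multiallelic")
  expect_identical(ncol(ds$genotypes), 1L)
  expect_identical(unname(ds$genotypes[, 1]), c(1L, 2L))
  expect_error(read_vcf(path, multiallelic = "error"), "multiallelic")
})

test_that("merging disjoint variant sets unions variants", {
  a <- tiny_dataset(matrix(c(0L, 1L, 2L, 0L), nrow = 2),
                    phenotype = c(1L, 0L), pos = c(100L, 200L))
  b <- tiny_dataset(matrix(c(1L, 1L), nrow = 2),
                    phenotype = c(1L, 0L), pos = 300L)
  b$variants$vid <- "w001"
  m <- merge_datasets(a, b)
  expect_identical(ncol(m$genotypes), 3L)
  expect_identical(attr(m, "n_dropped_alleles"), 0L)
})

test_that("allele-flipped duplicate variants reconcile by flipping dosage", {
  a <- tiny_dataset(matrix(c(0L, 1L, 2L), nrow = 3),
                    phenotype = c(1L, 0L, 1L), pos = 500L)
  b <- a
  b$variants$ref <- "G"; b$variants$alt <- "A"    # swapped alleles
  b$genotypes[] <- 2L - a$genotypes               # same underlying calls
  m <- merge_datasets(a, b)
  expect_identical(ncol(m$genotypes), 1L)
  expect_identical(unname(m$genotypes[, 1]), c(0L, 1L, 2L))
  expect_identical(attr(m, "n_call_conflicts"), 0L)

  # dosage 2 in b with swapped alleles means dosage 0 on a's coding
  b2 <- tiny_dataset(matrix(2L), phenotype = 1L, pos = 500L)
  b2$variants$ref <- "G"; b2$variants$alt <- "A"
  a2 <- tiny_dataset(matrix(NA_integer_), phenotype = 1L, pos = 500L)
  m2 <- merge_datasets(a2, b2)
  expect_identical(unname(m2$genotypes[1, 1]), 0L)
})

test_that("merge handles conflicts, bad alleles and phenotype mismatches", {
  a <- tiny_dataset(matrix(c(0L, 1L), nrow = 2), phenotype = c(1L, 0L),
                    pos = 100L)
  conflict <- a
  conflict$genotypes[1, 1] <- 2L
  m <- merge_datasets(a, conflict)
  expect_true(is.na(m$genotypes[1, 1]))
  expect_identical(attr(m, "n_call_conflicts"), 1L)

  irre <- a
  irre$variants$ref <- "C"; irre$variants$alt <- "T"
  b <- tiny_dataset(matrix(c(0L, 1L), nrow = 2), phenotype = c(1L, 0L),
                    pos = 200L)
  b$variants$vid <- "w001"
  m2 <- merge_datasets(merge_datasets(a, b), irre)
  expect_identical(attr(m2, "n_dropped_alleles"), 1L)

  bad <- a
  bad$samples$phenotype <- c(0L, 0L)
  expect_error(merge_datasets(a, bad), "phenotype")
})

test_that("a random two-chip split merges back to the original dataset", {
  ds <- random_dataset(n = 30, m = 40, seed = 11, phenotype = TRUE)
  idx <- withr::with_seed(3, sample(c(TRUE, FALSE), 40, replace = TRUE))
  overlap <- withr::with_seed(4, sample(40, 10))
  chip1 <- subset_dataset(ds, variants = sort(unique(c(which(idx), overlap))))
  chip2 <- subset_dataset(ds, variants = sort(unique(c(which(!idx), overlap))))
  m <- merge_datasets(chip1, chip2)
  expect_identical(dim(m$genotypes), dim(ds$genotypes))
  expect_identical(m$genotypes[, ds$variants$vid], ds$genotypes)
  # symmetry up to ordering
  m2 <- merge_datasets(chip2, chip1)
  expect_identical(m2$genotypes[, colnames(m$genotypes)], m$genotypes)
})

test_that("prior-graph edge lists read, validate and round-trip", {
  d <- withr::local_tempdir()
  empty <- file.path(d, "empty.tsv")
  writeLines("node_a\tnode_b\tkind_a\tkind_b\tweight\tsource", empty)
  g0 <- read_prior_graph(empty)
  expect_identical(nrow(g0$edges), 0L)

  path <- file.path(d, "g.tsv")
  writeLines(c(
    "node_a\tnode_b\tkind_a\tkind_b\tweight\tsource",
    "v001\tGENE1\tvariant\tgene\t1\tlit",
    "v002\tGENE1\tvariant\tgene\t0.5\tlit",
    "v999\tGENE1\tvariant\tgene\t1\tlit"
  ), path)
  ds <- random_dataset(n = 10, m = 5, seed = 2)
  g <- read_prior_graph(path, ds)
  expect_identical(nrow(g$edges), 3L)
  # two variants linked through one gene: distance 2
  expect_equal(variant_distance(g, "v001", "v002"), 2)
  # unmatched variant node flagged, not dropped
  expect_false(g$nodes$matched[g$nodes$id == "v999"])
  expect_true(all(g$propensity > 0))

  neg <- file.path(d, "neg.tsv")
  writeLines(c("node_a\tnode_b\tkind_a\tkind_b\tweight\tsource",
               "v001\tGENE1\tvariant\tgene\t-1\tlit"), neg)
  expect_error(read_prior_graph(neg), "negative")

  # simulator-emitted graph round-trips with equal node/edge counts
  sim <- simulate_study(preset_config("epistatic_ppmi_like", seed = 5))
  gp <- file.path(d, "sim_graph.tsv")
  write_prior_graph(sim$graph, gp)
  g2 <- read_prior_graph(gp, sim$dataset)
  expect_identical(nrow(g2$edges), nrow(sim$graph$edges))
  # isolated variant nodes are not present in an edge list; all connected
  # nodes must round-trip
  connected <- unique(c(sim$graph$edges$from, sim$graph$edges$to))
  expect_setequal(g2$nodes$id, connected)
})
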