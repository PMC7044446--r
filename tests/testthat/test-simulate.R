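test_that("simulate_methylome is deterministic and truth-consistent", {
  cfg <- sim_config(seed = 3, n_cpgs = 400L, chrom_length = 1e5,
                    planted_dmrs = list(n = 3L, delta = 0.3,
                                        n_cpgs = c(7L, 10L),
                                        spacing = c(50L, 150L),
                                        treated = "TPA", direction = "both"),
                    planted_dmps = list(n = 5L, delta = 0.2,
                                        treated = "TPA"))
  a <- simulate_methylome(cfg)
  b <- simulate_methylome(cfg)
  expect_identical(lapply(a$tables, `[[`, "data"),
                   lapply(b$tables, `[[`, "data"))
  expect_identical(a$truth$rates, b$truth$rates)
  expect_length(a$tables, 9L)     # 3 conditions x 3 technical replicates

  # truth consistency: every planted block CpG carries the configured shift
  tr <- a$truth
  for (i in seq_len(nrow(tr$dmrs))) {
    blk <- tr$dmrs[i]
    inb <- tr$rates[chrom == blk$chrom & pos >= blk$start & pos < blk$end]
    expect_equal(nrow(inb), blk$n_cpgs)
    expect_equal(inb$true_TPA - inb$true_UN, rep(blk$delta, nrow(inb)))
    expect_true(all(inb$true_UN == inb$true_RA))
  }
  # background CpGs share rates across conditions
  bg <- tr$rates[chrom != "chrM"]
  bg <- bg[!tr$dmrs, on = .(chrom, pos >= start, pos < end)]
  bg <- bg[!tr$dmps, on = .(chrom, pos)]
  expect_true(all(bg$true_UN == bg$true_TPA))
  # chrM carries the configured non-conversion rate
  expect_true(all(tr$rates[chrom == "chrM"]$true_UN == cfg$nonconversion))
  # tables are valid: sorted, unique, meth <= cov
  for (t in a$tables) {
    expect_true(all(t$data$meth_calls <= t$data$coverage))
    expect_false(anyDuplicated(t$data, by = c("chrom", "pos")) > 0)
  }
})

test_that("beta-binomial mode inflates replicate variance", {
  base <- sim_config(seed = 61, n_cpgs = 3000L, n_chrm_cpgs = 0L,
                     n_replicates = 2L)
  over <- base
  over$rate_overdispersion <- 0.2
  var_of <- function(cfg) {
    sim <- simulate_methylome(cfg)
    r1 <- cpg_rates(sim$tables[["UN_rep1"]])
    r2 <- cpg_rates(sim$tables[["UN_rep2"]])
    stats::var(r1 - r2, na.rm = TRUE)
  }
  expect_gt(var_of(over), 2 * var_of(base))
})

test_that("background rates follow the bimodal mixture", {
  cfg <- sim_config(seed = 19, n_cpgs = 50000L, chrom_length = 5e6,
                    n_chrm_cpgs = 0L)
  sim <- simulate_methylome(cfg)
  r <- sim$truth$rates$true_UN
  ks <- suppressWarnings(
    stats::ks.test(r, function(q) background_mixture_cdf(q)))
  expect_gt(ks$p.value, 0.01)
  # mode weights show up in the rate bands the mixture targets
  expect_gt(mean(r > 0.75), 0.55)    # dominated by the high mode
  expect_gt(mean(r < 0.25), 0.15)    # small low fraction
  expect_lt(mean(r >= 0.25 & r <= 0.75), 0.25)
})

test_that("null methylome yields a conservative DMP fraction", {
  cfg <- sim_config(seed = 23, n_cpgs = 3000L, n_chrm_cpgs = 0L)
  sim <- simulate_methylome(cfg)
  filt <- filter_by_coverage(sim$tables)
  d <- fisher_dmp(pool_condition_counts(filt, "UN"),
                  pool_condition_counts(filt, "TPA"))
  expect_lte(nrow(d) / attr(d, "n_tested"), 0.05)
})

test_that("a planted 0 -> 0.2 DMP at deep coverage is detected", {
  set.seed(29)
  hits <- 0L
  n_mc <- 20L
  for (i in seq_len(n_mc)) {
    cov <- 100L
    meth_a <- rbinom(1, cov, 0.001)
    meth_b <- rbinom(1, cov, 0.2)
    p <- fisher_exact_2x2(meth_a, cov - meth_a, meth_b, cov - meth_b)
    hits <- hits + (p <= 0.05)
  }
  expect_gte(hits / n_mc, 0.8)
})

test_that("simulate_features couples enhancer placement to planted blocks", {
  cfg0 <- sim_config(seed = 5, n_cpgs = 1500L,
                     planted_dmrs = list(n = 10L, delta = 0.3,
                                         n_cpgs = c(7L, 12L),
                                         spacing = c(50L, 150L),
                                         treated = "TPA",
                                         direction = "both"))
  sim <- simulate_methylome(cfg0)

  # factor 1: placement ignores the blocks (null); intervals BED-valid
  f1 <- simulate_features(cfg0, sim$truth)
  expect_true(all(GenomicRanges::start(f1) >= 1))
  expect_true(all(GenomicRanges::end(f1) <= cfg0$chrom_length))
  expect_true(all(GenomicRanges::width(f1) > 0))

  # factor 10: enhancer enrichment over planted DMPs beats the neutral class
  cfg10 <- cfg0
  cfg10$features$enrichment_factor <- 10
  f10 <- simulate_features(cfg10, sim$truth)
  blk_cpgs <- sim$truth$rates[sim$truth$dmrs,
                              on = .(chrom, pos >= start, pos < end),
                              .(chrom, pos = x.pos), nomatch = NULL]
  n <- nrow(blk_cpgs)
  enh <- f10[S4Vectors::mcols(f10)$feature == "enhancer"]
  neu <- f10[S4Vectors::mcols(f10)$feature == "neutral"]
  r_enh <- dmp_feature_enrichment(blk_cpgs, n, enh, cfg0$chrom_length)$ratio
  r_neu <- dmp_feature_enrichment(blk_cpgs, n, neu, cfg0$chrom_length)$ratio
  expect_gt(r_enh, r_neu)
})

test_that("simulate_expression plants sign-correct couplings", {
  cfg <- sim_config(seed = 37, n_cpgs = 1500L,
                    planted_dmrs = list(n = 12L, delta = 0.3,
                                        n_cpgs = c(7L, 12L),
                                        spacing = c(50L, 150L),
                                        treated = "TPA", direction = "both"),
                    genes = list(n = 30L, n_coupled = 12L,
                                 coupling_noise_sd = 0, expr_base = 40,
                                 expr_scale = 150, expr_noise_sd = 0))
  sim <- simulate_methylome(cfg)
  se <- simulate_expression(cfg, sim$truth)
  expect_true(all(as.matrix(se$expression[, -1]) >= 0))
  conds <- cfg$conditions
  for (i in seq_len(nrow(se$couplings))) {
    cp <- se$couplings[i]
    meth <- as.numeric(cp[, paste0("meth_", conds), with = FALSE])
    expr <- as.numeric(se$expression[cp$gene_id, conds, with = FALSE])
    r <- correlate_meth_expr(meth, expr)
    # zero noise: construction gives exactly +/-1
    expect_equal(r, cp$sign, tolerance = 1e-9)
  }
  # null genes: |log2FC| concentrated at 0
  null_expr <- se$expression[grepl("^geneN", gene_id)]
  lfc <- log2_fold_change(null_expr$UN, null_expr$TPA)
  expect_true(all(abs(lfc) < 1e-9))
})

test_that("simulate_occupancy digs dips at hypomethylated planted CpGs", {
  cfg <- sim_config(seed = 41, n_cpgs = 800L, chrom_length = 2e5,
                    planted_dmrs = list(n = 4L, delta = 0.3,
                                        n_cpgs = c(7L, 8L),
                                        spacing = c(50L, 150L),
                                        treated = "TPA", direction = "both"))
  sim <- simulate_methylome(cfg)
  occ <- simulate_occupancy(cfg, sim$truth)
  # non-dip condition: flat 1.0 everywhere
  anchors <- sim$truth$rates[sim$truth$dmrs[direction == "hypo"],
                             on = .(chrom, pos >= start, pos < end),
                             .(chrom, pos = x.pos), nomatch = NULL]
  p_un <- occupancy_profile(occ$UN, anchors, flank = 200L)
  expect_equal(p_un$mean, rep(1, 401))
  # dip condition: configured depth at offset 0
  p_tpa <- occupancy_profile(occ$TPA, anchors, flank = 200L)
  expect_equal(p_tpa$mean[p_tpa$offset == 0], 1 - cfg$occupancy$dip_depth,
               tolerance = 0.05)
  expect_gt(mean(p_tpa$mean[abs(p_tpa$offset) > 150]),
            p_tpa$mean[p_tpa$offset == 0])
  # tracks tile without overlap
  for (tr in occ) {
    by_chr <- split(tr, tr$chrom)
    for (x in by_chr) expect_true(all(x$start[-1] >= head(x$end, -1)))
  }
})

test_that("write_simulation emits consumable dialects", {
  cfg <- sim_config(seed = 43, n_cpgs = 300L, chrom_length = 1e5,
                    planted_dmrs = list(n = 2L, delta = 0.3,
                                        n_cpgs = c(7L, 8L),
                                        spacing = c(50L, 150L),
                                        treated = "TPA", direction = "both"))
  dir <- withr::local_tempdir()
  man <- write_simulation(cfg, dir)
  expect_length(man$samples, 9L)
  t <- read_cpg_table(file.path(dir, man$samples[[1]]$path),
                      man$samples[[1]]$sample_id,
                      man$samples[[1]]$condition)
  expect_s3_class(t, "cpg_table")
  expect_s4_class(read_features_bed(file.path(dir, "features.bed")),
                  "GRanges")
  expect_s4_class(read_gene_models(file.path(dir, "genes.bed")), "GRanges")
  expect_true(nrow(read_expression_table(
    file.path(dir, "expression.tsv"))) > 0)
  expect_true(nrow(read_interactions_bedpe(
    file.path(dir, "interactions.bedpe"))) > 0)
  expect_true(nrow(read_bedgraph(
    file.path(dir, "occupancy_TPA.bedgraph"))) > 0)
})
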