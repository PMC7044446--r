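# hand-constructable two-condition count tables around the window procedure

aligned <- function(pos, cov_a, meth_a, cov_b, meth_b, chrom = "chr1") {
  methdiff:::align_condition_counts(
    make_counts(pos, cov_a, meth_a, chrom = chrom),
    make_counts(pos, cov_b, meth_b, chrom = chrom))
}

test_that("build_windows slides one CpG at a time within the span limit", {
  # 5 CpGs, 100 bp apart -> 3 windows; 3 windows <-> 5 CpGs
  cnt <- aligned(pos = seq(0, 400, 100), cov_a = 30, meth_a = 27,
                 cov_b = 30, meth_b = 3)
  w <- build_windows(cnt)
  expect_equal(nrow(w), 3L)
  expect_equal(w$idx, 1:3)
  expect_equal(w$start, c(0L, 100L, 200L))
  expect_equal(w$end, c(201L, 301L, 401L))
  expect_equal(w$cov_a, rep(30, 3))

  # triple spanning 2.5 kb emits nothing
  w2 <- build_windows(aligned(pos = c(0, 1000, 2500), cov_a = 30,
                              meth_a = 1, cov_b = 30, meth_b = 1))
  expect_equal(nrow(w2), 0L)

  # fewer CpGs than a window
  w3 <- build_windows(aligned(pos = c(0, 10), cov_a = 30, meth_a = 1,
                              cov_b = 30, meth_b = 1))
  expect_equal(nrow(w3), 0L)

  # windows never straddle chromosomes
  cnt4 <- methdiff:::align_condition_counts(
    rbind(make_counts(c(0, 100), 30, 3), make_counts(c(0, 100), 30, 3, "chr2")),
    rbind(make_counts(c(0, 100), 30, 3), make_counts(c(0, 100), 30, 3, "chr2")))
  expect_equal(nrow(build_windows(cnt4)), 0L)
})

test_that("test_windows rounds averaged counts and tests both sides", {
  cnt <- aligned(pos = seq(0, 400, 100), cov_a = 30, meth_a = 27,
                 cov_b = 30, meth_b = 3)
  sig <- test_windows(build_windows(cnt))
  # frozen oracle value for [[27,3],[3,27]]: enum_fisher_oracle = 2.8197e-10
  expect_equal(nrow(sig), 3L)
  expect_equal(sig$p_value, rep(2.819733e-10, 3), tolerance = 1e-6)
  expect_equal(unique(sig$direction), "hypo")

  flat <- aligned(pos = seq(0, 400, 100), cov_a = 30, meth_a = 15,
                  cov_b = 30, meth_b = 15)
  expect_equal(nrow(test_windows(build_windows(flat))), 0L)
  expect_equal(nrow(test_windows(build_windows(flat), alpha = 1.0)), 0L)
  # alpha = 1 keeps all windows with a direction
  tilt <- aligned(pos = seq(0, 400, 100), cov_a = 30, meth_a = 14,
                  cov_b = 30, meth_b = 16)
  expect_equal(nrow(test_windows(build_windows(tilt), alpha = 1.0)), 3L)
})

test_that("test_windows rounding is half-away-from-zero", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5, 2.4)),
               c(1, 2, 3, -1, 2))
  # averaged counts 26.5 must round to 27, not 26 (banker's would give 26)
  cnt <- aligned(pos = c(0, 100), cov_a = c(30, 31), meth_a = c(26, 27),
                 cov_b = c(30, 30), meth_b = c(3, 3))
  w <- build_windows(cnt, window_cpgs = 2L)
  sig <- test_windows(w, alpha = 1)
  want <- fisher_exact_2x2(round_half_away(26.5), round_half_away(30.5) -
                             round_half_away(26.5), 3, 27)
  expect_equal(sig$p_value, want)
})

test_that("merge_windows merges adjacent same-direction runs only", {
  sig <- test_windows(build_windows(aligned(
    pos = seq(0, 400, 100), cov_a = 30, meth_a = 27,
    cov_b = 30, meth_b = 3)))
  reg <- merge_windows(sig)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$cpg_lo, 1L)
  expect_equal(reg$cpg_hi, 5L)
  expect_equal(reg$n_windows, 3L)

  # a non-significant middle window splits the run
  gap <- sig[c(1, 3)]
  reg2 <- merge_windows(gap)
  expect_equal(nrow(reg2), 2L)

  # adjacent but direction-flipped windows do not merge
  flip <- data.table::copy(sig)
  flip$direction[2] <- "hyper"
  expect_equal(nrow(merge_windows(flip)), 3L)
})

test_that("retest_regions sums member counts and re-tests", {
  cnt <- aligned(pos = seq(0, 400, 100), cov_a = 30, meth_a = 27,
                 cov_b = 30, meth_b = 3)
  reg <- merge_windows(test_windows(build_windows(cnt)))
  ret <- retest_regions(reg, cnt)
  expect_equal(nrow(ret), 1L)
  # summed region table is [[135,15],[15,135]] (frozen oracle 5.6944e-49)
  expect_equal(ret$p_value, 5.694432e-49, tolerance = 1e-6)
  expect_equal(ret$n_cpgs, 5L)
  expect_equal(ret$mean_delta, -0.8)

  # equal summed rates are dropped (p = 1), kept only at alpha = 1
  flat_reg <- data.table::data.table(chrom = "chr1", start = 0L, end = 401L,
                                     cpg_lo = 1L, cpg_hi = 5L,
                                     n_windows = 3L, direction = "hypo")
  flat_cnt <- aligned(pos = seq(0, 400, 100), cov_a = 30, meth_a = 15,
                      cov_b = 30, meth_b = 15)
  expect_equal(nrow(retest_regions(flat_reg, flat_cnt)), 0L)
  kept <- retest_regions(flat_reg, flat_cnt, alpha = 1)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$p_value, 1)
})

test_that("filter_dmrs applies density and window-count rules", {
  mk_reg <- function(start, end, n_cpgs, n_windows)
    data.table::data.table(chrom = "chr1", start = start, end = end,
                           cpg_lo = 1L, cpg_hi = n_cpgs, n_cpgs = n_cpgs,
                           n_windows = n_windows, p_value = 1e-6,
                           mean_delta = 0.5, direction = "hyper")
  # 7 CpGs at 0,100..600: span 601 bp -> density 11.6/kb, kept
  kept <- filter_dmrs(mk_reg(0L, 601L, 7L, 5L))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$density, 7 / 0.601, tolerance = 1e-9)
  # 5 CpGs over 1900 bp: 2.63/kb < 3, dropped
  expect_equal(nrow(filter_dmrs(mk_reg(0L, 1900L, 5L, 3L))), 0L)
  # 2 windows dropped regardless of density
  expect_equal(nrow(filter_dmrs(mk_reg(0L, 400L, 4L, 2L))), 0L)
})

test_that("call_dmrs runs the five steps end to end", {
  # null input: no DMRs
  null_cnt_a <- make_counts(seq(0, 2000, 100), 30, 15)
  expect_equal(nrow(call_dmrs(null_cnt_a, null_cnt_a)), 0L)

  # one planted 7-CpG delta=0.8 block at 30x inside flat background
  pos <- c(seq(0, 5000, 500), seq(10000, 10600, 100), seq(15000, 20000, 500))
  block <- pos >= 10000 & pos <= 10600
  ca <- make_counts(pos, 30, ifelse(block, 27, 15))
  cb <- make_counts(pos, 30, ifelse(block, 3, 15))
  dmrs <- call_dmrs(ca, cb)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$start, 10000L)
  expect_equal(dmrs$end, 10601L)
  expect_equal(dmrs$n_cpgs, 7L)
  expect_equal(dmrs$direction, "hypo")
  expect_gte(dmrs$n_windows, 3L)
  expect_gte(dmrs$density, 3)

  # two blocks separated by > 2 kb of unchanged CpGs give two DMRs
  pos2 <- c(seq(0, 600, 100), seq(5000, 5600, 100))
  ca2 <- make_counts(pos2, 30, 3)
  cb2 <- make_counts(pos2, 30, 27)
  mid <- make_counts(seq(1500, 4000, 500), 30, 15)
  ca2 <- data.table::setkey(rbind(ca2, mid), chrom, pos)
  cb2 <- data.table::setkey(rbind(cb2, mid), chrom, pos)
  dmrs2 <- call_dmrs(ca2, cb2)
  expect_equal(nrow(dmrs2), 2L)
  expect_equal(unique(dmrs2$direction), "hyper")
})

test_that("DMR invariants hold and pipeline is chromosome-order invariant", {
  set.seed(33)
  cfg <- sim_config(seed = 33, n_chroms = 2L, chrom_length = 1e5,
                    n_cpgs = 600L,
                    planted_dmrs = list(n = 4L, delta = 0.4,
                                        n_cpgs = c(7L, 10L),
                                        spacing = c(50L, 150L),
                                        treated = "TPA", direction = "both"))
  sim <- simulate_methylome(cfg)
  filt <- filter_by_coverage(lapply(sim$tables, drop_contig, "chrM"))
  pa <- pool_condition_counts(filt, "UN")
  pb <- pool_condition_counts(filt, "TPA")
  dmrs <- call_dmrs(pa, pb)
  expect_gt(nrow(dmrs), 0L)
  expect_true(all(dmrs$n_cpgs >= 5L))
  expect_true(all(dmrs$n_windows >= 3L))
  expect_true(all(dmrs$density >= 3))
  expect_true(all(dmrs$p_value <= 0.05))
  expect_true(all(dmrs$direction %in% c("hyper", "hypo")))

  # per-chromosome processing gives identical output
  per_chrom <- data.table::rbindlist(lapply(c("chr2", "chr1"), function(ch)
    call_dmrs(pa[chrom == ch], pb[chrom == ch])))
  data.table::setkey(per_chrom, chrom, start)
  whole <- data.table::copy(dmrs)
  data.table::setkey(whole, chrom, start)
  expect_equal(per_chrom, whole)

  # shrinking alpha never increases the DMR count
  n_dmrs <- vapply(c(0.05, 0.01, 0.001), function(al)
    nrow(call_dmrs(pa, pb, alpha = al)), 0L)
  expect_true(all(diff(n_dmrs) <= 0L))
})
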