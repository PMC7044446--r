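#' Simulation configuration
#'
#' Builds the configuration for the synthetic WGBS-like world. Defaults
#' describe the emulated system: three cell states (UN, RA, TPA) with three
#' technical replicates each at ~30x mean coverage, a bimodal background
#' methylome dominated by highly methylated CpGs (>0.75 rate) with smaller
#' lowly methylated and partially methylated fractions, small planted
#' methylation shifts, an unmethylated mitochondrial control contig with a
#' constant non-conversion rate, and occupancy dips at hypomethylated
#' planted CpGs in the TPA-like state.
#'
#' @param seed RNG seed (all generators are deterministic given the seed).
#' @param n_chroms number of autosome-like contigs (`chr1`..).
#' @param chrom_length contig length in bp.
#' @param n_cpgs total background CpGs across contigs.
#' @param mean_coverage,coverage_dispersion negative-binomial coverage
#'   model per replicate (mean 30, size 8 by default).
#' @param conditions condition labels; the first is the reference.
#' @param n_replicates technical replicates per condition.
#' @param mix_weights mixture weights for the high / low / partial
#'   methylation modes (sum to 1).
#' @param planted_dmrs list: `n` blocks, `delta` shift, `n_cpgs` range per
#'   block, `spacing` range of the bp gap between consecutive block CpGs
#'   (blocks emulate CpG-dense regulatory elements, so their CpGs sit
#'   closer than the background), `treated` condition, `direction`
#'   (`"hyper"`, `"hypo"` or `"both"`).
#' @param planted_dmps list: `n` isolated DMPs, `delta`, `treated`.
#' @param rate_overdispersion beta-binomial overdispersion rho in [0, 1).
#'   0 (default) draws methylated counts binomially at the true rate; a
#'   positive value first perturbs each replicate's rate with a
#'   Beta(mean = true rate, rho) draw, emulating replicate-level
#'   overdispersion the Fisher test does not model.
#' @param n_chrm_cpgs CpGs on the chrM control contig.
#' @param nonconversion bisulfite non-conversion rate (apparent chrM
#'   methylation).
#' @param features list: `n_enhancer`, `n_neutral`, `width`,
#'   `enrichment_factor` for the feature generator.
#' @param genes list: `n` genes, `n_coupled` methylation-coupled genes,
#'   `coupling_noise_sd` (sd of the measured methylation-rate noise),
#'   `expr_base`, `expr_scale`, `expr_noise_sd`.
#' @param occupancy list: `bin` bp, `dip_depth`, `dip_halfwidth`,
#'   `dip_condition`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L,
                       chrom_length = 5e5,
                       n_cpgs = 2000L,
                       mean_coverage = 30,
                       coverage_dispersion = 8,
                       conditions = c("UN", "RA", "TPA"),
                       n_replicates = 3L,
                       mix_weights = c(high = 0.7, low = 0.2, mid = 0.1),
                       planted_dmrs = list(n = 0L, delta = 0.3,
                                           n_cpgs = c(7L, 15L),
                                           spacing = c(50L, 150L),
                                           treated = "TPA",
                                           direction = "both"),
                       planted_dmps = list(n = 0L, delta = 0.2,
                                           treated = "TPA"),
                       rate_overdispersion = 0,
                       n_chrm_cpgs = 100L,
                       nonconversion = 0.005,
                       features = list(n_enhancer = 40L, n_neutral = 40L,
                                       width = 500L, enrichment_factor = 1),
                       genes = list(n = 40L, n_coupled = 10L,
                                    coupling_noise_sd = 0.02,
                                    expr_base = 40, expr_scale = 150,
                                    expr_noise_sd = 0),
                       occupancy = list(bin = 10L, dip_depth = 0.5,
                                        dip_halfwidth = 50L,
                                        dip_condition = "TPA")) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(cfg$mix_weights) - 1) < 1e-9,
            cfg$nonconversion >= 0, cfg$nonconversion <= 1,
            cfg$planted_dmrs$delta > 0, cfg$planted_dmrs$delta <= 1)
  structure(cfg, class = "sim_config")
}

# mixture parameters of the background rate model (beta components)
.mix_shapes <- list(high = c(18, 2), low = c(1.5, 28), mid = c(2, 2))

#' CDF of the background methylation-rate mixture
#'
#' Used by distribution checks against generated background rates.
#'
#' @param q quantiles.
#' @param mix_weights named weights (high, low, mid).
#' @return mixture CDF values.
#' @export
background_mixture_cdf <- function(q, mix_weights = c(high = 0.7, low = 0.2,
                                                      mid = 0.1)) {
  mix_weights[["high"]] * stats::pbeta(q, 18, 2) +
    mix_weights[["low"]] * stats::pbeta(q, 1.5, 28) +
    mix_weights[["mid"]] * stats::pbeta(q, 2, 2)
}

draw_background_rates <- function(n, mix_weights) {
  comp <- sample(names(.mix_shapes), n, replace = TRUE, prob = mix_weights)
  r <- numeric(n)
  for (nm in names(.mix_shapes)) {
    idx <- comp == nm
    sh <- .mix_shapes[[nm]]
    r[idx] <- stats::rbeta(sum(idx), sh[1], sh[2])
  }
  r
}

#' Simulate a WGBS-like methylome with planted signal
#'
#' Draws CpG positions, background rates from the bimodal mixture (shared
#' across conditions), plants DMR blocks and isolated DMPs by shifting the
#' treated condition's true rate by `delta`, adds a chrM control contig at
#' the configured non-conversion rate, then emits one call table per
#' condition x replicate with negative-binomial coverage and binomial
#' methylated-call counts.
#'
#' @param config a [sim_config()].
#' @return list: `tables` (list of `cpg_table`), `truth` (list with
#'   `rates` — true per-condition rates per CpG —, `dmps`, `dmrs`).
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_per <- rep(config$n_cpgs %/% config$n_chroms, config$n_chroms)
  n_per[1] <- n_per[1] + config$n_cpgs %% config$n_chroms
  chroms <- paste0("chr", seq_len(config$n_chroms))
  pos_list <- lapply(seq_len(config$n_chroms), function(i)
    sort(sample.int(config$chrom_length, n_per[i]) - 1L))
  rates <- data.table::data.table(
    chrom = rep(chroms, n_per), pos = unlist(pos_list))
  base <- draw_background_rates(nrow(rates), config$mix_weights)
  for (cc in config$conditions) rates[, (paste0("true_", cc)) := base]

  truth_dmrs <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    n_cpgs = integer(), delta = numeric(), direction = character())
  truth_dmps <- data.table::data.table(
    chrom = character(), pos = integer(), delta = numeric(),
    direction = character())
  used <- rep(FALSE, nrow(rates))           # CpGs already claimed (+ margin)

  claim <- function(i0, i1, margin = 10L) {
    lo <- max(1L, i0 - margin); hi <- min(nrow(rates), i1 + margin)
    if (any(used[lo:hi])) return(FALSE)
    used[lo:hi] <<- TRUE
    TRUE
  }

  pd <- config$planted_dmrs
  if (pd$n > 0L) {
    treated <- pd$treated
    spacing <- pd$spacing %||% c(50L, 150L)
    sizes <- sample(seq(pd$n_cpgs[1], pd$n_cpgs[2]), pd$n, replace = TRUE)
    dirs <- switch(pd$direction,
                   both = rep_len(c("hyper", "hypo"), pd$n),
                   rep(pd$direction, pd$n))
    placed <- 0L
    tries <- 0L
    while (placed < pd$n && tries < 50L * pd$n) {
      tries <- tries + 1L
      sz <- sizes[placed + 1L]
      i0 <- sample.int(nrow(rates) - sz, 1L)
      i1 <- i0 + sz - 1L
      if (rates$chrom[i0] != rates$chrom[i1]) next
      # blocks are CpG-dense clusters: compact the claimed CpGs to
      # spacing[1]..spacing[2] bp gaps; needs room before the next CpG
      gaps <- sample(seq(spacing[1], spacing[2]), sz - 1L, replace = TRUE)
      new_pos <- rates$pos[i0] + c(0L, cumsum(gaps))
      right_bound <- if (i1 < nrow(rates) &&
                           rates$chrom[i1 + 1L] == rates$chrom[i0])
        rates$pos[i1 + 1L] else as.integer(config$chrom_length)
      if (new_pos[sz] >= right_bound) next
      if (!claim(i0, i1)) next
      data.table::set(rates, i0:i1, "pos", new_pos)
      placed <- placed + 1L
      dir <- dirs[placed]
      b <- if (dir == "hyper") stats::runif(1, 0.05, 1 - pd$delta - 0.05)
           else stats::runif(1, pd$delta + 0.05, 0.95)
      shift <- if (dir == "hyper") pd$delta else -pd$delta
      for (cc in config$conditions)
        data.table::set(rates, i0:i1, paste0("true_", cc), b)
      data.table::set(rates, i0:i1, paste0("true_", treated), b + shift)
      truth_dmrs <- rbind(truth_dmrs, data.table::data.table(
        chrom = rates$chrom[i0], start = rates$pos[i0],
        end = rates$pos[i1] + 1L, n_cpgs = sz, delta = shift,
        direction = dir))
    }
    if (placed < pd$n)
      stopf("could not place %d non-overlapping DMR blocks", pd$n)
  }

  pp <- config$planted_dmps
  if (pp$n > 0L) {
    placed <- 0L; tries <- 0L
    while (placed < pp$n && tries < 50L * pp$n) {
      tries <- tries + 1L
      i <- sample.int(nrow(rates), 1L)
      if (!claim(i, i, margin = 5L)) next
      placed <- placed + 1L
      dir <- if (placed %% 2L == 1L) "hyper" else "hypo"
      b <- if (dir == "hyper") stats::runif(1, 0.05, 1 - pp$delta - 0.05)
           else stats::runif(1, pp$delta + 0.05, 0.95)
      shift <- if (dir == "hyper") pp$delta else -pp$delta
      for (cc in config$conditions)
        data.table::set(rates, i, paste0("true_", cc), b)
      data.table::set(rates, i, paste0("true_", pp$treated), b + shift)
      truth_dmps <- rbind(truth_dmps, data.table::data.table(
        chrom = rates$chrom[i], pos = rates$pos[i], delta = shift,
        direction = dir))
    }
  }

  # chrM control contig: apparent methylation = non-conversion rate
  if (config$n_chrm_cpgs > 0L) {
    mpos <- sort(sample.int(16000L, config$n_chrm_cpgs) - 1L)
    mdt <- data.table::data.table(chrom = "chrM", pos = mpos)
    for (cc in config$conditions)
      mdt[, (paste0("true_", cc)) := config$nonconversion]
    rates <- rbind(rates, mdt)
  }
  data.table::setkey(rates, chrom, pos)

  rho <- config$rate_overdispersion %||% 0
  tables <- list()
  for (cc in config$conditions) {
    true_rate <- rates[[paste0("true_", cc)]]
    for (rep_i in seq_len(config$n_replicates)) {
      coverage <- stats::rnbinom(nrow(rates), mu = config$mean_coverage,
                                 size = config$coverage_dispersion)
      rate_i <- if (rho > 0) {
        # beta-binomial mode: Beta with mean true_rate, rho = 1/(a+b+1)
        s <- (1 - rho) / rho
        p <- pmin(pmax(true_rate, 1e-6), 1 - 1e-6)
        stats::rbeta(nrow(rates), p * s, (1 - p) * s)
      } else true_rate
      meth <- stats::rbinom(nrow(rates), coverage, rate_i)
      tables[[paste(cc, rep_i, sep = "_rep")]] <- cpg_table(
        data.table::data.table(chrom = rates$chrom, pos = rates$pos,
                               coverage = coverage, meth_calls = meth),
        sample_id = paste(cc, rep_i, sep = "_rep"), condition = cc)
    }
  }
  list(tables = tables,
       truth = list(rates = rates[], dmps = truth_dmps[], dmrs = truth_dmrs[],
                    config = config))
}

#' Simulate feature tracks tied to the planted signal
#'
#' Emits an `enhancer` class whose intervals preferentially cover planted
#' DMR blocks (an interval is block-centred with probability
#' `1 - 1/enrichment_factor`; factor 1 means uniform placement) and a
#' `neutral` class placed uniformly.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_methylome()].
#' @return `GRanges` with a `feature` column (classes `enhancer`,
#'   `neutral`).
#' @export
simulate_features <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  fc <- config$features
  chroms <- paste0("chr", seq_len(config$n_chroms))
  rand_interval <- function(n) {
    ch <- sample(chroms, n, replace = TRUE)
    st <- vapply(ch, function(x)
      sample.int(config$chrom_length - fc$width, 1L) - 1L, 0L)
    data.table::data.table(chrom = ch, start = st, end = st + fc$width)
  }
  p_block <- if (fc$enrichment_factor <= 1 || nrow(truth$dmrs) == 0L) 0
             else 1 - 1 / fc$enrichment_factor
  on_block <- stats::runif(fc$n_enhancer) < p_block
  enh <- rand_interval(fc$n_enhancer)
  if (any(on_block)) {
    pick <- sample.int(nrow(truth$dmrs), sum(on_block), replace = TRUE)
    ctr <- (truth$dmrs$start[pick] + truth$dmrs$end[pick]) %/% 2L
    enh[on_block, `:=`(chrom = truth$dmrs$chrom[pick],
                       start = pmax(0L, ctr - as.integer(fc$width %/% 2L)))]
    enh[on_block, end := start + fc$width]
  }
  neu <- rand_interval(fc$n_neutral)
  gr <- bed_to_granges(c(enh$chrom, neu$chrom), c(enh$start, neu$start),
                       c(enh$end, neu$end))
  S4Vectors::mcols(gr)$feature <- rep(c("enhancer", "neutral"),
                                      c(nrow(enh), nrow(neu)))
  gr
}

#' Simulate gene models and methylation-coupled expression
#'
#' Coupled genes get a promoter placed over a planted DMR block; their
#' expression is a monotone (sign-alternating) linear function of the
#' block's true methylation across conditions. The measured per-condition
#' promoter methylation is the true rate plus Gaussian noise
#' (`coupling_noise_sd`). Null genes get condition-independent expression.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_methylome()].
#' @return list: `genes` (`GRanges` with `gene_id`), `expression`
#'   (data.table), `couplings` (gene_id, sign, block index, measured
#'   per-condition methylation `meth_<cond>`).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2000L)
  gc <- config$genes
  conds <- config$conditions
  n_coupled <- min(gc$n_coupled, nrow(truth$dmrs))
  n_null <- gc$n - n_coupled
  gene_len <- 2000L
  rows <- list(); expr <- list(); coup <- list()
  for (i in seq_len(n_coupled)) {
    blk <- truth$dmrs[i]
    ctr <- (blk$start + blk$end) %/% 2L
    gid <- sprintf("geneC%02d", i)
    sign_i <- if (i %% 2L == 1L) 1 else -1
    # block true methylation per condition = rates of CpGs inside the block
    in_blk <- truth$rates[chrom == blk$chrom & pos >= blk$start &
                            pos < blk$end]
    true_meth <- vapply(conds, function(cc)
      mean(in_blk[[paste0("true_", cc)]]), 0)
    meas_meth <- pmin(1, pmax(0, true_meth +
                                stats::rnorm(length(conds),
                                             sd = gc$coupling_noise_sd)))
    e <- pmax(0, gc$expr_base +
                sign_i * gc$expr_scale * (true_meth - mean(true_meth)) +
                stats::rnorm(length(conds), sd = gc$expr_noise_sd))
    rows[[gid]] <- data.table::data.table(
      chrom = blk$chrom, start = ctr, end = ctr + gene_len,
      gene_id = gid, strand = "+")
    expr[[gid]] <- c(gene_id = gid, as.list(e))
    coup[[gid]] <- data.table::data.table(
      gene_id = gid, sign = sign_i, block = i,
      t(stats::setNames(meas_meth, paste0("meth_", conds))))
  }
  for (i in seq_len(n_null)) {
    gid <- sprintf("geneN%02d", i)
    st <- sample.int(config$chrom_length - gene_len - 3000L, 1L) + 2500L
    strand_i <- sample(c("+", "-"), 1L)
    level <- stats::runif(1, 20, 100)
    e <- pmax(0, level + stats::rnorm(length(conds), sd = gc$expr_noise_sd))
    rows[[gid]] <- data.table::data.table(
      chrom = sample(paste0("chr", seq_len(config$n_chroms)), 1L),
      start = st, end = st + gene_len, gene_id = gid, strand = strand_i)
    expr[[gid]] <- c(gene_id = gid, as.list(e))
  }
  gdt <- data.table::rbindlist(rows)
  genes <- bed_to_granges(gdt$chrom, gdt$start, gdt$end, strand = gdt$strand)
  S4Vectors::mcols(genes)$gene_id <- gdt$gene_id
  ex <- data.table::rbindlist(lapply(expr, as.list))
  data.table::setnames(ex, c("gene_id", conds))
  for (cc in conds) ex[, (cc) := as.numeric(get(cc))]
  data.table::setkey(ex, gene_id)
  list(genes = genes, expression = ex[],
       couplings = if (length(coup)) data.table::rbindlist(coup)
                   else data.table::data.table())
}

#' Simulate chromatin interaction pairs anchored on planted blocks
#'
#' One interaction per coupled gene: anchor A spans the planted block,
#' anchor B spans the gene's TSS region, enabling distal DMP-to-gene
#' linking.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_methylome()].
#' @param sim_expr result of [simulate_expression()].
#' @return BEDPE-style data.table (see [read_interactions_bedpe()]).
#' @export
simulate_interactions <- function(config, truth, sim_expr) {
  coup <- sim_expr$couplings
  if (nrow(coup) == 0L) {
    return(data.table::data.table(
      chromA = character(), startA = integer(), endA = integer(),
      chromB = character(), startB = integer(), endB = integer(),
      pair_id = integer()))
  }
  genes <- sim_expr$genes
  gid <- S4Vectors::mcols(genes)$gene_id
  tss <- tss_region(genes)
  out <- lapply(seq_len(nrow(coup)), function(i) {
    blk <- truth$dmrs[coup$block[i]]
    g <- which(gid == coup$gene_id[i])
    data.table::data.table(
      chromA = blk$chrom, startA = pmax(0L, blk$start - 200L),
      endA = blk$end + 200L,
      chromB = as.character(GenomicRanges::seqnames(tss))[g],
      startB = GenomicRanges::start(tss)[g] - 1L,
      endB = GenomicRanges::end(tss)[g])
  })
  dt <- data.table::rbindlist(out)
  dt[, pair_id := seq_len(.N)]
  dt[]
}

#' Simulate nucleosome occupancy tracks
#'
#' Baseline occupancy 1.0 tiled in `bin`-bp steps per condition; in the
#' dip condition, occupancy drops by `dip_depth` within
#' `dip_halfwidth` bp of every hypomethylated planted CpG (block members
#' and isolated DMPs).
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_methylome()].
#' @return named list of bedGraph-style data.tables, one per condition.
#' @export
simulate_occupancy <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  oc <- config$occupancy
  chroms <- paste0("chr", seq_len(config$n_chroms))
  tile <- data.table::rbindlist(lapply(chroms, function(ch) {
    st <- seq.int(0L, config$chrom_length - 1L, by = oc$bin)
    data.table::data.table(chrom = ch, start = st,
                           end = pmin(st + oc$bin, config$chrom_length),
                           value = 1.0)
  }))
  dips <- rbind(
    if (nrow(truth$dmrs)) {
      hypo <- truth$dmrs[direction == "hypo"]
      if (nrow(hypo)) truth$rates[hypo, on = .(chrom, pos >= start, pos < end),
                                  .(chrom, pos = x.pos), nomatch = NULL]
    },
    if (nrow(truth$dmps)) truth$dmps[direction == "hypo", .(chrom, pos)])
  out <- list()
  for (cc in config$conditions) {
    tr <- data.table::copy(tile)
    if (cc == oc$dip_condition && !is.null(dips) && nrow(dips)) {
      for (i in seq_len(nrow(dips))) {
        lo <- dips$pos[i] - oc$dip_halfwidth
        hi <- dips$pos[i] + oc$dip_halfwidth
        tr[chrom == dips$chrom[i] & end > lo & start <= hi,
           value := 1 - oc$dip_depth]
      }
    }
    data.table::setkey(tr, chrom, start, end)
    out[[cc]] <- tr[]
  }
  out
}

#' Write a full synthetic dataset to disk
#'
#' Emits every file dialect the pipeline consumes (CpG call tables,
#' feature BED, gene BED6, expression TSV, interactions BEDPE, occupancy
#' bedGraphs) plus a JSON manifest recording the configuration and file
#' paths.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return the manifest as a list, invisibly; files are written under
#'   `dir`.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_methylome(config)
  feats <- simulate_features(config, sim$truth)
  se <- simulate_expression(config, sim$truth)
  inter <- simulate_interactions(config, sim$truth, se)
  occ <- simulate_occupancy(config, sim$truth)

  samples <- list()
  for (nm in names(sim$tables)) {
    p <- file.path(dir, paste0(nm, ".cpg.tsv"))
    write_cpg_table(sim$tables[[nm]], p)
    samples[[nm]] <- list(path = basename(p),
                          sample_id = sim$tables[[nm]]$sample_id,
                          condition = sim$tables[[nm]]$condition)
  }
  fdt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(feats)),
    start = GenomicRanges::start(feats) - 1L,
    end = GenomicRanges::end(feats),
    feature = S4Vectors::mcols(feats)$feature)
  data.table::fwrite(fdt, file.path(dir, "features.bed"), sep = "\t",
                     col.names = FALSE)
  gdt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(se$genes)),
    start = GenomicRanges::start(se$genes) - 1L,
    end = GenomicRanges::end(se$genes),
    gene_id = S4Vectors::mcols(se$genes)$gene_id, score = 0,
    strand = as.character(GenomicRanges::strand(se$genes)))
  data.table::fwrite(gdt, file.path(dir, "genes.bed"), sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(se$expression, file.path(dir, "expression.tsv"),
                     sep = "\t")
  data.table::fwrite(inter[, 1:6], file.path(dir, "interactions.bedpe"),
                     sep = "\t", col.names = FALSE)
  occ_paths <- list()
  for (cc in names(occ)) {
    p <- file.path(dir, paste0("occupancy_", cc, ".bedgraph"))
    data.table::fwrite(occ[[cc]], p, sep = "\t", col.names = FALSE)
    occ_paths[[cc]] <- basename(p)
  }
  data.table::fwrite(sim$truth$dmrs, file.path(dir, "truth_dmrs.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$truth$dmps, file.path(dir, "truth_dmps.tsv"),
                     sep = "\t")
  manifest <- list(
    seed = config$seed, conditions = config$conditions,
    samples = samples, features = "features.bed", genes = "genes.bed",
    expression = "expression.tsv", interactions = "interactions.bedpe",
    occupancy = occ_paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
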