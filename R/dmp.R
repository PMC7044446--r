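#' Pool counts across samples of one condition
#'
#' Sums coverage and methylated calls per position over all tables carrying
#' the given condition label. Tables must already share an identical
#' position index (run [filter_by_coverage()] first).
#'
#' @param tables list of `cpg_table`s.
#' @param condition condition label to pool.
#' @return data.table with `chrom`, `pos`, `coverage`, `meth_calls`.
#' @export
pool_condition_counts <- function(tables, condition) {
  stopifnot(all(vapply(tables, inherits, TRUE, "cpg_table")))
  sel <- Filter(function(t) t$condition == condition, tables)
  if (length(sel) == 0L) stopf("no samples with condition %s", condition)
  n_pos <- vapply(sel, function(t) nrow(t$data), 0L)
  if (length(unique(n_pos)) != 1L)
    stopf("tables of condition %s do not share a position index; filter first",
          condition)
  all <- data.table::rbindlist(lapply(sel, `[[`, "data"))
  pooled <- all[, .(coverage = sum(coverage), meth_calls = sum(meth_calls)),
                by = .(chrom, pos)]
  if (nrow(pooled) != n_pos[1])
    stopf("tables of condition %s do not share a position index; filter first",
          condition)
  data.table::setkey(pooled, chrom, pos)
  pooled[]
}

#' Call differentially methylated positions (DMPs) by Fisher exact test
#'
#' For each CpG a 2x2 table of pooled (methylated, unmethylated) calls in
#' the two conditions is tested with the two-sided Fisher exact test
#' ([fisher_exact_2x2()]). CpGs with `p <= alpha` are returned as DMPs with
#' the rate difference `delta = rate_b - rate_a` (treated minus reference,
#' so `"hyper"` means higher methylation after treatment).
#'
#' No multiple-testing correction is applied by default (raw `alpha`);
#' `p_adjust = "BH"` switches to Benjamini-Hochberg adjusted p-values.
#'
#' @param counts_a,counts_b pooled count tables from
#'   [pool_condition_counts()], aligned on the same position index
#'   (condition A = reference, B = treated).
#' @param alpha significance level in (0, 1), default 0.05.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.table of DMPs: `chrom`, `pos`, `cov_a`, `meth_a`, `cov_b`,
#'   `meth_b`, `rate_a`, `rate_b`, `delta`, `p_value`, `direction`. The
#'   number of CpGs tested is attached as attribute `n_tested`.
#' @export
fisher_dmp <- function(counts_a, counts_b, alpha = 0.05,
                       p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stopf("alpha must lie in (0, 1)")
  a <- data.table::as.data.table(counts_a)
  b <- data.table::as.data.table(counts_b)
  if (nrow(a) != nrow(b) || !identical(a$pos, b$pos) ||
      !identical(a$chrom, b$chrom))
    stopf("counts_a and counts_b must share an identical position index")
  if (any(a$coverage <= 0L) || any(b$coverage <= 0L))
    stopf("all pooled coverages must be positive; filter first")
  dt <- data.table::data.table(
    chrom = a$chrom, pos = a$pos,
    cov_a = a$coverage, meth_a = a$meth_calls,
    cov_b = b$coverage, meth_b = b$meth_calls)
  dt[, rate_a := meth_a / cov_a]
  dt[, rate_b := meth_b / cov_b]
  dt[, delta := rate_b - rate_a]
  dt[, p_value := fisher_exact_2x2(meth_a, cov_a - meth_a,
                                   meth_b, cov_b - meth_b)]
  if (p_adjust == "BH") dt[, p_value := stats::p.adjust(p_value, "BH")]
  n_tested <- nrow(dt)
  out <- dt[p_value <= alpha]
  out[, direction := ifelse(delta > 0, "hyper", "hypo")]
  out <- out[delta != 0]          # delta == 0 cannot be directional
  data.table::setattr(out, "n_tested", n_tested)
  out[]
}

#' Union of DMP sets across comparisons
#'
#' De-duplicates DMPs from several pairwise comparisons by `(chrom, pos)`,
#' keeping the provenance of contributing comparisons.
#'
#' @param dmp_sets named list of DMP tables (names = comparison labels).
#' @return data.table of unique positions with a `comparisons` column
#'   (comma-separated contributing comparison labels).
#' @export
union_dmps <- function(dmp_sets) {
  stopifnot(is.list(dmp_sets), length(dmp_sets) >= 1L)
  nms <- names(dmp_sets) %||% paste0("cmp", seq_along(dmp_sets))
  if (is.null(names(dmp_sets))) names(dmp_sets) <- nms
  tagged <- data.table::rbindlist(lapply(nms, function(nm) {
    d <- data.table::as.data.table(dmp_sets[[nm]])
    if (nrow(d) == 0L) return(data.table::data.table(
      chrom = character(), pos = integer(), comparison = character()))
    d[, .(chrom, pos, comparison = nm)]
  }))
  out <- tagged[, .(comparisons = paste(sort(unique(comparison)),
                                        collapse = ",")),
                by = .(chrom, pos)]
  data.table::setkey(out, chrom, pos)
  out[]
}

#' Principal component analysis of sample methylation profiles
#'
#' Samples are the observations and CpG rates the variables; variables are
#' mean-centred, not scaled. Returns per-sample scores and explained
#' variance fractions (non-increasing, summing to 1 when total variance is
#' positive; components with zero variance are dropped).
#'
#' @param rate_matrix numeric matrix, CpG positions x samples (no missing
#'   values; apply the joint coverage filter first).
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions) and `sdev`.
#' @export
methylation_pca <- function(rate_matrix) {
  x <- as.matrix(rate_matrix)
  if (ncol(x) < 2L) stopf("need >= 2 samples")
  if (anyNA(x)) stopf("missing rates; filter to a shared position index first")
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  keep <- fit$sdev > max(fit$sdev) * 1e-12 & fit$sdev > 0
  if (!any(keep)) {           # all samples identical
    return(list(scores = fit$x[, 0, drop = FALSE],
                explained = numeric(0), sdev = numeric(0)))
  }
  vars <- fit$sdev[keep]^2
  list(scores = fit$x[, keep, drop = FALSE],
       explained = vars / sum(vars),
       sdev = fit$sdev[keep])
}

#' Write DMPs as BED6+ with extra columns
#'
#' Columns: chrom, start, end, name (comparison label), score (-log10 p,
#' capped at 999), strand ".", then rate_a, rate_b, delta, direction.
#'
#' @param dmps a DMP table from [fisher_dmp()].
#' @param path output path.
#' @param name comparison label written in the name column.
#' @return `path`, invisibly.
#' @export
write_dmp_bed <- function(dmps, path, name = "dmp") {
  d <- data.table::as.data.table(dmps)
  out <- d[, .(chrom, start = pos, end = pos + 1L, name = name,
               score = round(pmin(999, -log10(pmax(p_value, 1e-300))), 4),
               strand = ".", rate_a = round(rate_a, 6),
               rate_b = round(rate_b, 6), delta = round(delta, 6), direction)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
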