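#' Align two pooled condition count tables
#'
#' @param counts_a,counts_b pooled tables from [pool_condition_counts()].
#' @return merged data.table with per-condition count columns, sorted by
#'   `(chrom, pos)`.
#' @keywords internal
align_condition_counts <- function(counts_a, counts_b) {
  a <- data.table::as.data.table(counts_a)
  b <- data.table::as.data.table(counts_b)
  if (nrow(a) != nrow(b) || !identical(a$pos, b$pos) ||
      !identical(a$chrom, b$chrom))
    stopf("condition count tables must share an identical position index")
  dt <- data.table::data.table(
    chrom = a$chrom, pos = a$pos,
    cov_a = a$coverage, meth_a = a$meth_calls,
    cov_b = b$coverage, meth_b = b$meth_calls)
  if (is.unsorted(order(dt$chrom, dt$pos)) ||
      any(dt[, diff(pos) <= 0, by = chrom]$V1))
    stopf("CpGs must be sorted and unique within chromosomes")
  dt
}

#' Build 3-CpG sliding windows
#'
#' One window per run of `window_cpgs` consecutive CpGs on a chromosome
#' (step = one CpG, so windows overlap: three consecutive windows span five
#' CpGs). Windows wider than `max_span` base pairs are skipped. Each window
#' stores the per-condition *mean* coverage and mean methylated-call count
#' over its CpGs.
#'
#' @param counts merged count table from [align_condition_counts()] (or the
#'   two pooled tables via `call_dmrs`).
#' @param window_cpgs CpGs per window (default 3).
#' @param max_span maximum window span in bp, end-exclusive (default 2000).
#' @return data.table of windows: `chrom`, `idx` (row index of the first
#'   member CpG in `counts`), `start`, `end`, mean count columns.
#' @export
build_windows <- function(counts, window_cpgs = 3L, max_span = 2000L) {
  dt <- counts
  w <- window_cpgs
  n <- nrow(dt)
  if (n < w) {
    return(data.table::data.table(
      chrom = character(), idx = integer(), start = integer(),
      end = integer(), cov_a = numeric(), meth_a = numeric(),
      cov_b = numeric(), meth_b = numeric()))
  }
  # candidate first-CpG indices: the whole triple must sit on one chromosome
  first <- seq_len(n - w + 1L)
  same_chrom <- dt$chrom[first] == dt$chrom[first + w - 1L]
  first <- first[same_chrom]
  span_ok <- (dt$pos[first + w - 1L] + 1L - dt$pos[first]) <= max_span
  first <- first[span_ok]
  mean_over <- function(col) {
    s <- numeric(length(first))
    for (j in 0:(w - 1L)) s <- s + dt[[col]][first + j]
    s / w
  }
  data.table::data.table(
    chrom = dt$chrom[first], idx = first,
    start = dt$pos[first], end = dt$pos[first + w - 1L] + 1L,
    cov_a = mean_over("cov_a"), meth_a = mean_over("meth_a"),
    cov_b = mean_over("cov_b"), meth_b = mean_over("meth_b"))
}

#' First-pass window significance test
#'
#' Averaged counts are rounded to integers (half away from zero), formed
#' into a 2x2 table and tested with the two-sided Fisher exact test.
#' Windows with `p <= alpha` and a defined direction are returned; the
#' direction is the sign of the averaged rate difference (condition B minus
#' condition A).
#'
#' @param windows window table from [build_windows()].
#' @param alpha significance level (default 0.05).
#' @param count_mode `"mean"` (default; mean counts rounded half away from
#'   zero) or `"sum"` (summed counts, no rounding needed).
#' @return significant windows with `p_value`, `delta`, `direction`.
#' @export
test_windows <- function(windows, alpha = 0.05,
                         count_mode = c("mean", "sum")) {
  count_mode <- match.arg(count_mode)
  w <- data.table::copy(data.table::as.data.table(windows))
  if (nrow(w) == 0L) {
    w[, `:=`(p_value = numeric(0), delta = numeric(0),
             direction = character(0))]
    return(w[])
  }
  scale <- if (count_mode == "sum") 3 else 1    # undo the mean
  ma <- round_half_away(w$meth_a * scale); ca <- round_half_away(w$cov_a * scale)
  mb <- round_half_away(w$meth_b * scale); cb <- round_half_away(w$cov_b * scale)
  ma <- pmin(ma, ca); mb <- pmin(mb, cb)        # rounding guard
  stopifnot(all(ca - ma >= 0), all(cb - mb >= 0))
  w[, p_value := fisher_exact_2x2(ma, ca - ma, mb, cb - mb)]
  w[, delta := meth_b / cov_b - meth_a / cov_a]
  out <- w[p_value <= alpha & delta != 0]
  out[, direction := ifelse(delta > 0, "hyper", "hypo")]
  out[]
}

#' Merge continuous significant windows into candidate regions
#'
#' Significant windows whose first-CpG indices are consecutive (step one,
#' i.e. overlapping by two CpGs) and that share a direction are merged; a
#' non-significant window or a direction flip breaks the run. Region CpGs
#' are the union of member-window CpGs (a contiguous index range).
#'
#' @param sig_windows output of [test_windows()].
#' @param window_cpgs CpGs per window (default 3).
#' @return data.table of candidate regions with member CpG index range,
#'   `n_windows` (count of first-pass significant member windows) and
#'   `direction`.
#' @export
merge_windows <- function(sig_windows, window_cpgs = 3L) {
  w <- data.table::as.data.table(sig_windows)
  if (nrow(w) == 0L) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      cpg_lo = integer(), cpg_hi = integer(), n_windows = integer(),
      direction = character()))
  }
  data.table::setorder(w, chrom, idx)
  new_run <- c(TRUE, diff(w$idx) != 1L |
                 w$direction[-1] != w$direction[-nrow(w)] |
                 w$chrom[-1] != w$chrom[-nrow(w)])
  w[, run_id := cumsum(new_run)]
  w[, .(chrom = chrom[1L],
        start = min(start), end = max(end),
        cpg_lo = min(idx), cpg_hi = max(idx) + window_cpgs - 1L,
        n_windows = .N, direction = direction[1L]),
    by = run_id][, run_id := NULL][]
}

#' Second-pass region significance test
#'
#' Pooled counts are summed over every member CpG of a region per condition
#' and the single 2x2 table is re-tested; regions with `p <= alpha` are
#' kept with the second-pass p-value and the mean per-CpG rate difference.
#'
#' @param regions candidate regions from [merge_windows()].
#' @param counts the merged count table the windows were built from.
#' @param alpha significance level (default 0.05).
#' @return regions passing the re-test, with `p_value`, `mean_delta`,
#'   `n_cpgs`.
#' @export
retest_regions <- function(regions, counts, alpha = 0.05) {
  r <- data.table::copy(data.table::as.data.table(regions))
  if (nrow(r) == 0L) {
    r[, `:=`(p_value = numeric(0), mean_delta = numeric(0),
             n_cpgs = integer(0))]
    return(r[])
  }
  if (any(r$cpg_hi < r$cpg_lo)) stopf("empty region")
  stats_one <- function(lo, hi) {
    rows <- lo:hi
    ca <- sum(counts$cov_a[rows]); ma <- sum(counts$meth_a[rows])
    cb <- sum(counts$cov_b[rows]); mb <- sum(counts$meth_b[rows])
    d <- mean(counts$meth_b[rows] / counts$cov_b[rows] -
                counts$meth_a[rows] / counts$cov_a[rows])
    c(fisher_exact_2x2(ma, ca - ma, mb, cb - mb), d)
  }
  res <- mapply(stats_one, r$cpg_lo, r$cpg_hi)
  r[, p_value := res[1, ]]
  r[, mean_delta := res[2, ]]
  r[, n_cpgs := cpg_hi - cpg_lo + 1L]
  r[p_value <= alpha][]
}

#' Final DMR density and window-count filter
#'
#' Keeps regions with at least `min_density` CpGs per kb of span (span =
#' last CpG position - first CpG position + 1) and at least `min_windows`
#' first-pass significant member windows (equivalently >= 5 CpGs), dropping
#' regions likely driven by a single differentially methylated CpG.
#'
#' @param regions re-tested regions from [retest_regions()].
#' @param min_density minimum CpGs/kb (default 3).
#' @param min_windows minimum member windows (default 3).
#' @return data.table of DMRs: `chrom`, `start`, `end`, `n_cpgs`,
#'   `n_windows`, `density`, `p_value`, `mean_delta`, `direction`.
#' @export
filter_dmrs <- function(regions, min_density = 3, min_windows = 3L) {
  r <- data.table::copy(data.table::as.data.table(regions))
  if (nrow(r) == 0L) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      n_cpgs = integer(), n_windows = integer(), density = numeric(),
      p_value = numeric(), mean_delta = numeric(), direction = character()))
  }
  r[, span := end - start]                 # = last - first + 1 (end exclusive)
  r[, density := ifelse(span > 0L, n_cpgs / (span / 1000), Inf)]
  out <- r[density >= min_density & n_windows >= min_windows]
  out[, .(chrom, start, end, n_cpgs, n_windows, density, p_value,
          mean_delta, direction)][]
}

#' Call differentially methylated regions (DMRs)
#'
#' Runs the five-step sliding-window procedure: build overlapping 3-CpG
#' windows (max 2 kb span), Fisher-test each window at `alpha`, merge
#' continuous same-direction significant windows, re-test each merged
#' region on its summed counts, then apply the CpG-density and
#' window-count filters. Deterministic given its input.
#'
#' @param counts_a,counts_b pooled per-condition count tables sharing a
#'   position index (A = reference, B = treated).
#' @param alpha significance level for both passes (default 0.05).
#' @param window_cpgs CpGs per window (default 3).
#' @param max_span maximum window span in bp (default 2000).
#' @param min_density minimum CpGs/kb (default 3).
#' @param min_windows minimum significant member windows (default 3).
#' @param count_mode window count mode, see [test_windows()].
#' @return data.table of DMRs (see [filter_dmrs()]).
#' @export
call_dmrs <- function(counts_a, counts_b, alpha = 0.05, window_cpgs = 3L,
                      max_span = 2000L, min_density = 3, min_windows = 3L,
                      count_mode = "mean") {
  counts <- align_condition_counts(counts_a, counts_b)
  win <- build_windows(counts, window_cpgs, max_span)
  sig <- test_windows(win, alpha, count_mode)
  cand <- merge_windows(sig, window_cpgs)
  retested <- retest_regions(cand, counts, alpha)
  filter_dmrs(retested, min_density, min_windows)
}

#' Write DMRs as BED6+ with statistics columns
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param path output path.
#' @param name name column value.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path, name = "dmr") {
  d <- data.table::as.data.table(dmrs)
  out <- d[, .(chrom, start, end, name = name,
               score = round(pmin(999, -log10(pmax(p_value, 1e-300))), 4),
               strand = ".", n_cpgs, n_windows, density = round(density, 4),
               p_value = signif(p_value, 6),
               mean_delta = round(mean_delta, 6), direction)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
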