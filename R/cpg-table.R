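#' CpG call tables
#'
#' A `cpg_table` holds per-sample CpG methylation calls: one row per CpG with
#' `chrom`, `pos` (0-based position of the C), `coverage` (total calls) and
#' `meth_calls` (methylated calls). The methylation rate ("b-value") is
#' `meth_calls / coverage` and is exposed via [cpg_rates()] rather than
#' stored. Rows are sorted by `(chrom, pos)` with no duplicate positions.
#'
#' @param data a data.frame/data.table with columns `chrom`, `pos`,
#'   `coverage`, `meth_calls`.
#' @param sample_id sample identifier.
#' @param condition condition label (e.g. `"UN"`, `"RA"`, `"TPA"`).
#' @return an object of class `cpg_table`.
#' @export
cpg_table <- function(data, sample_id, condition) {
  dt <- data.table::as.data.table(data)[, .(chrom, pos, coverage, meth_calls)]
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, coverage := as.integer(coverage)]
  dt[, meth_calls := as.integer(meth_calls)]
  if (anyNA(dt)) stopf("cpg_table: missing values in call table")
  if (any(dt$coverage < 0L) || any(dt$meth_calls < 0L))
    stopf("cpg_table: negative counts")
  bad <- which(dt$meth_calls > dt$coverage)
  if (length(bad))
    stopf("cpg_table: meth_calls > coverage at %d position(s), first at %s:%d",
          length(bad), dt$chrom[bad[1]], dt$pos[bad[1]])
  dt <- unique(dt)
  data.table::setkey(dt, chrom, pos)
  if (anyDuplicated(dt, by = c("chrom", "pos")))
    stopf("cpg_table: conflicting duplicate records for the same position")
  structure(list(sample_id = sample_id, condition = condition, data = dt),
            class = "cpg_table")
}

#' @export
print.cpg_table <- function(x, ...) {
  cat(sprintf("<cpg_table> sample %s (condition %s): %d CpGs on %d contig(s)\n",
              x$sample_id, x$condition, nrow(x$data),
              data.table::uniqueN(x$data$chrom)))
  invisible(x)
}

#' Methylation rates of a CpG table
#'
#' @param x a `cpg_table`.
#' @return numeric vector of `meth_calls / coverage`, `NA` where coverage is 0.
#' @export
cpg_rates <- function(x) {
  stopifnot(inherits(x, "cpg_table"))
  ifelse(x$data$coverage > 0L, x$data$meth_calls / x$data$coverage, NA_real_)
}

#' Read a CpG call table
#'
#' Reads the 5-column tab-separated CpG dialect: `chrom`, `pos0`, `pos1`
#' (must equal `pos0 + 1`), `coverage`, `meth_calls`; positions 0-based.
#'
#' @param path file path.
#' @param sample_id,condition labels attached to the table.
#' @return a [cpg_table()].
#' @export
read_cpg_table <- function(path, sample_id, condition) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE,
                      colClasses = list(character = 1)),
    error = function(e) stopf("parse error in %s: %s", path, conditionMessage(e)))
  if (ncol(dt) != 5L)
    stopf("parse error in %s: expected 5 tab-separated columns, found %d",
          path, ncol(dt))
  data.table::setnames(dt, c("chrom", "pos", "pos1", "coverage", "meth_calls"))
  for (col in c("pos", "pos1", "coverage", "meth_calls")) {
    v <- suppressWarnings(as.integer(dt[[col]]))
    bad <- which(is.na(v) | v != dt[[col]])
    if (length(bad))
      stopf("parse error in %s at line %d: non-integer %s", path, bad[1], col)
    data.table::set(dt, j = col, value = v)
  }
  bad <- which(dt$pos1 != dt$pos + 1L)
  if (length(bad))
    stopf("parse error in %s at line %d: end must equal start + 1", path, bad[1])
  bad <- which(dt$meth_calls > dt$coverage)
  if (length(bad))
    stopf("validation error in %s at line %d: meth_calls > coverage",
          path, bad[1])
  cpg_table(dt[, .(chrom, pos, coverage, meth_calls)], sample_id, condition)
}

#' Write a CpG call table
#'
#' Inverse of [read_cpg_table()]; round-trips losslessly.
#'
#' @param x a `cpg_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(x, path) {
  stopifnot(inherits(x, "cpg_table"))
  out <- x$data[, .(chrom, pos, pos1 = pos + 1L, coverage, meth_calls)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Export CpG methylation rates as 4-column bedGraph
#'
#' @param x a `cpg_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rates_bedgraph <- function(x, path) {
  stopifnot(inherits(x, "cpg_table"))
  out <- x$data[coverage > 0L,
                .(chrom, pos, pos1 = pos + 1L,
                  rate = meth_calls / coverage)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Combine technical replicates by summing counts
#'
#' Coverage and methylated-call counts are summed per position across
#' replicate tables of the same sample; positions absent from a replicate
#' contribute zero. Summation (rather than rate averaging) preserves the
#' binomial evidence for the downstream exact tests.
#'
#' @param tables list of `cpg_table`s sharing `sample_id` and `condition`.
#' @return a single combined `cpg_table`.
#' @export
combine_technical_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L, all(vapply(tables, inherits, TRUE, "cpg_table")))
  ids <- unique(vapply(tables, `[[`, "", "sample_id"))
  conds <- unique(vapply(tables, `[[`, "", "condition"))
  if (length(ids) != 1L || length(conds) != 1L)
    stopf("combine_technical_replicates: mixed sample_ids or conditions (%s / %s)",
          paste(ids, collapse = ","), paste(conds, collapse = ","))
  all <- data.table::rbindlist(lapply(tables, `[[`, "data"))
  comb <- all[, .(coverage = sum(coverage), meth_calls = sum(meth_calls)),
              by = .(chrom, pos)]
  cpg_table(comb, ids, conds)
}

#' Joint coverage filter across samples
#'
#' Keeps exactly the positions present in *every* table with coverage at
#' least `min_cov` in every table, so that all outputs share one identical
#' position index (the joint ">= min_cov in all sample replicates" rule).
#'
#' @param tables list of `cpg_table`s.
#' @param min_cov minimum per-sample coverage (default 10).
#' @return list of filtered `cpg_table`s with a shared position index.
#' @export
filter_by_coverage <- function(tables, min_cov = 10L) {
  stopifnot(length(tables) >= 1L, all(vapply(tables, inherits, TRUE, "cpg_table")))
  if (min_cov < 1L) stopf("min_cov must be >= 1")
  keys <- lapply(tables, function(t)
    t$data[coverage >= min_cov, .(chrom, pos)])
  shared <- Reduce(function(a, b)
    merge(a, b, by = c("chrom", "pos"), sort = TRUE), keys)
  lapply(tables, function(t) {
    sub <- t$data[shared, on = c("chrom", "pos"), nomatch = NULL]
    cpg_table(sub, t$sample_id, t$condition)
  })
}

#' Estimate bisulfite non-conversion from a control contig
#'
#' The mitochondrial genome is assumed unmethylated, so any apparent
#' methylation on it measures incomplete bisulfite conversion. Returns
#' pooled `sum(meth_calls) / sum(coverage)` over the control contig.
#'
#' @param table a `cpg_table`.
#' @param control_contig contig name (default `"chrM"`).
#' @return non-conversion rate in `[0, 1]`.
#' @export
estimate_nonconversion <- function(table, control_contig = "chrM") {
  stopifnot(inherits(table, "cpg_table"))
  ctrl <- table$data[chrom == control_contig]
  if (nrow(ctrl) == 0L || sum(ctrl$coverage) == 0L)
    stopf("no control data: contig %s absent or has zero coverage",
          control_contig)
  sum(ctrl$meth_calls) / sum(ctrl$coverage)
}

#' Drop a contig from a CpG table
#'
#' Convenience used to exclude the non-conversion control contig before
#' differential analysis.
#'
#' @param table a `cpg_table`.
#' @param contig contig name to drop.
#' @return a `cpg_table` without the contig.
#' @export
drop_contig <- function(table, contig) {
  stopifnot(inherits(table, "cpg_table"))
  cpg_table(table$data[chrom != contig], table$sample_id, table$condition)
}
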