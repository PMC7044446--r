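#' Read a BED3+name feature file
#'
#' Columns: chrom, start, end (0-based half-open) and optionally a 4th
#' column naming the feature class. All intervals are returned as a
#' [GenomicRanges::GRanges] with a `feature` metadata column; intervals may
#' overlap within a class.
#'
#' @param path BED file path.
#' @param feature_class class name used when the file has no name column.
#' @return `GRanges` with a `feature` column.
#' @export
read_features_bed <- function(path, feature_class = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3L) stopf("%s: BED needs >= 3 columns", path)
  data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
  if (any(dt$start >= dt$end)) stopf("%s: BED interval with start >= end", path)
  cls <- if (ncol(dt) >= 4L) as.character(dt[[4L]])
         else rep(feature_class %||% basename(path), nrow(dt))
  gr <- bed_to_granges(dt$chrom, dt$start, dt$end)
  S4Vectors::mcols(gr)$feature <- cls
  gr
}

#' Read gene models from BED6
#'
#' Columns: chrom, start, end, gene_id, score (ignored), strand.
#'
#' @param path BED6 file path.
#' @return `GRanges` with `gene_id` metadata and strand set.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 6L) stopf("%s: BED6 needs 6 columns", path)
  data.table::setnames(dt, 1:6,
                       c("chrom", "start", "end", "gene_id", "score", "strand"))
  if (!all(dt$strand %in% c("+", "-")))
    stopf("%s: strand must be + or -", path)
  if (any(dt$start >= dt$end)) stopf("%s: gene with start >= end", path)
  gr <- bed_to_granges(dt$chrom, dt$start, dt$end, strand = dt$strand)
  S4Vectors::mcols(gr)$gene_id <- as.character(dt$gene_id)
  gr
}

#' Read a per-condition expression table
#'
#' TSV with header: `gene_id` then one non-negative expression column per
#' condition.
#'
#' @param path TSV path.
#' @return data.table keyed by `gene_id`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"gene_id" %in% names(dt)) stopf("%s: missing gene_id column", path)
  vals <- as.matrix(dt[, !"gene_id"])
  if (any(vals < 0)) stopf("%s: negative expression values", path)
  data.table::setkey(dt, gene_id)
  dt
}

#' Read chromatin interaction pairs (BEDPE)
#'
#' First six columns: chromA, startA, endA, chromB, startB, endB
#' (0-based half-open anchors).
#'
#' @param path BEDPE path.
#' @return data.table with anchor columns and a `pair_id`.
#' @export
read_interactions_bedpe <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 6L) stopf("%s: BEDPE needs >= 6 columns", path)
  data.table::setnames(dt, 1:6, c("chromA", "startA", "endA",
                                  "chromB", "startB", "endB"))
  if (any(dt$startA >= dt$endA) || any(dt$startB >= dt$endB))
    stopf("%s: invalid anchor interval", path)
  dt[, pair_id := seq_len(.N)]
  dt[]
}

#' Read a bedGraph occupancy track
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @return data.table sorted by position.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) != 4L) stopf("%s: bedGraph needs 4 columns", path)
  data.table::setnames(dt, c("chrom", "start", "end", "value"))
  data.table::setkey(dt, chrom, start, end)
  dt[]
}
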