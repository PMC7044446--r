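#' Promoter (TSS) region of a gene
#'
#' The TSS region extends 2 kb upstream and 1 kb downstream of the gene
#' start. By default the rule is strand-aware (the biological TSS: the
#' right end of a minus-strand gene); `strand_aware = FALSE` applies the
#' literal left-coordinate rule to every gene. Regions are clipped at
#' position 0.
#'
#' @param genes `GRanges` with `gene_id` and strand (see
#'   [read_gene_models()]).
#' @param up,down bp upstream/downstream of the TSS (defaults 2000/1000).
#' @param strand_aware logical (default `TRUE`).
#' @return `GRanges` of 3 kb promoter regions with `gene_id`.
#' @export
tss_region <- function(genes, up = 2000L, down = 1000L, strand_aware = TRUE) {
  s0 <- GenomicRanges::start(genes) - 1L    # 0-based gene start
  e0 <- GenomicRanges::end(genes)           # 0-based exclusive gene end
  minus <- as.character(GenomicRanges::strand(genes)) == "-" & strand_aware
  lo <- ifelse(minus, e0 - down, s0 - up)
  hi <- ifelse(minus, e0 + up, s0 + down)
  lo <- pmax(lo, 0L)
  out <- bed_to_granges(as.character(GenomicRanges::seqnames(genes)), lo, hi)
  S4Vectors::mcols(out)$gene_id <- S4Vectors::mcols(genes)$gene_id
  out
}

#' Log2 fold change with pseudocount
#'
#' `log2((b + 1) / (a + 1))`; the pseudocount keeps zero expression finite.
#'
#' @param expr_a,expr_b non-negative expression values (reference,
#'   treated).
#' @return numeric log2 fold change(s).
#' @export
log2_fold_change <- function(expr_a, expr_b) {
  if (any(expr_a < 0) || any(expr_b < 0)) stopf("expression must be >= 0")
  log2((expr_b + 1) / (expr_a + 1))
}

#' Pearson correlation between methylation and expression profiles
#'
#' @param meth methylation rates, one per condition.
#' @param expr expression values, one per condition (paired order).
#' @return Pearson r, or `NA` when either vector has zero variance.
#' @export
correlate_meth_expr <- function(meth, expr) {
  if (length(meth) != length(expr)) stopf("length mismatch")
  if (length(meth) < 3L) stopf("need >= 3 paired conditions")
  if (stats::sd(meth) == 0 || stats::sd(expr) == 0) return(NA_real_)
  stats::cor(meth, expr, method = "pearson")
}

#' Per-condition pooled rate matrix at given positions
#'
#' Convenience for integration: pools each condition's counts and returns
#' one methylation-rate column per condition, restricted to `positions`
#' when given.
#'
#' @param tables filtered `cpg_table`s sharing a position index.
#' @param conditions condition labels to pool.
#' @param positions optional data.table (`chrom`, `pos`) to restrict to.
#' @return data.table: `chrom`, `pos`, then one `rate_<condition>` column
#'   per condition.
#' @export
condition_rate_matrix <- function(tables, conditions, positions = NULL) {
  pooled <- lapply(conditions, function(cc) pool_condition_counts(tables, cc))
  out <- pooled[[1]][, .(chrom, pos)]
  for (i in seq_along(conditions)) {
    out[, (paste0("rate_", conditions[i])) :=
          pooled[[i]]$meth_calls / pooled[[i]]$coverage]
  }
  if (!is.null(positions)) {
    key <- data.table::as.data.table(positions)[, .(chrom, pos)]
    out <- out[key, on = c("chrom", "pos"), nomatch = NULL]
  }
  out[]
}

#' Select methylation-expression candidate genes
#'
#' A candidate gene has `|log2FC| >= min_lfc` between the two conditions
#' and at least one DMP in its TSS region with `|delta| >= min_delta` that
#' also lies in a transcription-factor binding site interval (the TFBS
#' filter can be disabled explicitly). For each candidate the per-condition
#' mean methylation of its TSS DMPs is correlated with its expression
#' across all conditions.
#'
#' @param dmps DMP table with `chrom`, `pos`, `delta` and one
#'   `rate_<condition>` column per condition (see
#'   [condition_rate_matrix()]).
#' @param genes gene models (`GRanges`, see [read_gene_models()]).
#' @param expression expression table (see [read_expression_table()]).
#' @param tfbs `GRanges` of TFBS intervals, or `NULL` with
#'   `require_tfbs = FALSE`.
#' @param cond_a,cond_b reference and treated condition (fold change is
#'   `cond_b` vs `cond_a`).
#' @param conditions all condition labels used for the correlation.
#' @param min_delta minimum |rate difference| per DMP (default 0.2).
#' @param min_lfc minimum |log2 fold change| (default 1.5).
#' @param require_tfbs apply the TFBS membership filter (default `TRUE`).
#' @param up,down,strand_aware TSS region parameters, see [tss_region()].
#' @return list with `candidates` (per gene: `gene_id`, `lfc`, `n_dmps`,
#'   `mean_delta`, per-condition mean TSS methylation, `r`) and `pairs`
#'   (gene x DMP associations for scatter summaries).
#' @export
select_candidates <- function(dmps, genes, expression, tfbs,
                              cond_a, cond_b, conditions = c(cond_a, cond_b),
                              min_delta = 0.2, min_lfc = 1.5,
                              require_tfbs = TRUE,
                              up = 2000L, down = 1000L, strand_aware = TRUE) {
  d <- data.table::as.data.table(dmps)
  if (require_tfbs) {
    if (is.null(tfbs) || length(tfbs) == 0L)
      stopf("empty TFBS set; pass require_tfbs = FALSE to skip the filter")
  } else if (is.null(tfbs) || length(tfbs) == 0L) {
    warning("TFBS filter disabled", call. = FALSE)
    tfbs <- NULL
  }
  d <- d[abs(delta) >= min_delta]
  if (!is.null(tfbs) && nrow(d)) {
    inside <- GenomicRanges::countOverlaps(
      points_to_granges(d$chrom, d$pos), tfbs) > 0L
    d <- d[inside]
  }
  ex <- data.table::as.data.table(expression)
  if (!identical(data.table::key(ex), "gene_id")) data.table::setkey(ex, gene_id)
  lfc <- log2_fold_change(ex[[cond_a]], ex[[cond_b]])
  genes_keep <- genes[S4Vectors::mcols(genes)$gene_id %in%
                        ex$gene_id[abs(lfc) >= min_lfc]]
  lfc_map <- stats::setNames(lfc, ex$gene_id)
  empty <- list(
    candidates = data.table::data.table(gene_id = character(),
                                        lfc = numeric(), n_dmps = integer(),
                                        mean_delta = numeric(), r = numeric()),
    pairs = data.table::data.table(gene_id = character(), chrom = character(),
                                   pos = integer(), delta = numeric(),
                                   lfc = numeric()))
  if (nrow(d) == 0L || length(genes_keep) == 0L) return(empty)
  tss <- tss_region(genes_keep, up, down, strand_aware)
  hits <- GenomicRanges::findOverlaps(points_to_granges(d$chrom, d$pos), tss)
  if (length(hits) == 0L) return(empty)
  rate_cols <- paste0("rate_", conditions)
  pairs <- data.table::data.table(
    gene_id = S4Vectors::mcols(tss)$gene_id[S4Vectors::subjectHits(hits)],
    d[S4Vectors::queryHits(hits),
      c("chrom", "pos", "delta", rate_cols), with = FALSE])
  pairs[, lfc := lfc_map[gene_id]]
  cand <- pairs[, {
    mm <- vapply(rate_cols, function(cl) mean(.SD[[cl]]), 0)
    gid <- .BY$gene_id
    expr_vals <- as.numeric(ex[gid, conditions, with = FALSE][1L])
    c(list(lfc = lfc[1L], n_dmps = .N, mean_delta = mean(delta)),
      as.list(mm),
      list(r = correlate_meth_expr(mm, expr_vals)))
  }, by = gene_id]
  data.table::setnames(cand, rate_cols, paste0("meth_", conditions))
  list(candidates = cand[],
       pairs = pairs[, !rate_cols, with = FALSE][])
}

#' Histogram of per-gene correlation coefficients
#'
#' @param r numeric vector of Pearson correlations (may contain `NA`).
#' @param n_bins number of equal-width bins over `[-1, 1]` (default 20).
#' @return data.table with `bin_lo`, `bin_hi`, `count`; the number of
#'   missing correlations is attached as attribute `n_missing`.
#' @export
correlation_histogram <- function(r, n_bins = 20L) {
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  ok <- r[!is.na(r)]
  idx <- pmin(pmax(findInterval(ok, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- data.table::data.table(bin_lo = breaks[-length(breaks)],
                                bin_hi = breaks[-1L], count = counts)
  data.table::setattr(out, "n_missing", sum(is.na(r)))
  out[]
}

#' Link distal DMPs to genes through chromatin interaction anchors
#'
#' For every interaction pair, each DMP inside one anchor is paired with
#' every gene whose TSS region overlaps the partner anchor (both
#' orientations). Each link carries the Pearson correlation between the
#' DMP's per-condition methylation and the gene's expression, flagged when
#' `|r|` reaches the threshold.
#'
#' @param dmps DMP table with `chrom`, `pos` and `rate_<condition>`
#'   columns.
#' @param interactions interaction table (see [read_interactions_bedpe()]).
#' @param genes gene models (`GRanges`).
#' @param expression expression table.
#' @param conditions condition labels for the correlation.
#' @param r_flag |r| threshold for flagging strong links (default 0.7).
#' @param up,down,strand_aware TSS parameters.
#' @return data.table of links: `pair_id`, `chrom`, `pos`, `gene_id`, `r`,
#'   `flagged`.
#' @export
link_distal <- function(dmps, interactions, genes, expression,
                        conditions, r_flag = 0.7,
                        up = 2000L, down = 1000L, strand_aware = TRUE) {
  d <- data.table::as.data.table(dmps)
  inter <- data.table::as.data.table(interactions)
  ex <- data.table::as.data.table(expression)
  if (!identical(data.table::key(ex), "gene_id")) data.table::setkey(ex, gene_id)
  rate_cols <- paste0("rate_", conditions)
  tss <- tss_region(genes, up, down, strand_aware)
  empty <- data.table::data.table(pair_id = integer(), chrom = character(),
                                  pos = integer(), gene_id = character(),
                                  r = numeric(), flagged = logical())
  if (nrow(d) == 0L || nrow(inter) == 0L) return(empty)
  dmp_gr <- points_to_granges(d$chrom, d$pos)
  anchors <- list(
    A = bed_to_granges(inter$chromA, inter$startA, inter$endA),
    B = bed_to_granges(inter$chromB, inter$startB, inter$endB))
  links <- list()
  for (side in c("A", "B")) {
    near <- anchors[[side]]
    far <- anchors[[setdiff(c("A", "B"), side)]]
    dmp_hits <- GenomicRanges::findOverlaps(dmp_gr, near)
    tss_hits <- GenomicRanges::findOverlaps(tss, far)
    if (length(dmp_hits) == 0L || length(tss_hits) == 0L) next
    dh <- data.table::data.table(dmp = S4Vectors::queryHits(dmp_hits),
                                 pair = S4Vectors::subjectHits(dmp_hits))
    th <- data.table::data.table(gene = S4Vectors::queryHits(tss_hits),
                                 pair = S4Vectors::subjectHits(tss_hits))
    joined <- merge(dh, th, by = "pair", allow.cartesian = TRUE)
    if (nrow(joined) == 0L) next
    links[[side]] <- joined[, .(
      pair_id = inter$pair_id[pair],
      chrom = d$chrom[dmp], pos = d$pos[dmp],
      gene_id = S4Vectors::mcols(tss)$gene_id[gene],
      dmp_row = dmp)]
  }
  out <- data.table::rbindlist(links)
  if (nrow(out) == 0L) return(empty)
  out <- unique(out, by = c("pair_id", "chrom", "pos", "gene_id"))
  out[, r := {
    meth <- as.numeric(d[dmp_row[1L], rate_cols, with = FALSE][1L])
    gid <- .BY$gene_id
    expr_vals <- as.numeric(ex[gid, conditions, with = FALSE][1L])
    correlate_meth_expr(meth, expr_vals)
  }, by = .(pair_id, chrom, pos, gene_id)]
  out[, flagged := !is.na(r) & abs(r) >= r_flag]
  out[, dmp_row := NULL]
  out[]
}
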