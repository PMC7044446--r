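#' Count points falling in a feature class
#'
#' Number of 0-based point positions lying inside at least one half-open
#' `[start, end)` interval of the feature set; each point counts once even
#' under overlapping intervals.
#'
#' @param points data.frame/data.table with `chrom`, `pos` (0-based).
#' @param features `GRanges` of the feature class (see
#'   [read_features_bed()]).
#' @return integer count.
#' @export
overlap_count <- function(points, features) {
  p <- data.table::as.data.table(points)
  if (nrow(p) == 0L) return(0L)
  gr <- points_to_granges(p$chrom, p$pos)
  sum(GenomicRanges::countOverlaps(gr, features) > 0L)
}

#' Fold enrichment of a DMP subset in a genomic feature class
#'
#' Observed fraction over expected fraction:
#' `(subset DMPs inside feature / data_size) / (feature bp / genome bp)`.
#' `data_size` is the *total* number of DMPs of the comparison, not the
#' size of the hyper- or hypo-only subset. Overlapping intervals within the
#' class are collapsed before computing covered bp. With
#' `background = "cpg"` the expectation is instead count-based: the
#' fraction of supplied background CpGs inside the feature.
#'
#' @param dmps DMP subset (`chrom`, `pos`), e.g. hypermethylated DMPs of
#'   one comparison.
#' @param data_size total number of DMPs in the comparison.
#' @param features `GRanges` of one feature class.
#' @param genome_size total genome length in bp.
#' @param background `"bp"` (default) or `"cpg"`.
#' @param background_cpgs background CpG positions (required for
#'   `background = "cpg"`).
#' @return one-row data.table: `observed`, `data_size`, `expected`
#'   (fraction), `ratio`, `log2_ratio` (`NA` when ratio is 0).
#' @export
dmp_feature_enrichment <- function(dmps, data_size, features, genome_size,
                                   background = c("bp", "cpg"),
                                   background_cpgs = NULL) {
  background <- match.arg(background)
  if (data_size <= 0) stopf("data_size must be positive")
  observed <- overlap_count(dmps, features)
  if (background == "bp") {
    if (genome_size <= 0) stopf("genome_size must be positive")
    covered <- sum(GenomicRanges::width(GenomicRanges::reduce(features)))
    if (covered == 0) stopf("feature covers 0 bp")
    expected <- covered / genome_size
  } else {
    if (is.null(background_cpgs)) stopf("background_cpgs required")
    n_bg <- nrow(data.table::as.data.table(background_cpgs))
    if (n_bg == 0L) stopf("empty background CpG set")
    expected <- overlap_count(background_cpgs, features) / n_bg
    if (expected == 0) stopf("no background CpGs in feature")
  }
  ratio <- (observed / data_size) / expected
  data.table::data.table(
    observed = observed, data_size = data_size, expected = expected,
    ratio = ratio, log2_ratio = ifelse(ratio > 0, log2(ratio), NA_real_))
}

#' Module-by-feature fold enrichment
#'
#' For module m and feature f, with sizes measured in DMP counts:
#' `enrichment(m, f) = (mod_feature / feature_size) / (module_size /
#' total_modules)` where `mod_feature` is the number of module-m DMPs
#' inside f, `feature_size` the number of DMPs of any module inside f,
#' `module_size` the DMPs in m and `total_modules` all DMPs. The
#' module-size-weighted mean enrichment over modules is 1 for every
#' feature by construction.
#'
#' @param positions DMP positions (`chrom`, `pos`), one row per clustered
#'   DMP, in the clustering row order.
#' @param labels module labels from [cluster_dmps()].
#' @param features `GRanges` with a `feature` metadata column (one or more
#'   classes).
#' @return data.table with one row per (module, feature): `mod_feature`,
#'   `feature_size`, `module_size`, `total_modules`, `ratio`,
#'   `log2_ratio`. Features containing no DMPs yield `NA` ratios.
#' @export
module_feature_enrichment <- function(positions, labels, features) {
  p <- data.table::as.data.table(positions)
  if (nrow(p) != length(labels))
    stopf("positions and labels must have equal length")
  classes <- unique(S4Vectors::mcols(features)$feature)
  total <- nrow(p)
  mods <- sort(unique(labels))
  gr <- points_to_granges(p$chrom, p$pos)
  out <- list()
  for (f in classes) {
    fgr <- features[S4Vectors::mcols(features)$feature == f]
    inside <- GenomicRanges::countOverlaps(gr, fgr) > 0L
    feature_size <- sum(inside)
    for (m in mods) {
      mod_feature <- sum(inside & labels == m)
      module_size <- sum(labels == m)
      ratio <- if (feature_size > 0L)
        (mod_feature / feature_size) / (module_size / total) else NA_real_
      out[[length(out) + 1L]] <- data.table::data.table(
        module = m, feature = f, mod_feature = mod_feature,
        feature_size = feature_size, module_size = module_size,
        total_modules = total, ratio = ratio,
        log2_ratio = ifelse(!is.na(ratio) && ratio > 0, log2(ratio),
                            NA_real_))
    }
  }
  data.table::rbindlist(out)[]
}
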