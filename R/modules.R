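#' Cluster DMPs into methylation modules
#'
#' Hierarchical (agglomerative) clustering of per-DMP methylation profiles
#' with complete linkage on Euclidean distances, cut into exactly `k`
#' groups. Input profiles are the per-condition pooled methylation rates
#' (one column per cell state). Module labels `1..k` are assigned in order
#' of first appearance in the input, so the result is deterministic for a
#' fixed row order and invariant, up to label renaming, under permutation.
#'
#' @param rate_profiles numeric matrix, DMPs x conditions, no missing
#'   values.
#' @param k number of modules (default 12).
#' @param max_n guard on the O(n^2) distance matrix (default 100000);
#'   subsample above this.
#' @return list with `labels` (integer vector, 1..k), `k`, and `means`
#'   (k x conditions matrix of per-module mean rates).
#' @export
cluster_dmps <- function(rate_profiles, k = 12L, max_n = 100000L) {
  x <- as.matrix(rate_profiles)
  n <- nrow(x)
  if (anyNA(x)) stopf("missing rates in profiles")
  if (n < k) stopf("fewer DMPs (%d) than modules (%d)", n, k)
  if (n > max_n)
    stopf("%d DMPs exceed the guard of %d; subsample before clustering", n, max_n)
  if (k == 1L) {
    raw <- rep(1L, n)
  } else {
    hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                        method = "complete")
    raw <- stats::cutree(hc, k = k)
  }
  labels <- match(raw, unique(raw))        # relabel by first appearance
  means <- vapply(seq_len(k), function(m)
    colMeans(x[labels == m, , drop = FALSE]), numeric(ncol(x)))
  means <- t(means)
  rownames(means) <- paste0("M", seq_len(k))
  colnames(means) <- colnames(x)
  list(labels = labels, k = as.integer(k), means = means)
}

#' Summarise modules: sizes and per-condition mean rates
#'
#' @param assignment result of [cluster_dmps()].
#' @param rate_profiles the profile matrix that was clustered.
#' @return data.table with `module`, `size` and one mean-rate column per
#'   condition.
#' @export
summarize_modules <- function(assignment, rate_profiles) {
  x <- as.matrix(rate_profiles)
  labels <- assignment$labels
  if (length(labels) != nrow(x))
    stopf("assignment does not cover the profile rows")
  dt <- data.table::as.data.table(x)
  dt[, module := labels]
  out <- dt[, c(.(size = .N), lapply(.SD, mean)), by = module]
  data.table::setorder(out, module)
  out[]
}

#' Average occupancy profile around anchor CpGs
#'
#' For each offset in `[-flank, +flank]` relative to the anchor positions,
#' the mean of the occupancy track value at `anchor + offset` over all
#' anchors. Positions not covered by the track count as 0 occupancy.
#'
#' @param track occupancy track, data.table of (`chrom`, `start`, `end`,
#'   `value`) with 0-based half-open intervals (see [read_bedgraph()]).
#' @param anchors data.frame/data.table of anchor CpGs (`chrom`, `pos`).
#' @param flank half-width of the profile in bp (default 1000).
#' @return data.table with `offset` (-flank..flank) and `mean` occupancy;
#'   the number of anchors is attached as attribute `n_anchors`.
#' @export
occupancy_profile <- function(track, anchors, flank = 1000L) {
  a <- data.table::as.data.table(anchors)
  if (nrow(a) == 0L) stopf("no anchors")
  tr <- data.table::as.data.table(track)
  offsets <- seq.int(-flank, flank)
  acc <- numeric(length(offsets))
  for (i in seq_len(nrow(a))) {
    lo <- a$pos[i] - flank
    sub <- tr[chrom == a$chrom[i] & end > lo & start <= a$pos[i] + flank]
    v <- numeric(length(offsets))         # default 0 where uncovered
    if (nrow(sub)) {
      for (j in seq_len(nrow(sub))) {
        i0 <- max(sub$start[j], lo) - lo + 1L
        i1 <- min(sub$end[j] - 1L, a$pos[i] + flank) - lo + 1L
        if (i1 >= i0) v[i0:i1] <- sub$value[j]
      }
    }
    acc <- acc + v
  }
  out <- data.table::data.table(offset = offsets, mean = acc / nrow(a))
  data.table::setattr(out, "n_anchors", nrow(a))
  out[]
}

#' Per-module occupancy profiles for several condition tracks
#'
#' @param tracks named list of occupancy tracks (one per condition).
#' @param anchors anchors as in [occupancy_profile()].
#' @param flank half-width in bp.
#' @return data.table with `offset` and one mean column per condition.
#' @export
occupancy_profiles <- function(tracks, anchors, flank = 1000L) {
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  nms <- names(tracks) %||% paste0("track", seq_along(tracks))
  profs <- lapply(tracks, occupancy_profile, anchors = anchors, flank = flank)
  out <- data.table::data.table(offset = profs[[1]]$offset)
  for (i in seq_along(profs)) out[, (nms[i]) := profs[[i]]$mean]
  out[]
}
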