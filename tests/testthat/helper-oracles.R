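# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the Fisher oracle enumerates the hypergeometric pmf
# from lchoose() (the implementation uses dhyper), and the brute-force
# oracles are plain double loops.

# two-sided Fisher exact p by full enumeration of [[a,b],[c,d]] tables
enum_fisher_oracle <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; K <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || K == 0 || K == N) return(1)
  supp <- max(0, K - r2):min(K, r1)
  pmf <- exp(lchoose(r1, supp) + lchoose(r2, K - supp) - lchoose(N, K))
  pobs <- pmf[match(a, supp)]
  min(1, sum(pmf[pmf <= pobs * (1 + rel_tol)]))
}

# brute-force joint coverage filter: set intersection + recount
brute_filter_oracle <- function(tables, min_cov) {
  keys <- lapply(tables, function(t) {
    d <- t$data
    paste(d$chrom, d$pos)[d$coverage >= min_cov]
  })
  shared <- Reduce(intersect, keys)
  lapply(tables, function(t) {
    d <- t$data
    d[paste(d$chrom, d$pos) %in% shared]
  })
}

# brute-force per-offset profile mean
brute_profile_oracle <- function(track, anchors, flank) {
  offsets <- -flank:flank
  out <- numeric(length(offsets))
  for (oi in seq_along(offsets)) {
    vals <- numeric(nrow(anchors))
    for (ai in seq_len(nrow(anchors))) {
      p <- anchors$pos[ai] + offsets[oi]
      v <- 0
      for (ti in seq_len(nrow(track))) {
        if (track$chrom[ti] == anchors$chrom[ai] &&
            p >= track$start[ti] && p < track$end[ti]) {
          v <- track$value[ti]
          break
        }
      }
      vals[ai] <- v
    }
    out[oi] <- mean(vals)
  }
  out
}

# brute-force point-in-intervals membership count
brute_overlap_oracle <- function(points, intervals) {
  n <- 0L
  for (i in seq_len(nrow(points))) {
    inside <- FALSE
    for (j in seq_len(nrow(intervals))) {
      if (points$chrom[i] == intervals$chrom[j] &&
          points$pos[i] >= intervals$start[j] &&
          points$pos[i] < intervals$end[j]) inside <- TRUE
    }
    n <- n + inside
  }
  n
}

# small random cpg_table on a shared set of positions
random_cpg_table <- function(sample_id, condition, positions,
                             max_cov = 40L) {
  cov <- sample.int(max_cov, length(positions), replace = TRUE)
  meth <- rbinom(length(positions), cov, runif(length(positions)))
  cpg_table(data.frame(chrom = "chr1", pos = positions, coverage = cov,
                       meth_calls = meth), sample_id, condition)
}

# pooled count table from explicit vectors (shared chrom)
make_counts <- function(pos, coverage, meth, chrom = "chr1") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         coverage = as.integer(coverage),
                         meth_calls = as.integer(meth))
}

# interval overlap between two region tables (any bp shared)
regions_overlap <- function(a, b) {
  hits <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    hits[i] <- any(a$chrom[i] == b$chrom &
                     a$start[i] < b$end & b$start < a$end[i])
  }
  hits
}
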