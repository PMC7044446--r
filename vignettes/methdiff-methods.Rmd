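---
title: "methdiff: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methdiff: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdiff)
```

This vignette is the package's own account of its statistical model, its
tunable parameters, what the synthetic-data generator does and does not
emulate, and the choices we made where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The data model

The unit of data is a per-sample CpG call table: one row per CpG with a
contig, a 0-based position of the C, a total read-call count (`coverage`)
and a methylated-call count (`meth_calls`). The methylation rate
("b-value") is the ratio of the two and is only defined at covered
positions. All genomic coordinates in the package — call tables, BED
features, gene models, interaction anchors, bedGraph tracks — are 0-based
half-open, so the package's files interoperate with BED tooling directly.

Two assumptions run through everything downstream:

* **Binomial sampling.** Given a true per-CpG methylation level, the
  methylated-call count is binomial in the coverage. This is what makes
  pooling counts across technical replicates (summation, never rate
  averaging) the evidence-preserving operation, and it is the sampling
  model under which the Fisher exact test is exact.
* **Joint observability.** Only CpGs with coverage at least `min_cov`
  (default 10) in *every* sample are analysed; positions missing or
  shallow anywhere are dropped, not imputed. All stage inputs therefore
  share one position index.

Bisulfite non-conversion is estimated from the mitochondrial contig
(assumed unmethylated, so apparent chrM methylation = non-conversion) and
the contig is excluded from differential analysis. The estimate is
reported, not used as a correction — consistent with the descriptive role
it plays in this kind of study.

## DMP calling

Per comparison (reference condition A, treated condition B), counts are
pooled within condition and each CpG yields one 2×2 table. The two-sided
Fisher p-value is the sum of hypergeometric probabilities of all tables
with the observed margins whose probability does not exceed the observed
table's, with a relative tolerance of 1e-7 on the comparison to absorb
floating-point ties — the same convention as `stats::fisher.test`, but
vectorised. `alpha` defaults to 0.05 with **no multiple-testing
correction**, which is deliberately anti-conservative at the genome scale;
a Benjamini–Hochberg mode is available (`p_adjust = "BH"`) but off by
default because the raw-α behaviour is the procedure this package
implements. Δ is treated-minus-reference, so "hyper" always means more
methylated after treatment.

Whether the underlying study pooled replicates or tested a single
replicate pair per comparison is not recoverable; we pool, because
pooling is the only choice consistent with the binomial-evidence model
above, and we document it here rather than asserting it as the original
intent.

## The sliding-window DMR procedure

Five deterministic steps, in order:

1. **Windows.** One window per run of 3 consecutive CpGs on a chromosome
   (step one CpG, so windows overlap and 3 consecutive windows span
   exactly 5 CpGs). Windows wider than 2 kb are skipped. Each window
   carries per-condition *mean* coverage and mean methylated-call counts.
2. **First test.** The mean counts are rounded to integers and Fisher-
   tested at `alpha`; the window direction is the sign of the averaged
   rate difference.
3. **Merge.** Runs of significant windows with *adjacent* start indices
   and a common direction merge into a candidate region; a non-significant
   window or a direction flip breaks the run. (Windows two steps apart
   still share one CpG, but merging across an intervening non-significant
   window would contradict the continuity requirement, so adjacency is
   the rule.)
4. **Second test.** Each region's member-CpG counts are summed per
   condition and re-tested; regions failing `alpha` are dropped and the
   second-pass p is the region's p-value.
5. **Filters.** Regions need ≥ 3 CpGs per kb of span (span = last CpG −
   first CpG + 1) and ≥ 3 first-pass significant member windows
   (equivalently ≥ 5 CpGs).

Numerical choices the procedure text leaves open, fixed here: fractional
mean counts are rounded **half away from zero** (R's `round()` is
half-to-even, which would turn 26.5 into 26); a summed-counts window mode
(`count_mode = "sum"`) is provided as an alternative to mean-and-round;
`n_windows` counts *first-pass* significant member windows, since the
final filter speaks of the windows a region was made of; a zero-span
region would have infinite density but cannot reach 3 windows, so it is
removed by the window filter rather than special-cased.

## Modules and occupancy profiles

DMP profiles are the per-condition pooled rates (3 columns for a 3-state
design) — not per-replicate columns, matching the three-state heatmap
view of the analysis; clustering is `hclust` complete linkage on
Euclidean distances, `cutree` at k = 12. k = 12 is the canonical setting
of the emulated analysis, not an optimum the package estimates. Cluster
labels are renumbered by first appearance in the input, making results
deterministic for a fixed row order and invariant, up to renaming, under
permutation. An O(n²) guard (default 100,000 rows) fails loudly rather
than exhausting memory.

Occupancy profiles average a bedGraph track at every offset in ±`flank`
(default 1000) bp around each anchor CpG (the 0-based C position);
positions uncovered by the track count as occupancy 0, which biases means
downward at track gaps rather than silently dropping anchors.

## Enrichment

The enrichment formulas of the emulated analysis survive only as variable
definitions, so the package documents its reconstruction and computes pure
ratios with no significance test:

* DMP-set enrichment = (subset DMPs in feature / `data_size`) ÷ (feature
  bp / genome bp), where `data_size` is the total DMP count of the
  comparison — explicitly *not* the hyper- or hypo-only count. The mixed
  units (point counts vs covered bp) follow the definitions; a fully
  count-based background mode (`background = "cpg"`) is provided for users
  who prefer all-tested-CpGs as the expectation.
* Module enrichment = (`mod_feature`/`feature_size`) ÷
  (`module_size`/`total_modules`) with all four sizes in DMP counts. Two
  identities follow and are asserted in the tests: per-feature module
  overlaps sum to `feature_size`, and the module-size-weighted mean
  enrichment is exactly 1.

## Expression integration

The TSS region is −2 kb/+1 kb around the gene start. The emulated
procedure says "start of the gene" without mentioning strand; the package
is strand-aware by default (the biological TSS of a minus-strand gene is
its right coordinate) and offers `strand_aware = FALSE` to reproduce the
literal left-coordinate reading. Neither is asserted as the original
computation.

Candidates require |log2FC| ≥ 1.5 (pseudocount 1 inside the fold change,
because zero expression is legal and the emulated analysis is silent on
it) and ≥ 1 TSS DMP with |Δ| ≥ 0.2 inside a TFBS interval; the TFBS
filter can only be skipped explicitly, and "upstream TF binding region"
is operationalised as TSS-region ∩ TFBS. Correlations are Pearson r over
the condition profile — with only 3 conditions this is a descriptive
statistic, not an inferential one (r over 3 points takes values ±1 easily);
it is honoured because it is the emulated procedure, and the weakness is
flagged here rather than silently "fixed". Distal links pair every DMP in
one interaction anchor with every gene whose TSS region overlaps the
partner anchor, in both orientations, flagging |r| ≥ 0.7.

## What the generator emulates — and what it does not

The synthetic world is fixed by `sim_config()` defaults: three conditions
(UN/RA/TPA) × three technical replicates; negative-binomial coverage with
mean 30 and size 8 (so the joint 10× filter actually bites — about 13% of
CpGs fail it somewhere across nine tables, giving the filter realistic
work); a bimodal background rate mixture (70% high mode Beta(18,2), 20%
low mode Beta(1.5,28), 10% partial Beta(2,2)) shared across conditions;
binomial methylated counts by default, because the Fisher test assumes
binomial sampling and the default world tests the procedure under its own
model (a beta-binomial mode, `rate_overdispersion > 0`, is available to
probe replicate-level overdispersion); planted DMR blocks that
shift the treated condition by Δ (default 0.3) over 7–15 CpGs; a chrM
contig at a constant 0.005 non-conversion rate; occupancy baseline 1.0
with 0.5-deep dips of ±50 bp at hypomethylated planted CpGs in the
TPA-like state.

Planted blocks are generated as **CpG-dense clusters** (consecutive block
CpGs 50–150 bp apart) rather than runs of background-spaced CpGs. At the
test scale (2000 CpGs over 500 kb) background spacing averages 250 bp, so
background-spaced "blocks" frequently fail the procedure's own ≥ 3
CpGs/kb rule — they are not DMRs under the method's definition. Dense
placement matches where such regions occur in real methylomes (CpG
islands, enhancers). This was decided while constructing the generator,
not tuned against test outcomes.

What a green test therefore establishes: the procedure recovers planted
binomial-sampled signal of the stated effect size at the stated depth,
controls its type-I rate under its own sampling model, and satisfies its
structural invariants. What it does not establish: behaviour under
biological replicate overdispersion (the emulated design had technical
replicates only), under beta-binomial noise, under non-conversion bias
beyond chrM, or on genome-scale data volumes.

## Determinism and degenerate inputs

Every generator seeds the RNG from `config$seed` (plus a fixed offset per
generator), so a fixed configuration is byte-reproducible, file outputs
included; the pipeline itself uses no randomness. Degenerate inputs have
defined behaviour: zero-coverage CpGs have undefined (NA) rates and are
excluded by filtering; Fisher tables with an empty margin return p = 1;
zero-variance vectors yield missing correlations; a clustering input with
fewer rows than k, an empty anchor set, an absent control contig and a
zero-bp feature class all raise named errors rather than guessing.

## Known limitations

* Raw α = 0.05 per CpG is kept for fidelity; at genome scale users should
  enable the BH mode and understand they are then running a variant.
* The window procedure's rounding, merge and window-count conventions are
  one defensible reading of an underspecified recipe; alternatives
  (sum-mode windows, CpG-sharing merges) would change region boundaries
  at the margins.
* Enrichment ratios carry no uncertainty; do not read them as tests.
* Pearson r over three conditions is descriptive only.
* The O(n²) clustering guard means genome-scale module analysis requires
  subsampling DMPs.
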