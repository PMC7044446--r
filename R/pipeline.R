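#' Pipeline configuration
#'
#' Collects input file paths, the condition/replicate mapping and every
#' stage parameter. Defaults are the analysis' canonical settings: joint
#' coverage >= 10x, Fisher alpha 0.05, 3-CpG / 2 kb windows, >= 3 CpGs/kb
#' and >= 3 windows per DMR, 12 modules, candidate thresholds
#' |delta| >= 0.2 and |log2FC| >= 1.5, +/-1 kb occupancy flank,
#' correlation flag 0.7.
#'
#' @param samples data.frame with columns `path`, `sample_id`, `condition`.
#' @param outdir output directory for stage results.
#' @param comparisons list of `c(reference, treated)` condition pairs;
#'   default all pairwise in the order (RA vs UN, TPA vs UN, RA vs TPA)
#'   when the conditions are UN/RA/TPA, otherwise all pairs.
#' @param features,tfbs,genes,expression,interactions optional input file
#'   paths (BED3+name, BED, BED6, TSV, BEDPE).
#' @param occupancy optional named list of bedGraph paths (per condition).
#' @param integrate run the expression-integration stage (requires `genes`
#'   and `expression`).
#' @param genome_size genome size in bp for bp-background enrichment.
#' @param min_cov,alpha,window_cpgs,max_span,min_density,min_windows,k
#'   stage parameters (see the stage functions).
#' @param min_delta,min_lfc,flank,cor_threshold integration/profile
#'   parameters.
#' @param control_contig non-conversion control contig (dropped before
#'   differential analysis).
#' @param seed seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(samples, outdir,
                            comparisons = NULL,
                            features = NULL, tfbs = NULL, genes = NULL,
                            expression = NULL, interactions = NULL,
                            occupancy = NULL, integrate = !is.null(expression),
                            genome_size = NULL,
                            min_cov = 10L, alpha = 0.05, window_cpgs = 3L,
                            max_span = 2000L, min_density = 3,
                            min_windows = 3L, k = 12L, min_delta = 0.2,
                            min_lfc = 1.5, flank = 1000L,
                            cor_threshold = 0.7, control_contig = "chrM",
                            seed = 1L) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("path", "sample_id", "condition") %in% names(samples)))
  conds <- unique(samples$condition)
  if (is.null(comparisons)) {
    comparisons <- if (setequal(conds, c("UN", "RA", "TPA")))
      list(c("UN", "RA"), c("UN", "TPA"), c("TPA", "RA"))
    else if (length(conds) >= 2L) utils::combn(conds, 2, simplify = FALSE)
    else list()
  }
  if (integrate && (is.null(genes) || is.null(expression)))
    stopf("configuration error: integration enabled but no %s configured",
          if (is.null(expression)) "expression table" else "gene models")
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a simulation manifest
#'
#' @param dir directory written by [write_simulation()].
#' @param outdir output directory.
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_manifest <- function(dir, outdir, ...) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  samples <- data.table::rbindlist(lapply(man$samples, function(s)
    data.table::data.table(path = file.path(dir, s$path),
                           sample_id = s$sample_id,
                           condition = s$condition)))
  occ <- lapply(man$occupancy, function(p) file.path(dir, p))
  pipeline_config(
    samples = samples, outdir = outdir,
    features = file.path(dir, man$features),
    genes = file.path(dir, man$genes),
    expression = file.path(dir, man$expression),
    interactions = file.path(dir, man$interactions),
    occupancy = occ, seed = man$seed, ...)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Run the full differential-methylation pipeline
#'
#' Stage order: read and validate inputs, estimate non-conversion, joint
#' coverage filter, per-comparison DMP calling, DMP union, DMR calling,
#' module clustering, feature enrichment, expression integration, distal
#' linking, occupancy profiles and sample PCA. Every stage's output is
#' written as TSV/BED under `config$outdir` before the next stage runs;
#' re-running with an identical configuration reproduces byte-identical
#' outputs. The machine-readable run log (`run_log.json`) records every
#' effective parameter and per-stage result sizes.
#'
#' @param config a [pipeline_config()].
#' @return list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list(parameters = config[!(names(config) %in%
                                      c("samples", "outdir"))],
              samples = config$samples, stages = list())
  log$parameters$comparisons <- lapply(config$comparisons, paste,
                                       collapse = "_vs_")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  tables <- stage("read", {
    lapply(seq_len(nrow(config$samples)), function(i)
      read_cpg_table(config$samples$path[i], config$samples$sample_id[i],
                     config$samples$condition[i]))
  })

  nonconv <- stage("nonconversion", {
    data.table::data.table(
      sample_id = vapply(tables, `[[`, "", "sample_id"),
      condition = vapply(tables, `[[`, "", "condition"),
      nonconversion = vapply(tables, function(t)
        tryCatch(estimate_nonconversion(t, config$control_contig),
                 error = function(e) NA_real_), 0))
  })
  write_tsv(nonconv, file.path(config$outdir, "nonconversion.tsv"))
  tables <- lapply(tables, drop_contig, contig = config$control_contig)

  filtered <- stage("filter", filter_by_coverage(tables, config$min_cov))
  log$stages$filter <- list(n_cpgs = nrow(filtered[[1]]$data))

  conds <- unique(config$samples$condition)
  pooled <- stage("pool", {
    stats::setNames(lapply(conds, function(cc)
      pool_condition_counts(filtered, cc)), conds)
  })

  dmp_sets <- list()
  dmr_sets <- list()
  for (cmp in config$comparisons) {
    nm <- paste(cmp[2], "vs", cmp[1], sep = "_")
    dmps <- stage(paste0("dmp_", nm),
                  fisher_dmp(pooled[[cmp[1]]], pooled[[cmp[2]]],
                             alpha = config$alpha))
    write_dmp_bed(dmps, file.path(config$outdir, paste0("dmp_", nm, ".bed")),
                  name = nm)
    dmp_sets[[nm]] <- dmps
    dmrs <- stage(paste0("dmr_", nm),
                  call_dmrs(pooled[[cmp[1]]], pooled[[cmp[2]]],
                            alpha = config$alpha,
                            window_cpgs = config$window_cpgs,
                            max_span = config$max_span,
                            min_density = config$min_density,
                            min_windows = config$min_windows))
    write_dmr_bed(dmrs, file.path(config$outdir, paste0("dmr_", nm, ".bed")),
                  name = nm)
    dmr_sets[[nm]] <- dmrs
    log$stages[[paste0("dmp_", nm)]] <- list(n_dmps = nrow(dmps),
                                             n_tested = attr(dmps, "n_tested"))
    log$stages[[paste0("dmr_", nm)]] <- list(n_dmrs = nrow(dmrs))
  }

  union <- stage("union", union_dmps(dmp_sets))
  write_tsv(union, file.path(config$outdir, "dmp_union.tsv"))
  log$stages$union <- list(n_unique_dmps = nrow(union))

  rates <- stage("rates", condition_rate_matrix(filtered, conds, union))
  assignment <- NULL
  if (nrow(union) >= config$k) {
    prof <- as.matrix(rates[, paste0("rate_", conds), with = FALSE])
    colnames(prof) <- conds
    assignment <- stage("modules", cluster_dmps(prof, k = config$k))
    mod_tab <- data.table::data.table(rates[, .(chrom, pos)],
                                      module = assignment$labels,
                                      rates[, paste0("rate_", conds),
                                            with = FALSE])
    write_tsv(mod_tab, file.path(config$outdir, "modules.tsv"))
    write_tsv(summarize_modules(assignment, prof),
              file.path(config$outdir, "module_summary.tsv"))
    log$stages$modules <- list(k = config$k,
                               sizes = as.integer(table(assignment$labels)))
  }

  features <- NULL
  if (!is.null(config$features)) {
    features <- stage("features", read_features_bed(config$features))
    genome_size <- config$genome_size %||%
      sum(vapply(split(GenomicRanges::end(features),
                       as.character(GenomicRanges::seqnames(features))),
                 max, 0))
    enr <- list()
    for (nm in names(dmp_sets)) {
      d <- dmp_sets[[nm]]
      for (dir_i in c("hyper", "hypo")) {
        sub <- d[direction == dir_i]
        for (f in unique(S4Vectors::mcols(features)$feature)) {
          fgr <- features[S4Vectors::mcols(features)$feature == f]
          e <- tryCatch(
            dmp_feature_enrichment(sub, nrow(d), fgr, genome_size),
            error = function(e) NULL)
          if (!is.null(e))
            enr[[length(enr) + 1L]] <- data.table::data.table(
              comparison = nm, subset = dir_i, feature = f, e)
        }
      }
    }
    if (length(enr))
      write_tsv(data.table::rbindlist(enr),
                file.path(config$outdir, "enrichment_dmp.tsv"))
    if (!is.null(assignment)) {
      menr <- stage("module_enrichment",
                    module_feature_enrichment(rates[, .(chrom, pos)],
                                              assignment$labels, features))
      write_tsv(menr, file.path(config$outdir, "enrichment_modules.tsv"))
    }
  }

  if (config$integrate) {
    genes <- stage("genes", read_gene_models(config$genes))
    expr <- stage("expression", read_expression_table(config$expression))
    tfbs <- if (!is.null(config$tfbs)) read_features_bed(config$tfbs)
            else NULL
    all_r <- c()
    for (cmp in config$comparisons) {
      nm <- paste(cmp[2], "vs", cmp[1], sep = "_")
      d <- dmp_sets[[nm]]
      dm <- condition_rate_matrix(filtered, conds, d)[
        d[, .(chrom, pos, delta)], on = c("chrom", "pos")]
      sel <- stage(paste0("candidates_", nm),
                   select_candidates(dm, genes, expr, tfbs,
                                     cond_a = cmp[1], cond_b = cmp[2],
                                     conditions = conds,
                                     min_delta = config$min_delta,
                                     min_lfc = config$min_lfc,
                                     require_tfbs = !is.null(tfbs)))
      write_tsv(sel$candidates,
                file.path(config$outdir, paste0("candidates_", nm, ".tsv")))
      write_tsv(sel$pairs,
                file.path(config$outdir, paste0("candidate_pairs_", nm,
                                                ".tsv")))
      all_r <- c(all_r, sel$candidates$r)
      log$stages[[paste0("candidates_", nm)]] <-
        list(n_genes = nrow(sel$candidates))
    }
    hist_tab <- correlation_histogram(all_r)
    write_tsv(hist_tab, file.path(config$outdir,
                                  "correlation_histogram.tsv"))
    if (!is.null(config$interactions)) {
      inter <- stage("interactions",
                     read_interactions_bedpe(config$interactions))
      dm_all <- condition_rate_matrix(filtered, conds, union)
      links <- stage("links",
                     link_distal(dm_all, inter, genes, expr, conds,
                                 r_flag = config$cor_threshold))
      write_tsv(links, file.path(config$outdir, "links.tsv"))
      log$stages$links <- list(n_links = nrow(links),
                               n_flagged = sum(links$flagged))
    }
  }

  if (!is.null(config$occupancy) && !is.null(assignment)) {
    tracks <- stage("occupancy_read",
                    lapply(config$occupancy, read_bedgraph))
    profs <- list()
    for (m in seq_len(config$k)) {
      anchors <- rates[assignment$labels == m, .(chrom, pos)]
      if (nrow(anchors) == 0L) next
      pr <- stage(paste0("profile_M", m),
                  occupancy_profiles(tracks, anchors, config$flank))
      pr[, module := m]
      profs[[length(profs) + 1L]] <- pr
    }
    if (length(profs))
      write_tsv(data.table::rbindlist(profs),
                file.path(config$outdir, "occupancy_profiles.tsv"))
  }

  full_rates <- as.matrix(
    data.table::as.data.table(
      lapply(filtered, function(t) cpg_rates(t))))
  colnames(full_rates) <- vapply(filtered, `[[`, "", "sample_id")
  pca <- stage("pca", methylation_pca(full_rates))
  pca_tab <- data.table::data.table(sample_id = rownames(pca$scores),
                                    pca$scores)
  write_tsv(pca_tab, file.path(config$outdir, "pca_scores.tsv"))
  write_tsv(data.table::data.table(
    component = seq_along(pca$explained),
    explained = pca$explained),
    file.path(config$outdir, "pca_explained.tsv"))

  jsonlite::write_json(log, file.path(config$outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(tables = filtered, pooled = pooled, dmps = dmp_sets,
                 dmrs = dmr_sets, union = union, assignment = assignment,
                 rates = rates, pca = pca))
}
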