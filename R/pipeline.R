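#' Pipeline configuration
#'
#' Collects every tunable of the comparative-editing pipeline in one validated
#' document. Defaults encode the analysis constants used throughout the
#' package: 20x coverage in at least 7 of 10 populations, 20-percentage-point
#' differential gate at alpha 0.05, replicate |z| > 1.65 with a 10-point gap
#' for population-specific calls, 100-base locus grouping, 40-base isoform
#' cluster window, and a 2% noise floor for sequential-order inference.
#'
#' @param min_coverage,min_populations,reproducibility_max_spread site
#'   inclusion (see [inclusion_rule()]).
#' @param alpha,min_delta,correction differential testing (see
#'   [pairwise_differential()]).
#' @param z_thresh,min_gap specificity calling (see [call_specific()]).
#' @param locus_gap locus grouping gap, bases.
#' @param cluster_window isoform cluster window, bases.
#' @param noise_floor sequential-order noise floor (fraction of reads).
#' @param seed integer seed for any simulation step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_coverage = 20, min_populations = 7,
                            reproducibility_max_spread = 0.2,
                            alpha = 0.05, min_delta = 0.20, correction = "BH",
                            z_thresh = 1.65, min_gap = 0.10,
                            locus_gap = 100, cluster_window = 40,
                            noise_floor = 0.02, seed = 1L) {
  cfg <- list(min_coverage = min_coverage, min_populations = min_populations,
              reproducibility_max_spread = reproducibility_max_spread,
              alpha = alpha, min_delta = min_delta, correction = correction,
              z_thresh = z_thresh, min_gap = min_gap, locus_gap = locus_gap,
              cluster_window = cluster_window, noise_floor = noise_floor,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  stopifnot(cfg$min_coverage >= 1, cfg$min_populations >= 1,
            cfg$reproducibility_max_spread >= 0,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$min_delta >= 0, cfg$min_delta <= 1,
            cfg$correction %in% c("BH", "bonferroni", "none"),
            cfg$z_thresh > 0, cfg$min_gap >= 0,
            cfg$locus_gap >= 1, cfg$cluster_window >= 1,
            cfg$noise_floor >= 0, cfg$noise_floor < 1)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the comparative-editing pipeline end to end
#'
#' Quantification (inclusion filtering, pooled levels, overall editing),
#' pairwise differential editing, population-specific calling, and isoform
#' cluster detection over the specific sites, writing one TSV per stage plus
#' a provenance log. Deterministic for fixed inputs and configuration.
#'
#' @param cm `edit_counts` at replicate resolution.
#' @param sheet `sample_sheet`.
#' @param out_dir output directory (created if needed).
#' @param config `pipeline_config`.
#' @param annot optional annotation data.frame; enables the enrichment report.
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(cm, sheet, out_dir, config = pipeline_config(),
                         annot = NULL) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  rule <- inclusion_rule(config$min_coverage, config$min_populations,
                         config$reproducibility_max_spread)
  inc <- apply_inclusion(cm, sheet, rule)
  kept <- cm[inc$keep, ]
  pooled <- pool_replicates(kept, sheet)
  lv <- editing_levels(pooled)
  levels_df <- data.frame(
    chrom = rep(pooled$sites$chrom, length(pooled$samples)),
    pos = rep(pooled$sites$pos, length(pooled$samples)),
    strand = rep(pooled$sites$strand, length(pooled$samples)),
    population = rep(pooled$samples, each = nrow(pooled$sites)),
    a = as.vector(pooled$a), g = as.vector(pooled$g),
    level = as.vector(lv), stringsAsFactors = FALSE)
  write_table(levels_df, file.path(out_dir, "levels.tsv"))
  write_table(inc$report, file.path(out_dir, "inclusion.tsv"))
  overall <- overall_editing(kept)
  write_table(data.frame(sample = names(overall), overall_editing = overall),
              file.path(out_dir, "overall.tsv"))
  diff <- pairwise_differential(kept, sheet, alpha = config$alpha,
                                min_delta = config$min_delta,
                                correction = config$correction)
  write_table(diff, file.path(out_dir, "pairwise.tsv"))
  summ <- population_summary(diff)
  write_table(summ, file.path(out_dir, "summary.tsv"))
  zrec <- replicate_zscores(kept, sheet)
  specific <- call_specific(zrec, kept, sheet, z_thresh = config$z_thresh,
                            min_gap = config$min_gap)
  write_table(specific, file.path(out_dir, "specific.tsv"))
  enrich <- NULL
  if (!is.null(annot) && nrow(specific) > 0) {
    spec_sites <- kept$sites[match(specific$site_id, site_id(kept$sites)), ]
    enrich <- category_enrichment(spec_sites, kept$sites, annot)
    write_table(enrich, file.path(out_dir, "enrichment.tsv"))
  }
  clusters <- if (nrow(specific) > 0) {
    usid <- unique(specific$site_id)
    find_clusters(kept$sites[site_id(kept$sites) %in% usid, , drop = FALSE],
                  config$cluster_window)
  } else list()
  if (length(clusters)) {
    cl_df <- do.call(rbind, lapply(seq_along(clusters), function(i)
      cbind(cluster = i, clusters[[i]][, c("chrom", "pos", "strand")])))
    write_table(cl_df, file.path(out_dir, "clusters.tsv"))
  }
  log <- c(paste0("neuroedit ", as.character(utils::packageVersion("neuroedit"))),
           paste0("R ", R.version.string),
           paste0("started ", format(t0, "%Y-%m-%d %H:%M:%S")),
           paste0("elapsed_s ", round(as.numeric(Sys.time() - t0, units = "secs"), 2)),
           "config:",
           paste0("  ", names(config), ": ", unlist(config)))
  writeLines(log, file.path(out_dir, "provenance.log"))
  invisible(list(inclusion = inc, pooled = pooled, overall = overall,
                 differential = diff, summary = summ, zscores = zrec,
                 specific = specific, enrichment = enrich,
                 clusters = clusters))
}
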