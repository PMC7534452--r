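#' Packaged metrics of the 14 reference RIL populations
#'
#' Loads the packaged per-population metadata of the Arabidopsis NAM panel
#' (Col-0 recurrent parent): population sizes, marker counts, linkage-map
#' metrics and missing-data rates before and after imputation.
#'
#' @return Data frame, one row per RIL population.
#' @export
ril_population_metrics <- function() {
  utils::read.delim(system.file("extdata", "ril_population_metrics.tsv",
                                package = "namqtl"),
                    stringsAsFactors = FALSE)
}

#' Per-population small-effect QTL density-simulation summary
#'
#' Loads the packaged per-population summary of the small-effect
#' (10% PVE) marker-density simulation: mean estimated PVE and mean
#' 1.5-LOD support interval under the dense (GBS-augmented) and original
#' (INRA) maps, the percent interval reduction, and the percent of QTL the
#' sparse map detected.
#'
#' @return Data frame, one row per RIL population.
#' @export
density_simulation_metrics <- function() {
  utils::read.delim(system.file("extdata", "qtl_density_simulation_small_effect.tsv",
                                package = "namqtl"),
                    stringsAsFactors = FALSE)
}

#' Aggregate per-population panel metrics
#'
#' Panel-level summary of a per-population metrics table (as returned by
#' [ril_population_metrics()] or assembled from [map_metrics()] and
#' imputation reports): total line count and the across-population means
#' of the marker counts, interval metrics and missing-data rates.
#'
#' @param metrics Data frame with the columns of
#'   [ril_population_metrics()].
#' @return Named list of aggregates.
#' @export
panel_metrics_summary <- function(metrics = ril_population_metrics()) {
  list(n_populations = nrow(metrics),
       total_lines = sum(metrics$population_size),
       mean_gbs_markers = mean(metrics$gbs_markers),
       mean_overall_length_cM = mean(metrics$overall_length_cM),
       mean_avg_interval_cM = mean(metrics$avg_interval_cM),
       mean_max_interval_cM = mean(metrics$max_interval_cM),
       mean_pct_missing_gbs = mean(metrics$pct_missing_gbs),
       mean_pct_missing_postimpute = mean(metrics$pct_missing_postimpute))
}

#' Aggregate a per-population density-comparison table
#'
#' Across-population means of the density-simulation summary: estimated
#' PVE under each map, 1.5-LOD interval widths, the percent interval
#' reduction (averaged in magnitude) and the sparse-map detection rate.
#'
#' @param metrics Data frame with the columns of
#'   [density_simulation_metrics()].
#' @return Named list of aggregates.
#' @export
density_metrics_summary <- function(metrics = density_simulation_metrics()) {
  list(mean_pve_gbs = mean(metrics$mean_pve_gbs),
       mean_pve_inra = mean(metrics$mean_pve_inra),
       mean_interval_gbs_cM = mean(metrics$mean_interval_gbs_cM),
       mean_interval_inra_cM = mean(metrics$mean_interval_inra_cM),
       mean_pct_interval_reduction = mean(abs(metrics$pct_interval_reduction)),
       mean_pct_detected_inra = mean(metrics$pct_detected_inra))
}

#' Minimum allele replication in NAM and MAGIC designs
#'
#' The number of lines expected to carry a minor allele at its minimum
#' frequency: in a biparental RIL population every segregating locus has
#' allele frequency about 1/2, so a NAM sub-panel offers at least
#' n_lines / 2 carriers from the single segregating population; in a
#' multiparent intercross of f founders the minor-allele frequency can
#' fall to 1/f, leaving about n_lines / f carriers.
#'
#' @param n_lines Lines in the (sub)population.
#' @param min_maf Minimum minor-allele frequency of the design (1/2 for a
#'   biparental RIL population, 1/founders for a MAGIC-type population).
#' @return Expected carrier count (not rounded).
#' @examples
#' min_allele_replication(150, 1 / 2)   # single RIL population
#' min_allele_replication(527, 1 / 19)  # 19-founder intercross
#' @export
min_allele_replication <- function(n_lines, min_maf) {
  stopifnot(n_lines > 0, min_maf > 0, min_maf <= 0.5)
  n_lines * min_maf
}
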