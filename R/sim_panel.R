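#' Default desk-scale chromosome specification
#'
#' Five chromosomes with Arabidopsis-like physical lengths and genetic
#' lengths totalling about 480 cM, the scale of published Arabidopsis RIL maps.
#'
#' @return Data frame with `chrom`, `length_bp`, `length_cM`.
#' @export
default_chrom_spec <- function() {
  data.frame(chrom = paste0("Chr", 1:5),
             length_bp = c(30.4, 19.7, 23.5, 18.6, 27.0) * 1e6,
             length_cM = c(121, 88, 96, 76, 99))
}

#' Simulate a complete NAM panel
#'
#' End-to-end generator: builds a founder panel, breeds one F8 RIL
#' population per alternate founder, applies the GBS observation model
#' (markers sampled uniformly and independently per population from the
#' SNPs polymorphic in that cross, so GBS markers rarely overlap across
#' populations), runs the fill-in/filter imputation, projects the dense
#' parental SNPs and merges everything into a `nam_panel`.
#'
#' Defaults emulate the 14-population Arabidopsis panel: 14 alternate
#' founders, about 137-150 lines and 563-1525 GBS markers per population
#' with 16-27% missing calls, at a desk-scale dense-SNP density.
#'
#' @param n_pops Number of RIL populations (alternate founders).
#' @param lines_per_pop Integer vector (recycled) of population sizes.
#' @param gbs_markers Integer vector (recycled) of GBS marker counts per
#'   population (capped at the SNPs polymorphic in the cross).
#' @param missing_rate Numeric vector (recycled) of per-population GBS
#'   missing-call rates.
#' @param geno_error_rate Per-call genotyping error rate.
#' @param chrom_spec Chromosome specification (see [default_chrom_spec()]).
#' @param snp_density Dense panel SNPs per Mb.
#' @param epsilon Assumed error rate for the genotype-probability filter.
#' @param threshold Posterior threshold for [filter_low_confidence()].
#' @param impute Run fill-in + filter + dense projection (default TRUE;
#'   FALSE returns raw GBS populations only).
#' @param seed Master seed; all per-population seeds derive from it.
#' @return List: `panel` (the `nam_panel`, NULL when `impute = FALSE`),
#'   `pops` (list of GBS `ril_population`s; when imputed, `geno` holds the
#'   filled calls and `geno_observed` the raw GBS calls — estimate linkage
#'   maps from the latter, since filled cells copy their flanks and would
#'   bias recombination counts down), `founders` (the `founder_panel`),
#'   `dense` (per-population projection results) and `reports`
#'   (per-population imputation reports).
#' @export
simulate_nam_panel <- function(n_pops = 14L,
                               lines_per_pop = c(141, 145, 144, 144, 147, 148, 149,
                                                 148, 142, 137, 150, 149, 147, 137),
                               gbs_markers = c(563, 1175, 1158, 1419, 1525, 711, 1119,
                                               1477, 1257, 1000, 1269, 1264, 1348, 1096),
                               missing_rate = c(0.271, 0.236, 0.230, 0.166, 0.227,
                                                0.202, 0.236, 0.260, 0.215, 0.233,
                                                0.206, 0.197, 0.178, 0.164),
                               geno_error_rate = 0.002,
                               chrom_spec = default_chrom_spec(),
                               snp_density = 50,
                               epsilon = 0.01, threshold = 0.99,
                               impute = TRUE, seed = 1L) {
  lines_per_pop <- rep_len(lines_per_pop, n_pops)
  gbs_markers <- rep_len(gbs_markers, n_pops)
  missing_rate <- rep_len(missing_rate, n_pops)
  founders <- build_founder_panel(n_pops, chrom_spec, snp_density, seed = seed)
  pops <- list(); dense <- list(); reports <- list()
  for (k in seq_len(n_pops)) {
    alt <- colnames(founders$alt)[k]
    pop <- breed_ril_population(founders, alt, lines_per_pop[k],
                                seed = seed + 1000L * k, name = alt)
    poly <- polymorphic_snps(founders, alt)
    set.seed(seed + 1000L * k + 1L)
    mk <- sort(sample(poly, min(gbs_markers[k], length(poly))))
    pop <- apply_gbs_observation_model(pop, mk, missing_rate[k],
                                       geno_error_rate,
                                       seed = seed + 1000L * k + 2L)
    if (impute) {
      # keep the observed GBS calls: downstream map estimation must not see
      # filled cells (fills are copies of their flanks, so they would
      # selectively remove recombinant pairs and deflate the map)
      pop$geno_observed <- pop$geno
      filled <- fill_in_missing(pop$geno, pop$map)
      probs <- genotype_probabilities(pop$geno, pop$map, epsilon = epsilon)
      filled <- filter_low_confidence(filled, probs, threshold)
      pop$geno <- filled$geno
      reports[[alt]] <- filled$report
      dense[[alt]] <- impute_parental_snps(pop, founders)
    }
    pops[[alt]] <- pop
  }
  panel <- if (impute)
    merge_populations(pops, lapply(dense, `[[`, "geno"), founders) else NULL
  list(panel = panel, pops = pops, founders = founders,
       dense = dense, reports = reports)
}
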