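#' Apply a GBS-style observation model to a RIL population
#'
#' Restricts the population to a marker subset (the SNPs a
#' genotyping-by-sequencing assay would recover in this cross) and degrades
#' the calls: each call is independently flipped to the other homozygote
#' with probability `geno_error_rate` (HET calls are left alone) and set to
#' missing with probability `missing_rate`. The truth slot is untouched.
#'
#' @param pop A `ril_population`.
#' @param marker_ids Marker ids to retain (non-empty subset of the
#'   population's markers).
#' @param missing_rate,geno_error_rate Per-call rates in [0, 1).
#' @param seed Integer seed.
#' @return The degraded `ril_population` (markers restricted, `map` subset
#'   accordingly).
#' @export
apply_gbs_observation_model <- function(pop, marker_ids, missing_rate = 0.216,
                                        geno_error_rate = 0, seed = 1L) {
  stopifnot(inherits(pop, "ril_population"),
            missing_rate >= 0, missing_rate < 1,
            geno_error_rate >= 0, geno_error_rate < 1)
  if (length(marker_ids) == 0) stop("empty marker subset")
  if (!all(marker_ids %in% colnames(pop$geno)))
    stop("marker ids not present in population")
  set.seed(seed)
  keep <- colnames(pop$geno) %in% marker_ids
  geno <- pop$geno[, keep, drop = FALSE]
  if (geno_error_rate > 0) {
    hom <- which(is_hom(geno))
    flip <- hom[stats::runif(length(hom)) < geno_error_rate]
    geno[flip] <- GENO_ALT + GENO_REF - geno[flip]
  }
  if (missing_rate > 0) {
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  }
  pop$geno <- geno
  m <- pop$map[pop$map$marker %in% marker_ids, , drop = FALSE]
  class(m) <- c("genetic_map", "data.frame")
  pop$map <- m
  pop
}

#' Count recombination breakpoints per line
#'
#' Breakpoints are transitions between REF and ALT among the ordered
#' non-missing homozygous calls of a line along each chromosome (HET and
#' missing calls are skipped).
#'
#' @param geno Lines x markers genotype matrix.
#' @param map `genetic_map` matching the marker columns.
#' @return Integer vector, one count per line.
#' @export
count_breakpoints <- function(geno, map) {
  stopifnot(ncol(geno) == nrow(map))
  chrom_idx <- split(seq_len(nrow(map)), map$chrom)
  vapply(seq_len(nrow(geno)), function(i) {
    sum(vapply(chrom_idx, function(idx) {
      g <- geno[i, idx]
      g <- g[is_hom(g)]
      if (length(g) < 2) 0L else sum(diff(g) != 0)
    }, integer(1)))
  }, integer(1))
}

#' Select the most informative RILs
#'
#' Ranks lines by recombination-breakpoint count (descending) with fewer
#' heterozygous calls as the tie-break, and keeps the top `k`. The ranking
#' is deterministic (stable in the original line order on full ties).
#'
#' @param pop A `ril_population`.
#' @param k Number of lines to keep (1 <= k <= n lines).
#' @return The subset `ril_population`.
#' @export
select_informative_lines <- function(pop, k) {
  stopifnot(inherits(pop, "ril_population"))
  n <- nrow(pop$geno)
  if (k <= 0) stop("k must be positive")
  if (k > n) stop("k exceeds the number of lines")
  bp <- count_breakpoints(pop$geno, pop$map)
  het <- rowSums(pop$geno == GENO_HET, na.rm = TRUE)
  ord <- order(-bp, het, seq_len(n))
  keep <- sort(ord[seq_len(k)])
  pop$geno <- pop$geno[keep, , drop = FALSE]
  if (!is.null(pop$truth)) pop$truth$geno <- pop$truth$geno[keep, , drop = FALSE]
  pop
}
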