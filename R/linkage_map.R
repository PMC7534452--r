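#' Estimate the recombinant fraction between two adjacent markers
#'
#' Counts lines that are homozygous and non-missing at both markers
#' (informative lines); the observed RIL recombinant fraction is the share
#' of those lines whose two calls differ. HET calls are excluded because a
#' selfed RIL is expected to be near-homozygous.
#'
#' @param geno Lines x markers genotype matrix.
#' @param i,j Column indices (or marker names) of the two markers.
#' @return List with `R_hat` (NA when no line is informative) and
#'   `n_informative`.
#' @export
estimate_adjacent_rf <- function(geno, i, j) {
  a <- geno[, i]; b <- geno[, j]
  ok <- is_hom(a) & is_hom(b)
  n <- sum(ok)
  if (n == 0) return(list(R_hat = NA_real_, n_informative = 0L))
  list(R_hat = sum(a[ok] != b[ok]) / n, n_informative = n)
}

#' Estimate a genetic map from RIL genotypes
#'
#' Markers are kept in physical order and the cM position of each marker is
#' the cumulative sum, along the chromosome, of adjacent-interval distances:
#' the observed recombinant fraction of each adjacent pair is corrected for
#' selfing-RIL map expansion (r = R / (2(1 - R))) and converted to cM with
#' the chosen map function (Kosambi by default). Each chromosome starts at
#' 0 cM.
#'
#' Intervals with no informative line take a fall-back length of 0 cM and
#' are flagged; observed fractions >= 0.5 are clamped (see
#' [rf_from_ril_R()]).
#'
#' Estimate from observed calls, not from fill-in imputed ones: filled
#' cells copy their flanks, so they add concordant pairs while
#' breakpoint-spanning missing runs stay excluded, deflating the map.
#' Conversely, uncorrected genotyping errors inflate the map (each error
#' adds a spurious recombinant pair to two intervals); screen the observed
#' calls with [correct_genotype_errors()] first.
#'
#' @param pop A `ril_population` (markers sorted by chromosome and bp).
#' @param map_function "kosambi" (default) or "haldane".
#' @return A `genetic_map` with an extra attribute `flagged_intervals`, a
#'   data frame of problem intervals (chrom, left marker, reason).
#' @export
estimate_map <- function(pop, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  stopifnot(inherits(pop, "ril_population"))
  phys <- pop$map
  flagged <- list()
  cm_all <- numeric(nrow(phys))
  for (ch in unique(phys$chrom)) {
    idx <- which(phys$chrom == ch)
    cm <- numeric(length(idx))
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1L)) {
        rf <- estimate_adjacent_rf(pop$geno, phys$marker[idx[k]], phys$marker[idx[k + 1L]])
        if (rf$n_informative == 0L) {
          d <- 0
          flagged[[length(flagged) + 1L]] <-
            data.frame(chrom = ch, marker = phys$marker[idx[k]], reason = "no informative lines")
        } else {
          if (rf$R_hat >= 0.5)
            flagged[[length(flagged) + 1L]] <-
              data.frame(chrom = ch, marker = phys$marker[idx[k]], reason = "R_hat >= 0.5")
          r <- suppressWarnings(rf_from_ril_R(rf$R_hat))
          d <- map_d_from_r(r, map_function)
        }
        cm[k + 1L] <- cm[k] + d
      }
    }
    cm_all[idx] <- cm
  }
  out <- genetic_map(phys$chrom, phys$marker, phys$pos_bp, cm_all)
  attr(out, "flagged_intervals") <- if (length(flagged)) do.call(rbind, flagged)
    else data.frame(chrom = character(0), marker = character(0), reason = character(0))
  out
}
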