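#' Pairwise linkage disequilibrium (r-squared) between two SNPs
#'
#' r^2 is the squared Pearson correlation of {0, 1} allele codes over lines
#' that are homozygous and non-missing at both SNPs; the p-value comes from
#' the correlation t-test on those complete pairs. HET and missing calls
#' are excluded pairwise.
#'
#' @param geno Lines x SNPs genotype matrix.
#' @param snpA,snpB Column names or indices.
#' @return List with `r2`, `p`, `n` (complete pairs); `r2` is NA (flagged)
#'   with fewer than 3 complete pairs or a monomorphic SNP.
#' @export
pairwise_r2 <- function(geno, snpA, snpB) {
  a <- geno[, snpA]; b <- geno[, snpB]
  ok <- is_hom(a) & is_hom(b)
  n <- sum(ok)
  if (n < 3) return(list(r2 = NA_real_, p = NA_real_, n = n))
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(list(r2 = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(a, b)
  list(r2 = unname(ct$estimate^2), p = ct$p.value, n = n)
}

# all intra-chromosomal pairwise r2 within a bp distance cap, vectorised
# per chromosome via pairwise-complete correlations on 0/1 hom codes
intra_chrom_pairs <- function(geno, map, max_dist_bp = 1e7) {
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    X <- geno[, idx, drop = FALSE]
    X[!is.na(X) & X == GENO_HET] <- NA_integer_
    suppressWarnings(C <- stats::cor(X, use = "pairwise.complete.obs"))
    pos <- map$pos_bp[idx]
    pr <- which(upper.tri(C), arr.ind = TRUE)
    d <- pos[pr[, 2L]] - pos[pr[, 1L]]
    r2 <- C[pr]^2
    keep <- d > 0 & d <= max_dist_bp & !is.na(r2)
    out[[ch]] <- data.frame(chrom = ch, dist_bp = d[keep], r2 = r2[keep])
  }
  do.call(rbind, out)
}

#' Linkage-disequilibrium decay with distance
#'
#' Samples `n_snps` SNPs without replacement (all SNPs, with a note, when
#' fewer are available), computes intra-chromosomal pairwise r^2 for pairs
#' closer than `max_dist_bp`, smooths r^2 against distance by binned means
#' over 50 log-spaced distance bins followed by an isotonic (non-increasing)
#' adjustment, and reports the smallest distance where the smoothed curve
#' falls to `level`.
#'
#' @param geno Lines x SNPs genotype matrix (e.g. `nam_panel$geno`, possibly
#'   row-subset to a population subset).
#' @param map Matching `genetic_map`.
#' @param n_snps Number of SNPs to sample (default 10000).
#' @param level r^2 level defining the decay distance (default 0.1).
#' @param max_dist_bp Distance cap for intra-chromosomal pairs (default 10 Mb).
#' @param n_bins Number of log-spaced distance bins (default 50).
#' @param seed Integer seed for the SNP sample.
#' @return Object of class `ld_decay`: list with `pairs` (dist_bp, r2),
#'   `curve` (bin mid-distance, smoothed r2), `d_at_r2` (bp; the smallest
#'   sampled distance when the curve starts at or below `level`, NA when it
#'   never reaches it), `level`, `n_snps_used`.
#' @export
ld_decay <- function(geno, map, n_snps = 10000L, level = 0.1,
                     max_dist_bp = 1e7, n_bins = 50L, seed = 1L) {
  stopifnot(nrow(geno) > 0)
  set.seed(seed)
  M <- ncol(geno)
  if (M > n_snps) {
    sel <- sort(sample.int(M, n_snps))
  } else {
    if (M < n_snps) message("fewer SNPs than requested; using all ", M)
    sel <- seq_len(M)
  }
  g <- geno[, sel, drop = FALSE]
  m <- map[sel, , drop = FALSE]
  pairs <- intra_chrom_pairs(g, m, max_dist_bp)
  if (is.null(pairs) || nrow(pairs) == 0) stop("no informative SNP pairs")
  breaks <- exp(seq(log(max(min(pairs$dist_bp), 1)), log(max(pairs$dist_bp)),
                    length.out = n_bins + 1L))
  breaks[1L] <- 0
  bin <- cut(pairs$dist_bp, breaks, labels = FALSE, include.lowest = TRUE)
  mids <- tapply(pairs$dist_bp, bin, stats::median)
  means <- tapply(pairs$r2, bin, mean)
  ok <- !is.na(means)
  mids <- as.numeric(mids[ok]); means <- as.numeric(means[ok])
  iso <- stats::isoreg(mids, -means)   # non-increasing fit
  sm <- -iso$yf[order(order(mids))]
  d_at <- if (sm[1L] <= level) min(pairs$dist_bp)
          else if (all(sm > level)) NA_real_
          else mids[which(sm <= level)[1L]]
  structure(list(pairs = pairs, curve = data.frame(dist_bp = mids, r2 = sm),
                 d_at_r2 = d_at, level = level, n_snps_used = length(sel)),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay over", nrow(x$pairs), "SNP pairs;",
      sprintf("r2 reaches %.2g at %.2f Mb\n", x$level, x$d_at_r2 / 1e6))
  invisible(x)
}

#' Screen for inter-chromosomal allelic incompatibilities
#'
#' Thins markers to one SNP per `window_bp` window per chromosome (the SNP
#' with the most informative homozygous calls, ties to the first), tests
#' every between-chromosome SNP pair for association (correlation test on
#' {0, 1} codes over complete homozygous pairs) with Bonferroni correction
#' at family level `alpha`, and reports, for each significant pair, the
#' 2 x 2 homozygote-combination frequency table and its rarest class —
#' the signature of a two-locus (Dobzhansky-Muller-type) incompatibility
#' purged during inbreeding.
#'
#' @param pop A `ril_population` (or any list with `geno` and `map`).
#' @param window_bp Thinning window (default 1 Mb).
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame of hits: chromA, bpA, chromB, bpB, r2, p,
#'   freq_RR, freq_RA, freq_AR, freq_AA (REF/ALT homozygote combination
#'   frequencies over informative lines), low_class, low_freq. Sorted by p.
#' @export
interchromosomal_screen <- function(pop, window_bp = 1e6, alpha = 0.05) {
  geno <- pop$geno; map <- pop$map
  if (length(unique(map$chrom)) < 2) stop("need at least 2 chromosomes")
  # thin: best-covered SNP per window
  n_inf <- colSums(is_hom(geno))
  sel <- integer(0)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    win <- floor(map$pos_bp[idx] / window_bp)
    for (w in unique(win)) {
      cand <- idx[win == w]
      sel <- c(sel, cand[which.max(n_inf[cand])])
    }
  }
  sel <- sort(sel)
  pr <- expand.grid(i = sel, j = sel)
  pr <- pr[map$chrom[pr$i] < map$chrom[pr$j], , drop = FALSE]
  n_tests <- nrow(pr)
  hits <- list()
  for (k in seq_len(n_tests)) {
    i <- pr$i[k]; j <- pr$j[k]
    res <- pairwise_r2(geno, i, j)
    if (is.na(res$p) || res$p > alpha / n_tests) next
    a <- geno[, i]; b <- geno[, j]
    ok <- is_hom(a) & is_hom(b)
    tab <- table(factor(a[ok], c(GENO_REF, GENO_ALT)),
                 factor(b[ok], c(GENO_REF, GENO_ALT))) / sum(ok)
    freq <- c(RR = tab[1, 1], RA = tab[1, 2], AR = tab[2, 1], AA = tab[2, 2])
    labs <- c("REF & REF", "REF & ALT", "ALT & REF", "ALT & ALT")
    low <- which.min(freq)
    hits[[length(hits) + 1L]] <- data.frame(
      chromA = map$chrom[i], bpA = map$pos_bp[i],
      chromB = map$chrom[j], bpB = map$pos_bp[j],
      r2 = res$r2, p = res$p,
      freq_RR = freq[1], freq_RA = freq[2], freq_AR = freq[3], freq_AA = freq[4],
      low_class = labs[low], low_freq = freq[low],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (length(hits)) do.call(rbind, hits)
    else data.frame(chromA = character(0), bpA = numeric(0), chromB = character(0),
                    bpB = numeric(0), r2 = numeric(0), p = numeric(0),
                    freq_RR = numeric(0), freq_RA = numeric(0), freq_AR = numeric(0),
                    freq_AA = numeric(0), low_class = character(0), low_freq = numeric(0))
  attr(out, "n_tests") <- n_tests
  out[order(out$p), , drop = FALSE]
}

#' Plant a two-locus incompatibility into a RIL population
#'
#' Removes (or down-samples to `survival`) lines carrying the lethal
#' homozygote combination at two unlinked loci, emulating recessive
#' embryo lethality purging an allelic combination during RIL development.
#'
#' @param pop A `ril_population`.
#' @param locusA,locusB Marker names/indices on different chromosomes.
#' @param lethal_class Length-2 integer vector: the (codeA, codeB)
#'   homozygote combination lost, e.g. `c(GENO_REF, GENO_ALT)`.
#' @param survival Fraction of lethal-class lines that survive (default 0).
#' @param seed Integer seed (used when 0 < survival < 1).
#' @return The shrunken `ril_population`.
#' @export
simulate_incompatibility <- function(pop, locusA, locusB,
                                     lethal_class = c(GENO_REF, GENO_ALT),
                                     survival = 0, seed = 1L) {
  map <- pop$map
  ia <- if (is.character(locusA)) match(locusA, map$marker) else locusA
  ib <- if (is.character(locusB)) match(locusB, map$marker) else locusB
  if (map$chrom[ia] == map$chrom[ib]) stop("loci must be on different chromosomes")
  a <- pop$geno[, ia]; b <- pop$geno[, ib]
  inclass <- !is.na(a) & !is.na(b) & a == lethal_class[1L] & b == lethal_class[2L]
  if (survival >= 1) return(pop)
  set.seed(seed)
  die <- inclass & stats::runif(length(inclass)) >= survival
  if (all(die)) stop("all lines removed")
  pop$geno <- pop$geno[!die, , drop = FALSE]
  if (!is.null(pop$truth)) pop$truth$geno <- pop$truth$geno[!die, , drop = FALSE]
  pop
}
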