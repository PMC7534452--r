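#' Conservative fill-in of missing genotypes
#'
#' For each line and chromosome, every maximal run of missing calls whose
#' nearest non-missing flanking calls are the same homozygous state is set
#' to that state. Runs touching a chromosome end, runs flanked by differing
#' states, and runs with a heterozygous flank (i.e. chromosome ends and
#' recombination-breakpoint regions) are left missing. Observed calls are
#' never altered.
#'
#' @param geno Lines x markers genotype matrix, columns ordered by map.
#' @param map `genetic_map` matching the columns.
#' @return List with `geno` (filled matrix), `origin` (integer matrix,
#'   0 = observed/still missing, 1 = filled) and `report` (list:
#'   `n_filled`, `missing_fraction_before`, `missing_fraction_after`).
#' @export
fill_in_missing <- function(geno, map) {
  stopifnot(ncol(geno) == nrow(map))
  origin <- matrix(0L, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  before <- mean(is.na(geno))
  chrom_idx <- split(seq_len(nrow(map)), factor(map$chrom, unique(map$chrom)))
  for (idx in chrom_idx) {
    for (i in seq_len(nrow(geno))) {
      g <- geno[i, idx]
      na <- is.na(g)
      if (!any(na)) next
      r <- rle(na)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        s <- starts[k]; e <- ends[k]
        if (s == 1L || e == length(g)) next
        left <- g[s - 1L]; right <- g[e + 1L]
        if (left == right && left != GENO_HET) {
          g[s:e] <- left
          origin[i, idx[s:e]] <- 1L
        }
      }
      geno[i, idx] <- g
    }
  }
  list(geno = geno, origin = origin,
       report = list(n_filled = sum(origin == 1L),
                     missing_fraction_before = before,
                     missing_fraction_after = mean(is.na(geno))))
}

# F_t residual heterozygosity
ril_het <- function(generation) 0.5^(generation - 1L)

# Transition matrix of the F_t RIL chain between two markers an observed
# RIL recombinant fraction R apart; states (REF, ALT, HET). Stationary
# distribution ((1-h)/2, (1-h)/2, h).
ril_transition <- function(R, h) {
  rbind(c((1 - h) * (1 - R), (1 - h) * R, h),
        c((1 - h) * R, (1 - h) * (1 - R), h),
        c((1 - h) / 2, (1 - h) / 2, h))
}

#' Multipoint genotype probabilities (forward-backward)
#'
#' Posterior probabilities of the true genotype {REF, ALT, HET} at each
#' marker of each line, from a per-chromosome Markov chain: the stationary
#' distribution for an F_t selfing RIL is ((1-h)/2, (1-h)/2, h) with
#' h = (1/2)^(t-1); transitions between flanking markers derive from the
#' interval cM through the map function and the selfing-RIL recombinant
#' fraction R = 2r/(1+2r); emissions put 1 - epsilon on the observed call
#' and epsilon/2 on each other state, and missing calls are uninformative.
#'
#' @param geno Lines x markers genotype matrix.
#' @param map `genetic_map` matching the columns (cM used for transitions).
#' @param epsilon Assumed genotyping error rate in [0, 0.5).
#' @param generation Selfing generation of the RILs (default 8).
#' @param map_function "kosambi" (default) or "haldane".
#' @return Object of class `geno_prob`: list of three lines x markers
#'   matrices `pREF`, `pALT`, `pHET`, plus the `map` and parameters.
#' @export
genotype_probabilities <- function(geno, map, epsilon = 0.01, generation = 8L,
                                   map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  stopifnot(ncol(geno) == nrow(map), epsilon >= 0, epsilon < 0.5)
  bad <- !is.na(geno) & !(geno %in% c(GENO_REF, GENO_ALT, GENO_HET))
  if (any(bad)) stop("unknown genotype state code")
  n <- nrow(geno); M <- ncol(geno)
  h <- ril_het(generation)
  pi0 <- c((1 - h) / 2, (1 - h) / 2, h)
  emis <- function(col) {
    # n x 3 emission matrix for one marker
    E <- matrix(1, n, 3)
    obs <- which(!is.na(col))
    if (length(obs)) {
      E[obs, ] <- epsilon / 2
      E[cbind(obs, col[obs] + 1L)] <- 1 - epsilon
    }
    E
  }
  pREF <- matrix(NA_real_, n, M, dimnames = dimnames(geno))
  pALT <- pREF; pHET <- pREF
  chrom_idx <- split(seq_len(M), factor(map$chrom, unique(map$chrom)))
  for (idx in chrom_idx) {
    m <- length(idx)
    Tm <- vector("list", max(m - 1L, 0L))
    if (m > 1) for (k in seq_len(m - 1L)) {
      d <- map$pos_cM[idx[k + 1L]] - map$pos_cM[idx[k]]
      R <- ril_R_from_r(map_r_from_d(d, map_function))
      Tm[[k]] <- ril_transition(R, h)
    }
    E <- lapply(idx, function(j) emis(geno[, j]))
    # forward
    alpha <- vector("list", m)
    a <- sweep(E[[1L]], 2, pi0, `*`)
    alpha[[1L]] <- a / rowSums(a)
    if (m > 1) for (k in 2:m) {
      a <- (alpha[[k - 1L]] %*% Tm[[k - 1L]]) * E[[k]]
      alpha[[k]] <- a / rowSums(a)
    }
    # backward
    beta <- matrix(1, n, 3)
    post <- alpha[[m]] * beta
    pREF[, idx[m]] <- post[, 1L] / rowSums(post)
    pALT[, idx[m]] <- post[, 2L] / rowSums(post)
    pHET[, idx[m]] <- post[, 3L] / rowSums(post)
    if (m > 1) for (k in (m - 1L):1L) {
      beta <- (beta * E[[k + 1L]]) %*% t(Tm[[k]])
      beta <- beta / rowSums(beta)
      post <- alpha[[k]] * beta
      s <- rowSums(post)
      pREF[, idx[k]] <- post[, 1L] / s
      pALT[, idx[k]] <- post[, 2L] / s
      pHET[, idx[k]] <- post[, 3L] / s
    }
  }
  structure(list(pREF = pREF, pALT = pALT, pHET = pHET, map = map,
                 epsilon = epsilon, generation = generation,
                 map_function = map_function),
            class = "geno_prob")
}

#' Revert low-confidence filled genotypes
#'
#' Cells that were filled by [fill_in_missing()] but whose multipoint
#' posterior probability for the filled state falls below `threshold`
#' revert to missing. Observed calls are untouched.
#'
#' @param filled The list returned by [fill_in_missing()].
#' @param probs A `geno_prob` from [genotype_probabilities()] computed on
#'   the observed (pre-fill) matrix, so a filled call's confidence comes
#'   from its neighbours rather than from its own imputed emission.
#' @param threshold Posterior threshold in (0.5, 1] (default 0.99).
#' @return The `filled` list with low-confidence cells reverted; the
#'   report gains `n_removed_low_confidence` and an updated
#'   `missing_fraction_after`.
#' @export
filter_low_confidence <- function(filled, probs, threshold = 0.99) {
  stopifnot(threshold > 0.5, threshold <= 1)
  geno <- filled$geno
  if (!all(dim(geno) == dim(probs$pREF))) stop("shape mismatch between genotypes and probabilities")
  pmat <- list(probs$pREF, probs$pALT, probs$pHET)
  idx <- which(filled$origin == 1L)
  state <- geno[idx]
  post <- numeric(length(idx))
  for (s in c(GENO_REF, GENO_ALT, GENO_HET)) {
    sel <- state == s
    post[sel] <- pmat[[s + 1L]][idx[sel]]
  }
  revert <- idx[post < threshold]
  geno[revert] <- NA_integer_
  filled$geno <- geno
  filled$origin[revert] <- 0L
  filled$report$n_removed_low_confidence <- length(revert)
  filled$report$missing_fraction_after <- mean(is.na(geno))
  filled
}

#' Revert likely-erroneous observed calls before map estimation
#'
#' Computes multipoint posteriors on the observed matrix and sets to
#' missing every observed call whose posterior probability for its own
#' called state falls below `threshold`. A singleton genotyping error
#' flanked by concordant calls gets a very low own-state posterior (its
#' neighbours outvote its emission), while a correct call adjacent to a
#' genuine recombination breakpoint keeps a posterior near 1 - epsilon,
#' so the screen removes errors without eating breakpoints. Run this
#' before [estimate_map()]: uncorrected errors each add a spurious
#' recombinant pair to two intervals and inflate the map.
#'
#' The default `threshold = 0.5` only reverts calls more likely wrong
#' than right; raising it trades a small loss of genuine close double
#' crossovers for stricter error removal.
#'
#' @param geno Lines x markers observed genotype matrix.
#' @param map `genetic_map` matching the columns.
#' @param epsilon Assumed genotyping error rate.
#' @param threshold Minimum own-state posterior to keep a call, in (0, 1].
#' @param ... Passed to [genotype_probabilities()].
#' @return List with `geno` (corrected matrix) and `n_reverted`.
#' @export
correct_genotype_errors <- function(geno, map, epsilon = 0.01,
                                    threshold = 0.5, ...) {
  stopifnot(threshold > 0, threshold <= 1)
  probs <- genotype_probabilities(geno, map, epsilon = epsilon, ...)
  pmat <- list(probs$pREF, probs$pALT, probs$pHET)
  revert <- integer(0)
  for (s in c(GENO_REF, GENO_ALT, GENO_HET)) {
    idx <- which(geno == s)
    revert <- c(revert, idx[pmat[[s + 1L]][idx] < threshold])
  }
  geno[revert] <- NA_integer_
  list(geno = geno, n_reverted = length(revert))
}

#' Project dense parental SNPs into anchored intervals
#'
#' For each line and chromosome, every interval between consecutive
#' non-missing homozygous GBS anchors that carry the same founder-origin
#' state assigns each dense panel SNP strictly inside the interval that
#' parent's allele: REF-anchored intervals take the recurrent-parent allele
#' (REF), ALT-anchored intervals take the alternate parent's allele at that
#' SNP (which is REF wherever the alternate parent carries the reference
#' base). Intervals with differing anchors, heterozygous calls (never
#' anchors) and chromosome-end overhangs are left missing. Dense SNPs
#' colocated with an anchor take the anchor's implied state.
#'
#' @param pop A `ril_population` whose `geno` holds the (typically filled
#'   and filtered) GBS calls; marker bp positions come from `pop$map`.
#' @param panel The `founder_panel` supplying dense SNP positions and the
#'   alternate parent's alleles.
#' @param geno Optional genotype matrix to use in place of `pop$geno`.
#' @return List with `geno` (lines x dense-SNPs allele codes), `origin`
#'   (0 = anchor-implied, 2 = projected, NA where missing) and `map` (the
#'   dense `genetic_map`).
#' @export
impute_parental_snps <- function(pop, panel, geno = pop$geno) {
  stopifnot(inherits(pop, "ril_population"), inherits(panel, "founder_panel"))
  if (!all(panel$snps$chrom %in% pop$map$chrom))
    stop("dense SNP on a chromosome absent from the population map")
  dense_map <- panel_dense_map(panel)
  da <- founder_alleles(panel, pop$alt_parent)
  n <- nrow(geno)
  out <- matrix(NA_integer_, n, nrow(dense_map),
                dimnames = list(rownames(geno), dense_map$marker))
  orig <- matrix(NA_integer_, n, nrow(dense_map), dimnames = dimnames(out))
  for (ch in unique(dense_map$chrom)) {
    dsel <- which(dense_map$chrom == ch)
    dpos <- dense_map$pos_bp[dsel]
    dall <- da[dsel]
    gsel <- which(pop$map$chrom == ch)
    gpos <- pop$map$pos_bp[gsel]
    for (i in seq_len(n)) {
      g <- geno[i, gsel]
      anc <- which(is_hom(g))
      if (length(anc) == 0) next
      apos <- gpos[anc]; astate <- g[anc]
      j <- findInterval(dpos, apos)
      coloc <- j >= 1L & dpos == apos[pmax(j, 1L)]
      if (any(coloc)) {
        st <- astate[j[coloc]]
        out[i, dsel[coloc]] <- ifelse(st == GENO_REF, GENO_REF, dall[coloc])
        orig[i, dsel[coloc]] <- 0L
      }
      inside <- !coloc & j >= 1L & j < length(anc)
      if (any(inside)) {
        same <- inside
        same[inside] <- astate[j[inside]] == astate[j[inside] + 1L]
        if (any(same)) {
          st <- astate[j[same]]
          out[i, dsel[same]] <- ifelse(st == GENO_REF, GENO_REF, dall[same])
          orig[i, dsel[same]] <- 2L
        }
      }
    }
  }
  list(geno = out, origin = orig, map = dense_map)
}

#' Double-crossover imputation error rate for a like-anchored interval
#'
#' The probability that a dense SNP projected into an interval of genetic
#' length d cM, anchored by like parental states, is wrong is the
#' probability of a double crossover in the interval, (d/100)^2. A
#' Kosambi-based alternative (the squared Kosambi recombination fraction)
#' is available but is not the default.
#'
#' @param d Interval length(s), cM, >= 0.
#' @param method "linear" (default; r = d/100) or "kosambi".
#' @return Error rate as a fraction (multiply by 100 for percent).
#' @examples
#' 100 * double_crossover_error_rate(0.4)   # 0.0016 (percent)
#' 100 * double_crossover_error_rate(13.9)  # 1.9321 (percent)
#' @export
double_crossover_error_rate <- function(d, method = c("linear", "kosambi")) {
  method <- match.arg(method)
  stopifnot(is.numeric(d), all(is.finite(d)))
  if (any(d < 0)) stop("interval length must be >= 0")
  r <- switch(method, linear = d / 100, kosambi = kosambi_r_from_d(d))
  r^2
}
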