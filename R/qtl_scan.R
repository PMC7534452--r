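#' Simulate a single-QTL phenotype at a marker
#'
#' y = a x + e with e ~ N(0, 1), x in {0, 1} coding the REF/ALT homozygote
#' at the target marker. Lines that are heterozygous or missing there get x
#' drawn from the empirical ratio of the two homozygote classes, so no line
#' is discarded. The additive effect is a = sqrt(PVE / ((1 - PVE) Var(x))),
#' which makes the expected share of phenotypic variance explained by the
#' marker equal to the target PVE.
#'
#' @param geno Lines x markers genotype matrix.
#' @param marker Target marker (column name or index); must segregate
#'   (both homozygote classes present).
#' @param pve Target proportion of variance explained, in (0, 1).
#' @param seed Integer seed.
#' @return List with `y` (phenotype vector), `x` (realised 0/1 QTL
#'   genotypes), `a` (additive effect) and `marker`.
#' @export
simulate_qtl_phenotype <- function(geno, marker, pve, seed = 1L) {
  stopifnot(pve > 0, pve < 1)
  g <- geno[, marker]
  n0 <- sum(!is.na(g) & g == GENO_REF)
  n1 <- sum(!is.na(g) & g == GENO_ALT)
  if (n0 == 0 || n1 == 0) stop("target marker is monomorphic")
  set.seed(seed)
  x <- as.numeric(g == GENO_ALT)
  amb <- is.na(g) | g == GENO_HET
  x[amb] <- stats::rbinom(sum(amb), 1L, n1 / (n0 + n1))
  vx <- mean((x - mean(x))^2)
  a <- sqrt(pve / ((1 - pve) * vx))
  y <- a * x + stats::rnorm(length(x))
  list(y = y, x = x, a = a, marker = marker)
}

# lines x markers matrix of P(ALT) weights among homozygote states, plus a
# flag for columns where every weight is exactly 0/1 (complete information)
scan_weights <- function(probs) {
  if (is.matrix(probs)) {
    w1 <- matrix(NA_real_, nrow(probs), ncol(probs), dimnames = dimnames(probs))
    w1[probs == GENO_REF] <- 0
    w1[probs == GENO_ALT] <- 1
    w1[probs == GENO_HET] <- 0.5
    frac <- colMeans(w1, na.rm = TRUE)
    na <- which(is.na(w1), arr.ind = TRUE)
    if (nrow(na)) w1[na] <- frac[na[, 2L]]
    map <- NULL
  } else if (inherits(probs, "geno_prob")) {
    w1 <- probs$pALT / (probs$pREF + probs$pALT)
    map <- probs$map
  } else stop("probs must be a geno_prob or a genotype matrix")
  list(w1 = w1, map = map,
       degenerate = apply(w1 == 0 | w1 == 1, 2L, all))
}

# closed-form ML LOD for fully-informative markers: the marker regression
# gives LOD = (n/2) log10(RSS0 / RSS1) = -(n/2) log10(1 - r^2)
lod_regression <- function(X, Y) {
  n <- nrow(X)
  Xs <- scale(X); Ys <- scale(Y)
  sdx0 <- attr(Xs, "scaled:scale") == 0
  r <- crossprod(Xs, Ys) / (n - 1)
  r[sdx0, ] <- 0
  -(n / 2) * log10(pmax(1 - r^2, 1e-300))
}

# vectorised EM over markers for one phenotype; W1 = P(ALT) weights
lod_em <- function(W1, y, tol = 1e-5, maxit = 60L) {
  n <- length(y)
  s0 <- colSums(W1); s1 <- n - s0
  ok <- s0 > 1e-8 & s1 > 1e-8
  lod <- numeric(ncol(W1))
  if (!any(ok)) return(lod)
  W <- W1[, ok, drop = FALSE]
  m1 <- colSums(W * y) / colSums(W)
  m0 <- colSums((1 - W) * y) / colSums(1 - W)
  ybar <- mean(y)
  s20 <- mean((y - ybar)^2)
  if (s20 <= 0) stop("zero phenotypic variance")
  ll0 <- sum(stats::dnorm(y, ybar, sqrt(s20), log = TRUE))
  Ymat <- matrix(y, n, ncol(W))
  R1 <- (Ymat - rep(m1, each = n))^2
  R0 <- (Ymat - rep(m0, each = n))^2
  s2 <- colSums(W * R1 + (1 - W) * R0) / n
  ll_old <- rep(-Inf, ncol(W))
  for (it in seq_len(maxit)) {
    inv2s2 <- rep(1 / (2 * s2), each = n)
    e1 <- exp(-R1 * inv2s2); e0 <- exp(-R0 * inv2s2)
    den <- W * e1 + (1 - W) * e0
    gam <- W * e1 / pmax(den, 1e-300)
    ll <- colSums(log(pmax(den, 1e-300))) - n / 2 * log(2 * pi * s2)
    if (max(abs(ll - ll_old)) < tol) { ll_old <- ll; break }
    ll_old <- ll
    cg <- colSums(gam)
    m1 <- colSums(gam * Ymat) / pmax(cg, 1e-12)
    m0 <- colSums((1 - gam) * Ymat) / pmax(n - cg, 1e-12)
    R1 <- (Ymat - rep(m1, each = n))^2
    R0 <- (Ymat - rep(m0, each = n))^2
    s2 <- colSums(gam * R1 + (1 - gam) * R0) / n
  }
  lod[ok] <- pmax((ll_old - ll0) / log(10), 0)
  lod
}

#' Maximum-likelihood single-QTL genome scan
#'
#' At each marker position, fits a two-component normal mixture for the
#' phenotype, with mixing weights given by each line's genotype
#' probabilities at that marker, by EM (the interval-mapping ML LOD). At a
#' fully observed marker this equals the marker-regression LOD,
#' (n/2) log10(RSS0/RSS1), and that closed form is used there directly.
#' Scan positions are the marker positions (no pseudomarker grid).
#'
#' @param probs A `geno_prob` from [genotype_probabilities()], or a
#'   genotype matrix (treated as fully informative where calls are
#'   homozygous; HET weight 0.5, missing weight = marker ALT frequency).
#' @param phenotype Numeric phenotype vector (no missing values).
#' @param map Optional `genetic_map` for the scan positions (taken from
#'   `probs` when it is a `geno_prob`).
#' @return A data frame of class `scan_result` with columns `chrom`,
#'   `marker`, `pos_cM`, `lod`.
#' @export
scan_ml <- function(probs, phenotype, map = NULL) {
  sw <- scan_weights(probs)
  map <- map %||% sw$map
  W1 <- sw$w1
  stopifnot(length(phenotype) == nrow(W1), !anyNA(phenotype))
  if (stats::var(phenotype) <= 0) stop("zero phenotypic variance")
  lod <- numeric(ncol(W1))
  if (any(sw$degenerate))
    lod[sw$degenerate] <- drop(lod_regression(W1[, sw$degenerate, drop = FALSE],
                                              matrix(phenotype)))
  if (any(!sw$degenerate))
    lod[!sw$degenerate] <- lod_em(W1[, !sw$degenerate, drop = FALSE], phenotype)
  out <- data.frame(chrom = if (!is.null(map)) map$chrom else "1",
                    marker = colnames(W1) %||% as.character(seq_len(ncol(W1))),
                    pos_cM = if (!is.null(map)) map$pos_cM else seq_len(ncol(W1)),
                    lod = lod, stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype `n_perm` times, records the genome-wide maximum
#' LOD of each permuted scan and returns the 100 (1 - alpha) percentile.
#'
#' @inheritParams scan_ml
#' @param n_perm Number of permutations (>= 100 recommended; fewer proceeds
#'   with a warning).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Integer seed.
#' @return The threshold LOD (scalar), with the permuted maxima as
#'   attribute `perm_max`.
#' @export
permutation_threshold <- function(probs, phenotype, n_perm = 1000L,
                                  alpha = 0.05, seed = 1L, map = NULL) {
  if (n_perm < 100L) warning("n_perm < 100; threshold will be noisy")
  sw <- scan_weights(probs)
  W1 <- sw$w1
  stopifnot(length(phenotype) == nrow(W1))
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample(phenotype), numeric(length(phenotype)))
  if (all(sw$degenerate)) {
    maxima <- apply(lod_regression(W1, P), 2L, max)
  } else {
    maxima <- vapply(seq_len(n_perm), function(i) {
      lod <- numeric(ncol(W1))
      if (any(sw$degenerate))
        lod[sw$degenerate] <- drop(lod_regression(W1[, sw$degenerate, drop = FALSE],
                                                  matrix(P[, i])))
      lod[!sw$degenerate] <- lod_em(W1[, !sw$degenerate, drop = FALSE], P[, i],
                                    tol = 1e-4)
      max(lod)
    }, numeric(1))
  }
  out <- unname(stats::quantile(maxima, 1 - alpha))
  attr(out, "perm_max") <- maxima
  out
}

#' 1.5-LOD support interval around the scan peak
#'
#' Takes the leftmost genome-wide peak, finds the contiguous span on the
#' peak's chromosome where LOD >= peak - drop, and expands it outward to
#' the nearest flanking scanned positions that fall below the cutoff
#' (endpoints included). A peak running into a chromosome end gives a
#' one-sided interval; a chromosome entirely above the cutoff gives the
#' whole chromosome, flagged.
#'
#' @param curve A `scan_result` from [scan_ml()].
#' @param drop LOD drop defining the support interval (default 1.5).
#' @return List with `chrom`, `cM_lo`, `cM_hi`, `peak_marker`, `peak_cM`,
#'   `peak_lod`, `width_cM` and `whole_chromosome` flag.
#' @export
lod_support_interval <- function(curve, drop = 1.5) {
  p <- which.max(curve$lod)  # leftmost max on ties
  ch <- curve$chrom[p]
  idx <- which(curve$chrom == ch)
  lod <- curve$lod[idx]
  pos <- curve$pos_cM[idx]
  pk <- which(idx == p)
  cut <- curve$lod[p] - drop
  above <- lod >= cut
  lo <- pk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- pk; while (hi < length(idx) && above[hi + 1L]) hi <- hi + 1L
  whole <- lo == 1L && hi == length(idx)
  # expand to flanking below-cutoff positions
  if (lo > 1L) lo <- lo - 1L
  if (hi < length(idx)) hi <- hi + 1L
  list(chrom = ch, cM_lo = pos[lo], cM_hi = pos[hi],
       peak_marker = curve$marker[p], peak_cM = curve$pos_cM[p],
       peak_lod = curve$lod[p], width_cM = pos[hi] - pos[lo],
       whole_chromosome = whole)
}

#' Estimated proportion of variance explained from a LOD score
#'
#' est_pve = 1 - 10^(-2 LOD / n); at a fully observed marker this equals
#' the regression R-squared.
#'
#' @param peak_lod LOD score (>= 0).
#' @param n Sample size (>= 2).
#' @return Estimated PVE in [0, 1).
#' @export
estimate_pve <- function(peak_lod, n) {
  stopifnot(peak_lod >= 0, n >= 2)
  1 - 10^(-2 * peak_lod / n)
}

#' Full single-QTL scan with threshold, support interval and PVE
#'
#' Convenience wrapper running [scan_ml()], [permutation_threshold()],
#' [lod_support_interval()] and [estimate_pve()]. Detection requires the
#' genome-wide peak to reach the permutation threshold; if `true_chrom` is
#' given, the peak must also lie on that chromosome.
#'
#' @inheritParams permutation_threshold
#' @param drop LOD drop for the support interval.
#' @param true_chrom Optional chromosome of the simulated QTL.
#' @return List: `curve`, `peak`, `threshold`, `interval`, `est_pve`,
#'   `detected`.
#' @export
scan_qtl <- function(probs, phenotype, n_perm = 1000L, alpha = 0.05,
                     seed = 1L, drop = 1.5, true_chrom = NULL, map = NULL) {
  curve <- scan_ml(probs, phenotype, map = map)
  thr <- permutation_threshold(probs, phenotype, n_perm, alpha, seed, map = map)
  iv <- lod_support_interval(curve, drop)
  det <- iv$peak_lod >= thr
  if (!is.null(true_chrom)) det <- det && iv$chrom == true_chrom
  list(curve = curve, peak = iv$peak_marker, threshold = as.numeric(thr),
       interval = iv, est_pve = estimate_pve(iv$peak_lod, length(phenotype)),
       detected = det)
}
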