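# shared machinery for the two NAM power scenarios
nam_power_engine <- function(panel, pves, n_reps, seed, scenario,
                             p_threshold = 1e-4) {
  pops <- levels(panel$population_of_line)
  n_pops <- length(pops)
  k <- length(panel$alt_parents)
  share <- alt_share_count(panel, colnames(panel$geno))
  cand <- if (scenario == "shared") which(share == k) else which(share == 1L)
  if (length(cand) == 0)
    stop("no candidate SNP for scenario '", scenario, "'")
  rates <- array(0L, c(n_pops, length(pves)),
                 dimnames = list(n_populations = seq_len(n_pops),
                                 pve = paste0(100 * pves, "%")))
  set.seed(seed)
  fp <- panel$panel
  for (rep in seq_len(n_reps)) {
    snp <- sample(cand, 1L)
    g <- panel$geno[, snp]
    if (scenario == "shared") {
      seg_pop <- NULL
      drop_order <- sample(pops)
    } else {
      seg_alt <- colnames(fp$alt)[fp$alt[match(colnames(panel$geno)[snp], fp$snps$id), ]]
      seg_pop <- panel$pop_names[match(seg_alt, panel$alt_parents)]
      # subsets keep drop_order[1:s], so the segregating population goes
      # first and is therefore part of every subset
      drop_order <- c(seg_pop, sample(setdiff(pops, seg_pop)))
    }
    # realised 0/1 QTL genotypes: HET/missing redrawn from the segregating
    # lines' homozygote ratio (missing calls in non-segregating populations
    # of the private scenario are REF by construction)
    x <- as.numeric(g == GENO_ALT)
    seg_lines <- if (is.null(seg_pop)) rep(TRUE, length(g))
                 else panel$population_of_line == seg_pop
    amb <- is.na(g) | g == GENO_HET
    n1 <- sum(g[seg_lines] == GENO_ALT, na.rm = TRUE)
    n0 <- sum(g[seg_lines] == GENO_REF, na.rm = TRUE)
    if (n1 == 0 || n0 == 0) next
    x[amb & !seg_lines] <- 0
    x[amb & seg_lines] <- stats::rbinom(sum(amb & seg_lines), 1L, n1 / (n0 + n1))
    # effect calibrated to the target PVE over the lines that realise it
    xv <- x[seg_lines]
    vx <- mean((xv - mean(xv))^2)
    e <- stats::rnorm(length(x))
    a_of <- sqrt(pves / ((1 - pves) * vx))
    for (s in n_pops:1) {
      keep_pops <- drop_order[seq_len(s)]
      lines <- panel$population_of_line %in% keep_pops
      xi <- x[lines]
      if (stats::var(xi) == 0) next
      # SNPs private to dropped populations are all-missing in the subset;
      # their removal inside kinship_matrix() is routine here
      K <- suppressMessages(kinship_matrix(panel$geno[lines, , drop = FALSE]))
      eig <- eigen(K, symmetric = TRUE)
      for (p in seq_along(pves)) {
        y <- a_of[p] * xi + e[lines]
        fit <- lmm_fit_fast(y, xi, eig)
        if (fit$p_value <= p_threshold) rates[s, p] <- rates[s, p] + 1L
      }
    }
  }
  rates <- rates / n_reps
  structure(list(rates = rates,
                 se = sqrt(rates * (1 - rates) / n_reps),
                 pves = pves, n_reps = n_reps, scenario = scenario,
                 seed = seed),
            class = "power_curve")
}

# numeric-covariate LMM LRT with a precomputed eigendecomposition;
# identical model to lmm_lrt() but skips genotype recoding
lmm_fit_fast <- function(y, x, eig) {
  ev <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- crossprod(U, y)
  X1 <- crossprod(U, cbind(1, x))
  f1 <- fit_lmm(ystar, X1, ev)
  f0 <- fit_lmm(ystar, X1[, 1L, drop = FALSE], ev)
  lrt <- max(2 * (f1$ll - f0$ll), 0)
  list(lrt_stat = lrt,
       p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       beta_hat = f1$beta[2L], lambda_hat = f1$lambda)
}

#' NAM power over population subsets: shared-allele QTL
#'
#' Per replicate, picks a SNP at which every alternate founder carries ALT
#' (so all populations segregate), simulates one phenotype across all
#' lines at each target panel-wide PVE (the same genotype and noise draws
#' are reused across PVE levels), draws one random population drop order,
#' and evaluates detection of the causal SNP by the kinship-corrected
#' mixed-model LRT on every nested subset, with kinship recomputed per
#' subset. Detection uses the causal SNP's own p-value at 1e-4.
#'
#' @param panel A `nam_panel`.
#' @param pves Target PVE levels (default the seven levels 5%, 7.5%, 10%,
#'   15%, 20%, 40%, 80%).
#' @param n_reps Replicates per grid cell.
#' @param seed Integer seed.
#' @param p_threshold Detection threshold (default 1e-4).
#' @return A `power_curve`: detection-rate matrix (subset size x PVE) with
#'   binomial standard errors.
#' @export
run_shared_qtl_power <- function(panel, pves = c(.05, .075, .10, .15, .20, .40, .80),
                                 n_reps = 1000L, seed = 1L, p_threshold = 1e-4) {
  nam_power_engine(panel, pves, n_reps, seed, "shared", p_threshold)
}

#' NAM power over population subsets: population-private QTL
#'
#' As [run_shared_qtl_power()], but the causal SNP segregates in exactly
#' one population: the effect size is calibrated so the PVE within the
#' segregating population equals the target, the segregating population is
#' never dropped, and the other populations contribute only noise lines.
#'
#' @inheritParams run_shared_qtl_power
#' @export
run_private_qtl_power <- function(panel, pves = c(.05, .075, .10, .15, .20, .40, .80),
                                  n_reps = 1000L, seed = 1L, p_threshold = 1e-4) {
  nam_power_engine(panel, pves, n_reps, seed, "private", p_threshold)
}

#' @export
print.power_curve <- function(x, ...) {
  cat("NAM power curve (", x$scenario, " scenario, ", x$n_reps, " reps)\n", sep = "")
  print(round(x$rates, 3))
  invisible(x)
}

#' Dense-vs-sparse marker density comparison
#'
#' Per replicate, simulates a QTL at a random polymorphic dense marker,
#' scans the trait with the dense marker set and again with the sparse
#' subset (both through [scan_ml()] on precomputed multipoint genotype
#' probabilities), and records the peak, the 1.5-LOD support interval, the
#' estimated PVE and (optionally) genome-wide detection against a
#' permutation threshold. Detection requires the peak to reach the
#' threshold on the true chromosome.
#'
#' @param pop A `ril_population` holding the (imputed) genotypes.
#' @param dense_markers Character vector of dense marker ids (the full set).
#' @param sparse_markers Subset of `dense_markers` forming the sparse map.
#' @param pves Target PVE levels (default 10% and 30%).
#' @param n_reps Replicates per PVE level.
#' @param seed Integer seed.
#' @param n_perm,alpha Permutation settings for detection.
#' @param detect Run permutation thresholds (default TRUE; FALSE records
#'   intervals only, much faster).
#' @param epsilon Error rate for the genotype-probability model.
#' @return Object of class `density_comparison`: per-rep results data frame
#'   plus a Table-style `summary` per PVE: mean estimated PVE and mean
#'   1.5-LOD interval for dense and sparse maps, percent interval
#'   reduction 100 (1 - dense/sparse), and percent detected with each map.
#' @export
run_density_comparison <- function(pop, dense_markers, sparse_markers,
                                   pves = c(0.10, 0.30), n_reps = 200L,
                                   seed = 1L, n_perm = 1000L, alpha = 0.05,
                                   detect = TRUE, epsilon = 0.01) {
  stopifnot(all(sparse_markers %in% dense_markers))
  di <- match(dense_markers, colnames(pop$geno))
  si <- match(sparse_markers, colnames(pop$geno))
  stopifnot(!anyNA(di), !anyNA(si))
  dmap <- pop$map[match(dense_markers, pop$map$marker), , drop = FALSE]
  smap <- pop$map[match(sparse_markers, pop$map$marker), , drop = FALSE]
  class(dmap) <- class(smap) <- c("genetic_map", "data.frame")
  gd <- pop$geno[, di, drop = FALSE]
  gs <- pop$geno[, si, drop = FALSE]
  probs_d <- genotype_probabilities(gd, dmap, epsilon = epsilon)
  probs_s <- genotype_probabilities(gs, smap, epsilon = epsilon)
  n0 <- colSums(gd == GENO_REF, na.rm = TRUE)
  n1 <- colSums(gd == GENO_ALT, na.rm = TRUE)
  poly <- which(n0 > 0 & n1 > 0)
  rows <- list()
  set.seed(seed)
  for (p in seq_along(pves)) {
    for (rep in seq_len(n_reps)) {
      mk <- sample(poly, 1L)
      sim <- simulate_qtl_phenotype(gd, mk, pves[p],
                                    seed = sample.int(2^31 - 1L, 1L))
      true_chrom <- dmap$chrom[mk]
      res <- lapply(list(dense = probs_d, sparse = probs_s), function(pr) {
        curve <- scan_ml(pr, sim$y)
        iv <- lod_support_interval(curve)
        det <- NA
        if (detect) {
          thr <- permutation_threshold(pr, sim$y, n_perm, alpha,
                                       seed = sample.int(2^31 - 1L, 1L))
          det <- iv$peak_lod >= thr && iv$chrom == true_chrom
        }
        list(iv = iv, det = det,
             pve = estimate_pve(iv$peak_lod, length(sim$y)))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        pve_target = pves[p], rep = rep, marker = dense_markers[mk],
        chrom = true_chrom,
        dense_width = res$dense$iv$width_cM, sparse_width = res$sparse$iv$width_cM,
        dense_pve = res$dense$pve, sparse_pve = res$sparse$pve,
        dense_detected = res$dense$det, sparse_detected = res$sparse$det,
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(pves, function(pv) {
    r <- reps[reps$pve_target == pv, ]
    use_d <- if (detect) r$dense_detected else rep(TRUE, nrow(r))
    use_s <- if (detect) r$sparse_detected else rep(TRUE, nrow(r))
    data.frame(pve_target = pv,
               mean_pve_dense = mean(r$dense_pve[use_d]),
               mean_pve_sparse = mean(r$sparse_pve[use_s]),
               mean_interval_dense = mean(r$dense_width[use_d]),
               mean_interval_sparse = mean(r$sparse_width[use_s]),
               pct_interval_reduction =
                 100 * (1 - mean(r$dense_width[use_d]) / mean(r$sparse_width[use_s])),
               pct_detected_dense = if (detect) 100 * mean(r$dense_detected) else NA_real_,
               pct_detected_sparse = if (detect) 100 * mean(r$sparse_detected) else NA_real_)
  }))
  structure(list(reps = reps, summary = summ, n_reps = n_reps, seed = seed),
            class = "density_comparison")
}

#' Summarise a power curve: marginal gains and the saturation knee
#'
#' For each PVE level, computes the marginal detection-rate gain of each
#' added population and the smallest panel size beyond which every further
#' incremental gain falls below `epsilon` (a flat curve reports 1).
#'
#' @param curve A `power_curve`.
#' @param epsilon Gain threshold (default 0.02).
#' @return List with `gains` (matrix, gains of sizes 2..S) and `knee`
#'   (named vector per PVE).
#' @export
summarize_power <- function(curve, epsilon = 0.02) {
  r <- curve$rates
  S <- nrow(r)
  gains <- r[-1L, , drop = FALSE] - r[-S, , drop = FALSE]
  rownames(gains) <- paste0("+pop", 2:S)
  knee <- apply(gains, 2L, function(g) {
    big <- which(g >= epsilon)
    if (length(big) == 0) 1L else max(big) + 1L
  })
  list(gains = gains, knee = knee)
}
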