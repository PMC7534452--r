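#' Merge RIL populations into a NAM panel
#'
#' Merges per-population dense (projected) genotype matrices on the union
#' of SNP positions of the shared coordinate system. A population lacking a
#' SNP contributes missing calls there; line ids are made globally unique
#' with a population prefix.
#'
#' @param pops List of `ril_population` objects (>= 2), all sharing the
#'   recurrent parent.
#' @param dense_genos List (same length) of dense genotype matrices for the
#'   populations, columns named by SNP id as in the founder panel.
#' @param panel The `founder_panel` (supplies SNP coordinates and founder
#'   states).
#' @return Object of class `nam_panel`: list with `geno` (all lines x
#'   union SNPs), `map` (dense `genetic_map` over the union),
#'   `population_of_line` (factor), `pop_names`, `alt_parents` and `panel`.
#' @export
merge_populations <- function(pops, dense_genos, panel) {
  stopifnot(length(pops) >= 2, length(dense_genos) == length(pops))
  snp_union <- sort(unique(unlist(lapply(dense_genos, colnames))))
  dense_map <- panel_dense_map(panel)
  keep <- dense_map$marker %in% snp_union
  map <- dense_map[keep, , drop = FALSE]
  class(map) <- c("genetic_map", "data.frame")
  mats <- list(); popf <- character(0)
  for (k in seq_along(pops)) {
    g <- dense_genos[[k]]
    rn <- paste0(pops[[k]]$name, ":", rownames(g) %||% seq_len(nrow(g)))
    m <- matrix(NA_integer_, nrow(g), nrow(map), dimnames = list(rn, map$marker))
    m[, intersect(colnames(g), map$marker)] <- g[, intersect(colnames(g), map$marker)]
    mats[[k]] <- m
    popf <- c(popf, rep(pops[[k]]$name, nrow(g)))
  }
  geno <- do.call(rbind, mats)
  if (anyDuplicated(rownames(geno))) stop("duplicate line ids after prefixing")
  structure(list(geno = geno, map = map,
                 population_of_line = factor(popf, unique(popf)),
                 pop_names = vapply(pops, `[[`, "", "name"),
                 alt_parents = vapply(pops, `[[`, "", "alt_parent"),
                 panel = panel),
            class = "nam_panel")
}

#' @export
print.nam_panel <- function(x, ...) {
  cat("NAM panel:", nlevels(x$population_of_line), "populations,",
      nrow(x$geno), "lines x", ncol(x$geno), "SNPs;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Collapse neighbouring markers in perfect linkage
#'
#' Maximal runs of adjacent SNPs whose full genotype columns are identical
#' with respect to both marker state and missing-data pattern are reduced
#' to their first member. A representatives map records, for every input
#' SNP, which retained SNP stands for it, so collapsed columns can be
#' reconstructed exactly. Idempotent.
#'
#' @param panel A `nam_panel`.
#' @return The reduced `nam_panel`, with a `representative` attribute:
#'   named character vector input SNP -> retained SNP.
#' @export
collapse_perfect_ld <- function(panel) {
  g <- panel$geno
  M <- ncol(g)
  rep_of <- character(M); names(rep_of) <- colnames(g)
  keep <- logical(M)
  cur <- 1L; keep[1L] <- TRUE; rep_of[1L] <- colnames(g)[1L]
  if (M > 1) for (j in 2:M) {
    same <- panel$map$chrom[j] == panel$map$chrom[cur] &&
      identical(unname(g[, j]), unname(g[, cur]))
    if (same) {
      rep_of[j] <- colnames(g)[cur]
    } else {
      keep[j] <- TRUE; cur <- j; rep_of[j] <- colnames(g)[j]
    }
  }
  panel$geno <- g[, keep, drop = FALSE]
  m <- panel$map[keep, , drop = FALSE]
  class(m) <- c("genetic_map", "data.frame")
  panel$map <- m
  attr(panel, "representative") <- rep_of
  panel
}

#' Number of alternate founders sharing the ALT state per SNP
#'
#' @param panel A `nam_panel` (or `founder_panel` with SNP ids).
#' @param snp_ids SNP ids to look up.
#' @return Integer vector of ALT-sharing counts among the panel's founders.
#' @export
alt_share_count <- function(panel, snp_ids) {
  fp <- if (inherits(panel, "nam_panel")) panel$panel else panel
  idx <- match(snp_ids, fp$snps$id)
  if (anyNA(idx)) stop("unknown SNP id(s)")
  rowSums(fp$alt[idx, , drop = FALSE])
}

#' Build the joint-linkage map of a NAM panel
#'
#' Retains SNPs whose ALT state is shared by at least `min_shared` of the
#' alternate founders (recombination events being detectable only where a
#' population segregates), recodes calls in populations that are not
#' polymorphic for a SNP to missing, and estimates cM positions on the
#' merged data with the adjacent-interval estimator of [estimate_map()].
#'
#' @param panel A `nam_panel` (typically after [collapse_perfect_ld()]).
#' @param min_shared Minimum number of alternate founders sharing ALT
#'   (default 11 of 14).
#' @param map_function Passed to [estimate_map()].
#' @return List of class `joint_map`: `map` (a `genetic_map`), `share`
#'   (per-SNP ALT-share counts) and `geno` (the recoded genotype matrix).
#' @export
build_joint_map <- function(panel, min_shared = 11L,
                            map_function = c("kosambi", "haldane")) {
  share <- alt_share_count(panel, colnames(panel$geno))
  keep <- share >= min_shared
  if (!any(keep)) {
    warning("no SNP passes the sharing threshold")
    return(structure(list(map = NULL, share = integer(0), geno = NULL,
                          empty = TRUE), class = "joint_map"))
  }
  g <- panel$geno[, keep, drop = FALSE]
  m <- panel$map[keep, , drop = FALSE]
  class(m) <- c("genetic_map", "data.frame")
  fp <- panel$panel
  snp_idx <- match(colnames(g), fp$snps$id)
  for (k in seq_along(panel$pop_names)) {
    lines_k <- panel$population_of_line == panel$pop_names[k]
    mono <- !fp$alt[snp_idx, panel$alt_parents[k]]
    if (any(mono)) g[lines_k, mono] <- NA_integer_
  }
  pseudo <- structure(list(name = "joint", alt_parent = NA_character_,
                           generation = 8L, geno = g, map = m),
                      class = "ril_population")
  est <- estimate_map(pseudo, map_function = match.arg(map_function))
  structure(list(map = est, share = share[keep], geno = g, empty = FALSE),
            class = "joint_map")
}

#' Realised-relationship kinship matrix
#'
#' K = G_c G_c' / p over the p retained SNPs, where G_c is the lines x SNPs
#' matrix of {0, 1} genotype codes (HET = 0.5) with missing calls
#' mean-imputed per SNP and each column centred. Symmetric and positive
#' semi-definite by construction.
#'
#' @param geno Lines x SNPs genotype matrix.
#' @return Lines x lines kinship matrix.
#' @export
kinship_matrix <- function(geno) {
  if (ncol(geno) < 2) stop("need at least 2 SNPs")
  X <- matrix(NA_real_, nrow(geno), ncol(geno))
  X[geno == GENO_REF] <- 0
  X[geno == GENO_ALT] <- 1
  X[geno == GENO_HET] <- 0.5
  mu <- colMeans(X, na.rm = TRUE)
  allna <- is.nan(mu)
  if (any(allna)) {
    X <- X[, !allna, drop = FALSE]; mu <- mu[!allna]
    message(sum(allna), " all-missing SNP(s) dropped from kinship")
  }
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na)) X[na] <- mu[na[, 2L]]
  Xc <- sweep(X, 2L, mu)
  K <- tcrossprod(Xc) / ncol(Xc)
  dimnames(K) <- list(rownames(geno), rownames(geno))
  K
}

# profile log-likelihood pieces after rotation by eigenvectors of K
lmm_profile_ll <- function(log_lambda, ystar, Xstar, ev) {
  lambda <- exp(log_lambda)
  d <- lambda * ev + 1
  w <- 1 / d
  XtWX <- crossprod(Xstar, Xstar * w)
  XtWy <- crossprod(Xstar, ystar * w)
  beta <- solve(XtWX, XtWy)
  res <- ystar - Xstar %*% beta
  n <- length(ystar)
  s2 <- sum(res^2 * w) / n
  ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n)
  list(ll = ll, beta = beta, lambda = lambda, s2 = s2)
}

fit_lmm <- function(ystar, Xstar, ev) {
  opt <- stats::optimize(function(l) lmm_profile_ll(l, ystar, Xstar, ev)$ll,
                         interval = log(c(1e-5, 1e5)), maximum = TRUE,
                         tol = 1e-8)
  fit <- lmm_profile_ll(opt$maximum, ystar, Xstar, ev)
  fit
}

#' Kinship-corrected mixed-model likelihood-ratio test for one SNP
#'
#' Fits y = mu + x beta + u + e with u ~ N(0, sigma_g^2 K) and
#' e ~ N(0, sigma_e^2 I) by maximum likelihood: after a one-time spectral
#' decomposition of K, the likelihood is profiled analytically in beta and
#' sigma_e^2 and maximised over lambda = sigma_g^2 / sigma_e^2 on the log
#' scale over [1e-5, 1e5]. The LRT statistic 2 (l1 - l0) against beta = 0
#' (each model maximised over its own lambda) is referred to chi-square
#' with 1 df; detection uses p <= 1e-4, inclusive at the boundary.
#'
#' Lines missing the tested SNP are dropped (pass a matching `eig` only if
#' computed on the same line subset).
#'
#' @param phenotype Numeric phenotype vector.
#' @param snp Genotype codes at the tested SNP (coded 0/1; HET counts 0.5).
#' @param K Kinship matrix (ignored when `eig` is supplied).
#' @param eig Optional precomputed `eigen(K, symmetric = TRUE)` for reuse
#'   across SNPs/phenotypes on the same line set.
#' @param p_threshold Detection threshold (default 1e-4).
#' @return List of class `lmm_result`: `beta_hat`, `lambda_hat`,
#'   `lrt_stat`, `p_value`, `detected`, `n`.
#' @export
lmm_lrt <- function(phenotype, snp, K = NULL, eig = NULL, p_threshold = 1e-4) {
  x <- rep(NA_real_, length(snp))
  x[!is.na(snp) & snp == GENO_REF] <- 0
  x[!is.na(snp) & snp == GENO_ALT] <- 1
  x[!is.na(snp) & snp == GENO_HET] <- 0.5
  ok <- !is.na(x) & !is.na(phenotype)
  if (is.null(eig)) {
    stopifnot(!is.null(K))
    Ks <- K[ok, ok, drop = FALSE]
    if (min(eigen(Ks, symmetric = TRUE, only.values = TRUE)$values) < -1e-6)
      stop("kinship matrix is not positive semi-definite")
    eig <- eigen(Ks, symmetric = TRUE)
  } else if (length(eig$values) != sum(ok)) {
    stop("precomputed eigendecomposition does not match the complete-case lines")
  }
  y <- phenotype[ok]; x <- x[ok]
  if (stats::var(x) == 0) stop("monomorphic SNP among complete-case lines")
  n <- length(y)
  ev <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- crossprod(U, y)
  X1 <- crossprod(U, cbind(1, x))
  X0 <- X1[, 1L, drop = FALSE]
  f1 <- fit_lmm(ystar, X1, ev)
  f0 <- fit_lmm(ystar, X0, ev)
  lrt <- max(2 * (f1$ll - f0$ll), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(beta_hat = f1$beta[2L], lambda_hat = f1$lambda,
                 lrt_stat = lrt, p_value = p,
                 detected = detect_association(p, p_threshold), n = n),
            class = "lmm_result")
}

#' Detection rule for NAM association tests
#'
#' @param p_value P-value in (0, 1].
#' @param threshold Detection threshold (default 1e-4, the conventional
#'   genome-wide cut corresponding to a LOD of about 3; the chi-square
#'   1-df quantile at 1e-4 is 15.137, i.e. LOD 3.29). Inclusive boundary.
#' @return Logical.
#' @export
detect_association <- function(p_value, threshold = 1e-4) {
  stopifnot(all(p_value > 0), all(p_value <= 1))
  p_value <= threshold
}
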