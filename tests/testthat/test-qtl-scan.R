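test_that("simulated phenotype hits the requested effect size and PVE", {
  g <- matrix(rep(c(GENO_REF, GENO_ALT), each = 2000), ncol = 1,
              dimnames = list(NULL, "q"))
  sim <- simulate_qtl_phenotype(g, "q", pve = 0.5, seed = 2)
  # Var(x) = 1/4 for a balanced marker, so a = sqrt(0.5 / (0.5 * 0.25)) = 2
  expect_equal(sim$a, 2)
  expect_identical(sim$x, as.numeric(g[, 1] == GENO_ALT))
  # realised R^2 close to the target PVE
  r2 <- summary(stats::lm(sim$y ~ sim$x))$r.squared
  expect_lt(abs(r2 - 0.5), 0.04)

  # HET/missing lines get x redrawn at the homozygote ratio, none dropped
  g2 <- matrix(c(rep(GENO_REF, 300), rep(GENO_ALT, 100),
                 rep(GENO_HET, 50), rep(NA_integer_, 50)), ncol = 1,
               dimnames = list(NULL, "q"))
  s2 <- simulate_qtl_phenotype(g2, "q", pve = 0.2, seed = 3)
  expect_equal(length(s2$y), 500)
  amb <- is.na(g2[, 1]) | g2[, 1] == GENO_HET
  expect_true(all(s2$x[amb] %in% c(0, 1)))
  expect_lt(abs(mean(s2$x[amb]) - 0.25), 3 * sqrt(0.25 * 0.75 / 100))

  gm <- matrix(rep(GENO_REF, 10), ncol = 1, dimnames = list(NULL, "q"))
  expect_error(simulate_qtl_phenotype(gm, "q", 0.3), "monomorphic")
})

test_that("complete-data scan equals the regression LOD from lm", {
  set.seed(21)
  n <- 80
  G <- matrix(sample(c(GENO_REF, GENO_ALT), n * 12, replace = TRUE), n, 12,
              dimnames = list(paste0("L", 1:n), paste0("m", 1:12)))
  y <- rnorm(n) + 0.8 * (G[, 4] == GENO_ALT)
  sc <- scan_ml(G, y)
  for (j in c(1, 4, 9)) {
    fit0 <- stats::lm(y ~ 1); fit1 <- stats::lm(y ~ I(G[, j] == GENO_ALT))
    lod_lm <- (n / 2) * log10(sum(resid(fit0)^2) / sum(resid(fit1)^2))
    expect_equal(sc$lod[j], lod_lm, tolerance = 1e-10)
  }
  # EM on degenerate weights agrees with the closed form
  W <- matrix(as.numeric(G == GENO_ALT), n, 12)
  expect_equal(namqtl:::lod_em(W, y), drop(namqtl:::lod_regression(W, matrix(y))),
               tolerance = 1e-6, ignore_attr = TRUE)
  # constant marker scores 0
  Gc <- cbind(G, const = rep(GENO_REF, n))
  expect_equal(scan_ml(Gc, y)$lod[13], 0)
  expect_error(scan_ml(G, rep(1, n)), "variance")
})

test_that("EM mixture LOD matches direct likelihood maximisation", {
  set.seed(31)
  n <- 40
  W <- matrix(runif(n * 3), n, 3)
  W[, 2] <- plogis(3 * rnorm(n))          # informative but uncertain weights
  y <- rnorm(n) + 1.2 * (W[, 2] > 0.5)
  lod_pkg <- namqtl:::lod_em(W, y, tol = 1e-9, maxit = 500L)
  mix_nll <- function(par, w) {
    s2 <- exp(par[3])
    -sum(log(pmax(w * dnorm(y, par[1], sqrt(s2)) +
                  (1 - w) * dnorm(y, par[2], sqrt(s2)), 1e-300)))
  }
  ll0 <- sum(dnorm(y, mean(y), sqrt(mean((y - mean(y))^2)), log = TRUE))
  for (j in 1:3) {
    best <- -Inf
    for (st in list(c(1, 0, 0), c(0, 1, 0), c(mean(y), mean(y), log(var(y))))) {
      o <- optim(st, mix_nll, w = W[, j], method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
      best <- max(best, -o$value)
    }
    expect_equal(lod_pkg[j], max((best - ll0) / log(10), 0), tolerance = 1e-4)
  }
})

test_that("permutation threshold matches the chi-square null and alpha limits", {
  set.seed(41)
  n <- 200
  G <- matrix(sample(c(GENO_REF, GENO_ALT), n, replace = TRUE), n, 1,
              dimnames = list(NULL, "m1"))
  y <- rnorm(n)
  thr <- permutation_threshold(G, y, n_perm = 600, alpha = 0.05, seed = 5)
  # single complete marker: 2 ln(10) LOD ~ chi-square_1 under the null, so
  # the 95% threshold is ~ qchisq(.95, 1) / (2 ln 10) = 0.834
  expect_lt(abs(as.numeric(thr) - qchisq(0.95, 1) / (2 * log(10))), 0.15)
  pm <- attr(thr, "perm_max")
  expect_length(pm, 600)
  # alpha = 1 gives the smallest permuted maximum
  thr1 <- permutation_threshold(G, y, n_perm = 200, alpha = 1, seed = 5)
  expect_equal(as.numeric(thr1), min(attr(thr1, "perm_max")))
  expect_warning(permutation_threshold(G, y, n_perm = 50, seed = 1), "noisy")
})

test_that("support interval follows the 1.5-LOD drop rules", {
  mk_curve <- function(chrom, pos, lod)
    structure(data.frame(chrom = chrom, marker = paste0("m", seq_along(pos)),
                         pos_cM = pos, lod = lod, stringsAsFactors = FALSE),
              class = c("scan_result", "data.frame"))
  # [0, 5, 0]: both flanks below cutoff are included
  iv <- lod_support_interval(mk_curve("c1", c(0, 10, 20), c(0, 5, 0)))
  expect_equal(c(iv$cM_lo, iv$cM_hi), c(0, 20))
  expect_equal(iv$peak_marker, "m2")
  expect_false(iv$whole_chromosome)
  # monotone rise to the right end: one-sided interval
  iv2 <- lod_support_interval(mk_curve("c1", c(0, 10, 20), c(1, 3, 6)))
  expect_equal(c(iv2$cM_lo, iv2$cM_hi), c(10, 20))
  # whole chromosome above the cutoff
  iv3 <- lod_support_interval(mk_curve("c1", c(0, 10, 20), c(5, 5.5, 5.2)))
  expect_true(iv3$whole_chromosome)
  expect_equal(iv3$width_cM, 20)
  # leftmost peak wins on a two-chromosome tie
  iv4 <- lod_support_interval(mk_curve(rep(c("c1", "c2"), each = 2),
                                       c(0, 10, 0, 10), c(1, 4, 4, 1)))
  expect_equal(iv4$chrom, "c1")
})

test_that("est_pve equals the complete-data regression R-squared", {
  expect_equal(estimate_pve(0, 100), 0)
  set.seed(51)
  n <- 120
  x <- rbinom(n, 1, 0.5); y <- x + rnorm(n)
  r2 <- summary(stats::lm(y ~ x))$r.squared
  lod <- -(n / 2) * log10(1 - r2)
  expect_equal(estimate_pve(lod, n), r2, tolerance = 1e-12)
  expect_error(estimate_pve(-1, 100), ">= 0")
})

test_that("a 30% PVE QTL is detected with a localised support interval", {
  fx <- make_pop(n_lines = 150, seed = 71, snp_density = 15)
  poly <- polymorphic_snps(fx$founders, fx$alt)
  G <- fx$pop$truth$geno[, poly]
  map <- fx$pop$truth$map[match(poly, fx$pop$truth$map$marker), ]
  # pick a segregating marker mid-chromosome 1
  c1 <- which(map$chrom == "Chr1")
  q <- c1[which.min(abs(map$pos_cM[c1] - 35))]
  sim <- simulate_qtl_phenotype(G, map$marker[q], pve = 0.30, seed = 8)
  res <- scan_qtl(G, sim$y, n_perm = 300, seed = 9, true_chrom = "Chr1",
                  map = map)
  expect_true(res$detected)
  expect_equal(res$interval$chrom, "Chr1")
  expect_lt(abs(res$interval$peak_cM - map$pos_cM[q]), 10)
  expect_gte(map$pos_cM[q], res$interval$cM_lo)
  expect_lte(map$pos_cM[q], res$interval$cM_hi)
  expect_lt(abs(res$est_pve - 0.30), 0.12)
})
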